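#' Build a directed small-RNA signature from DE results
#'
#' A signature is the set of features significant at `q < alpha`, each with
#' the sign of its training log2 fold-change and the mean/sd of its training
#' log2-cpm (used to standardize unseen samples). Features with zero training
#' sd are excluded. An empty signature is legal (scored as 0 downstream).
#'
#' @param de An `srna_de` tibble computed on the training samples only.
#' @param train_logcpm Log2-cpm matrix restricted to the training samples.
#' @param alpha Significance threshold on the BH-adjusted p-value.
#' @return A tibble of class `srna_signature` with columns `feature_id`,
#'   `direction`, `train_mean`, `train_sd`; attributes `comparison`, `alpha`.
#' @export
build_signature <- function(de, train_logcpm, alpha = 0.05) {
  sel <- de$feature_id[de$q_value < alpha]
  dir <- sign(de$log2fc[de$q_value < alpha])
  if (length(sel)) {
    missing <- setdiff(sel, rownames(train_logcpm))
    if (length(missing)) {
      abort(paste0("signature feature(s) absent from the expression matrix: ",
                   toString(head(missing, 5))))
    }
    mu <- rowMeans(train_logcpm[sel, , drop = FALSE])
    s <- apply(train_logcpm[sel, , drop = FALSE], 1, sd)
    keep <- s > 0
    sig <- tibble::tibble(feature_id = sel[keep], direction = dir[keep],
                          train_mean = mu[keep], train_sd = s[keep])
  } else {
    sig <- tibble::tibble(feature_id = character(), direction = numeric(),
                          train_mean = numeric(), train_sd = numeric())
  }
  structure(sig, class = c("srna_signature", class(sig)),
            comparison = attr(de, "comparison"), alpha = alpha)
}

#' Score samples against a signature
#'
#' The score of a sample is the mean over signature entries of
#' `direction * (log2cpm - train_mean) / train_sd`: a direction-aligned
#' standardized mean, parameter-free and monotone in every selected feature.
#' Higher scores predict the second-named group of the training contrast.
#' An empty signature scores every sample 0 (the class-ambiguous value) and
#' sets the `empty` attribute.
#'
#' @param sig An `srna_signature`.
#' @param logcpm Feature-by-sample log2-cpm matrix containing the signature
#'   features (each sample's transform depends only on its own counts and
#'   per-sample technical factor, so no test-sample information leaks into
#'   training).
#' @return Named numeric vector of scores, one per column of `logcpm`.
#' @export
score_samples <- function(sig, logcpm) {
  if (nrow(sig) == 0) {
    return(structure(setNames(rep(0, ncol(logcpm)), colnames(logcpm)),
                     empty = TRUE))
  }
  missing <- setdiff(sig$feature_id, rownames(logcpm))
  if (length(missing)) {
    abort(paste0("feature(s) missing from the expression matrix: ",
                 toString(head(missing, 5))))
  }
  z <- (logcpm[sig$feature_id, , drop = FALSE] - sig$train_mean) / sig$train_sd
  structure(colMeans(sig$direction * z), empty = FALSE)
}

#' Leave-one-out cross-validated signature evaluation
#'
#' For every sample in the two compared groups: hold the sample out, run the
#' full selection pipeline on the remainder (expression filter, precision
#' weighting, moderated t, BH adjustment, signature construction at
#' `q < alpha`), then score the held-out sample. Feature selection is thus
#' nested inside every fold, which is what keeps the null AUC at 0.5.
#' Normalization factors are per-sample technical quantities derived from the
#' spike-ins without access to labels, so they are computed once globally.
#' After all folds, the out-of-fold scores give the ROC curve, Mann-Whitney
#' AUC, DeLong confidence interval and one-sided rank-test p-value.
#'
#' @inheritParams de_analysis
#' @param alpha Signature significance threshold.
#' @param nested If `FALSE`, feature selection is deliberately done once on
#'   all samples (the biased, non-nested mode) — provided only to demonstrate
#'   the selection bias the nested design avoids.
#' @param predictor `"standardized_mean"` (default; parameter-free, no tuning
#'   inside small folds) or `"logistic"`: a logistic regression on the
#'   standardized signature features, refit in every training fold, provided
#'   for comparison. Rank-deficient or separated fits fall back on dropping
#'   inestimable coefficients.
#' @return An object of class `srna_cv`: list with `scores` (tibble:
#'   `sample_id`, `group`, `label`, `score`, `signature_size`), `auc`, `ci`,
#'   `ci_flagged`, `p_value`, `n_pos`, `n_neg`, `empty_fold_fraction`,
#'   `settings`.
#' @export
loocv_signature <- function(ds, comparison, covariates = c("age", "sex", "bmi"),
                            rule = c("frac50", "all_samples"), alpha = 0.05,
                            factors = NULL, extra = NULL, lib_size = NULL,
                            nested = TRUE,
                            predictor = c("standardized_mean", "logistic")) {
  rule <- match.arg(rule)
  predictor <- match.arg(predictor)
  comparison <- SRNA_GROUPS[match(tolower(as.character(comparison)),
                                  tolower(SRNA_GROUPS))]
  if (is.null(factors) && length(calibrator_ids(ds)) >= 2) {
    factors <- calibrator_norm_factors(ds)
  }
  if (is.null(lib_size)) lib_size <- biological_libsize(ds)

  smp <- ds$samples
  in_cmp <- smp$sample_id[smp$group %in% comparison]
  grp <- smp$group[match(in_cmp, smp$sample_id)]
  if (any(table(factor(grp, levels = comparison)) < 2)) {
    abort("both compared groups need at least 2 samples")
  }
  cds <- subset_dataset(ds, samples = in_cmp)
  logcpm <- cpm_matrix(cds, factors, log = TRUE, lib_size = lib_size)

  fixed_sig_features <- NULL
  if (!nested) {
    de_all <- de_analysis(cds, comparison, covariates, rule, factors,
                          extra, lib_size)
    fixed_sig_features <- de_all[de_all$q_value < alpha,
                                 c("feature_id", "log2fc")]
  }

  one_fold <- function(s) {
    train_id <- setdiff(in_cmp, s)
    tgrp <- grp[in_cmp != s]
    if (any(table(factor(tgrp, levels = comparison)) == 0)) {
      abort(paste0("removing sample '", s, "' empties a training group"))
    }
    train <- subset_dataset(cds, samples = train_id)
    train_logcpm <- logcpm[, train_id, drop = FALSE]
    if (nested) {
      de <- de_analysis(train, comparison, covariates, rule, factors,
                        extra, lib_size)
      sig <- build_signature(de, train_logcpm[de$feature_id, , drop = FALSE],
                             alpha)
    } else {
      fake_de <- tibble::tibble(feature_id = fixed_sig_features$feature_id,
                                log2fc = fixed_sig_features$log2fc,
                                q_value = 0)
      attr(fake_de, "comparison") <- comparison
      present <- fake_de$feature_id[fake_de$feature_id %in% rownames(train_logcpm)]
      fake_de <- fake_de[fake_de$feature_id %in% present, , drop = FALSE]
      sig <- build_signature(fake_de,
                             train_logcpm[fake_de$feature_id, , drop = FALSE],
                             alpha)
    }
    if (predictor == "logistic" && nrow(sig) > 0) {
      sc <- logistic_score(sig, train_logcpm, tgrp == comparison[2],
                           logcpm[, s, drop = FALSE])
    } else {
      sc <- score_samples(sig, logcpm[, s, drop = FALSE])
    }
    c(score = unname(sc[1]), size = nrow(sig))
  }

  fold <- vapply(in_cmp, one_fold, c(score = 0, size = 0))
  scores <- tibble::tibble(
    sample_id = in_cmp,
    group = grp,
    label = as.integer(grp == comparison[2]),
    score = fold["score", ],
    signature_size = as.integer(fold["size", ])
  )

  a <- auc_mw(scores$score, scores$label)
  ci <- auc_ci_delong(scores$score, scores$label)
  pv <- auc_pvalue_mw(scores$score, scores$label)

  structure(list(
    scores = scores,
    auc = a,
    ci = as.numeric(ci),
    ci_flagged = isTRUE(attr(ci, "flagged")),
    p_value = pv,
    n_pos = sum(scores$label == 1),
    n_neg = sum(scores$label == 0),
    empty_fold_fraction = mean(scores$signature_size == 0),
    settings = list(comparison = paste(comparison, collapse = "_vs_"),
                    covariates = covariates, filter_rule = rule,
                    alpha = alpha, nested = nested, predictor = predictor)
  ), class = "srna_cv")
}

#' @export
print.srna_cv <- function(x, ...) {
  cat("Leave-one-out cross-validated signature (", x$settings$comparison,
      ")\n", sep = "")
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f), one-sided p = %.3g\n",
              x$auc, x$ci[1], x$ci[2], x$p_value))
  cat(sprintf("  %d folds (%d vs %d); empty-signature folds: %.0f%%\n",
              nrow(x$scores), x$n_pos, x$n_neg, 100 * x$empty_fold_fraction))
  invisible(x)
}

#' ROC curve from scores and binary labels
#'
#' Thresholds at every distinct score with ties grouped; the curve is
#' anchored at (0,0) and (1,1) and both coordinates are non-decreasing.
#'
#' @param scores Numeric scores (higher predicts the positive class).
#' @param labels Binary labels (1/TRUE = positive class).
#' @return A tibble of class `srna_roc` with columns `threshold`, `fpr`,
#'   `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  lab <- check_labels(scores, labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- lab[o]
  grp_end <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1 - y)[grp_end]
  out <- tibble::tibble(
    threshold = c(Inf, s[grp_end]),
    fpr = c(0, fp / sum(lab == 0)),
    tpr = c(0, tp / sum(lab == 1))
  )
  structure(out, class = c("srna_roc", class(out)))
}

#' Mann-Whitney AUC estimator
#'
#' `(concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg)`, identical to
#' the trapezoidal area under [roc_curve()]. Computed via mid-ranks.
#'
#' @inheritParams roc_curve
#' @return The AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  lab <- check_labels(scores, labels)
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  r <- rank(scores)  # mid-ranks for ties
  (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance via structural components (the per-positive and
#' per-negative placement values), with a Wald interval on the AUC scale
#' truncated to \[0, 1\]. Perfect separation gives zero variance; the
#' interval degenerates to `(auc, auc)` and is flagged.
#'
#' @inheritParams roc_curve
#' @param level Confidence level (default 0.95).
#' @return Length-2 numeric `(low, high)` with attributes `auc`, `se` and
#'   `flagged`.
#' @export
auc_ci_delong <- function(scores, labels, level = 0.95) {
  lab <- check_labels(scores, labels)
  x <- scores[lab == 1]; y <- scores[lab == 0]
  m <- length(x); n <- length(y)
  if (m < 2 || n < 2) abort("DeLong CI needs >= 2 samples in each class")
  # placement values: fraction of the other class each sample beats
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  a <- mean(v10)
  s2 <- var(v10) / m + var(v01) / n
  if (s2 <= 0) {
    return(structure(c(a, a), auc = a, se = 0, flagged = TRUE))
  }
  z <- qnorm(1 - (1 - level) / 2)
  ci <- pmin(1, pmax(0, a + c(-1, 1) * z * sqrt(s2)))
  structure(ci, auc = a, se = sqrt(s2), flagged = FALSE)
}

#' One-sided Mann-Whitney p-value for AUC > 0.5
#'
#' Normal approximation to the Mann-Whitney U statistic with tie-corrected
#' variance; tests H0: AUC = 0.5 against AUC > 0.5.
#'
#' @inheritParams roc_curve
#' @return The one-sided p-value.
#' @export
auc_pvalue_mw <- function(scores, labels) {
  lab <- check_labels(scores, labels)
  m <- sum(lab == 1); n <- sum(lab == 0)
  N <- m + n
  r <- rank(scores)
  U <- sum(r[lab == 1]) - m * (m + 1) / 2
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- m * n / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(if (U > m * n / 2) 0 else 0.5)
  z <- (U - m * n / 2) / sqrt(v)
  pnorm(z, lower.tail = FALSE)
}

# Logistic-regression predictor over standardized signature features; the
# linear predictor of the held-out sample is the score. Coefficients that a
# rank-deficient fit cannot estimate are treated as zero.
logistic_score <- function(sig, train_logcpm, train_pos, test_col) {
  zt <- t((train_logcpm[sig$feature_id, , drop = FALSE] - sig$train_mean) /
            sig$train_sd)
  X <- cbind(1, zt)
  fit <- suppressWarnings(
    stats::glm.fit(X, as.numeric(train_pos),
                   family = stats::binomial())
  )
  b <- fit$coefficients
  b[is.na(b)] <- 0
  zs <- (test_col[sig$feature_id, 1] - sig$train_mean) / sig$train_sd
  sum(b * c(1, zs))
}

# Coerce labels to 0/1 and require both classes.
check_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.integer(labels == levels(labels)[2])
  if (!all(labels %in% c(0, 1))) abort("labels must be binary (0/1, logical, or a 2-level factor)")
  if (length(unique(labels)) < 2) abort("both classes must be present")
  as.integer(labels)
}
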