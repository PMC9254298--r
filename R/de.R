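#' Class-specific expression filter
#'
#' Keeps features expressed at `>= min_cpm` counts-per-million (inclusive
#' boundary: "at least 1 cpm") in either all samples (`"all_samples"`, the
#' rule for mature miRNAs) or at least half of the samples (`"frac50"`, the
#' laxer rule for isomiRs and other sRNAs, which are by construction less
#' expressed than their parent miRNAs). cpm uses calibrator-effective library
#' sizes, the same transform as everywhere else in the pipeline. Calibrator
#' rows are always removed before testing.
#'
#' @param ds An [srna_dataset()].
#' @param factors Normalization factors tibble, or `NULL` for unit factors.
#' @param rule `"frac50"` or `"all_samples"`.
#' @param min_cpm Expression threshold in cpm (default 1).
#' @param lib_size Optional per-sample library-size override (see
#'   [cpm_matrix()]).
#' @return The filtered `srna_dataset` (possibly with zero features, with a
#'   warning).
#' @export
filter_features <- function(ds, factors = NULL,
                            rule = c("frac50", "all_samples"),
                            min_cpm = 1, lib_size = NULL) {
  rule <- match.arg(rule)
  x <- cpm_matrix(ds, factors, log = FALSE, lib_size = lib_size)
  frac <- rowMeans(x >= min_cpm)
  keep <- if (rule == "all_samples") frac >= 1 else frac >= 0.5
  keep <- keep & ds$annotation$feature_class != "calibrator"
  if (!any(keep)) warn("no feature passes the expression filter")
  subset_dataset(ds, features = rownames(ds$counts)[keep])
}

#' Build a two-group design matrix with clinical covariates
#'
#' Rows are restricted to the two compared groups. Columns are an intercept,
#' a treatment-coded group indicator (1 for the second-named group, so the
#' reported log2 fold-change is second vs first), then the requested
#' covariates. `sex` is coded female = 0 / male = 1; continuous covariates
#' enter unscaled. Extra per-sample covariates (e.g. the tRNA-length
#' abundance) are supplied as named numeric vectors keyed by sample id.
#' Missing covariate values are a hard error, never dropped or imputed.
#'
#' @param samples A sample table (tibble with `sample_id`, `group`, ...).
#' @param comparison Character vector of two group names, reference first.
#' @param covariates Names of covariate columns in `samples` (default age,
#'   sex, bmi; `duration` may be added for within-diabetes contrasts).
#' @param extra Named list of additional numeric covariates, each a vector
#'   named by sample id.
#' @return The design matrix with attributes `coef` (the group coefficient
#'   name), `comparison` and `sample_id`.
#' @export
build_design <- function(samples, comparison,
                         covariates = c("age", "sex", "bmi"),
                         extra = NULL) {
  comparison <- as.character(comparison)
  if (length(comparison) != 2) abort("comparison must name exactly two groups")
  idx <- match(tolower(comparison), tolower(SRNA_GROUPS))
  if (anyNA(idx)) abort(paste0("unknown group in comparison: ",
                               toString(comparison[is.na(idx)])))
  comparison <- SRNA_GROUPS[idx]

  keep <- samples$group %in% comparison
  if (sum(samples$group == comparison[1]) == 0 ||
      sum(samples$group == comparison[2]) == 0) {
    abort(paste0("comparison group(s) empty: ", toString(comparison)))
  }
  smp <- samples[keep, , drop = FALSE]

  coef_name <- paste0("group", comparison[2])
  X <- cbind(`(Intercept)` = 1,
             as.numeric(smp$group == comparison[2]))
  colnames(X)[2] <- coef_name

  for (v in covariates) {
    if (!v %in% names(smp)) abort(paste0("covariate '", v, "' not found in sample table"))
    col <- smp[[v]]
    if (v == "sex") col <- as.numeric(smp$sex == "male")
    col <- as.numeric(col)
    if (anyNA(col)) {
      abort(paste0("covariate '", v, "' is missing for sample(s): ",
                   toString(head(smp$sample_id[is.na(col)], 5)),
                   " (missing covariates are never imputed)"))
    }
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- v
  }
  for (v in names(extra)) {
    col <- extra[[v]][smp$sample_id]
    if (anyNA(col)) {
      abort(paste0("extra covariate '", v, "' is missing for sample(s): ",
                   toString(head(smp$sample_id[is.na(col)], 5))))
    }
    X <- cbind(X, as.numeric(col))
    colnames(X)[ncol(X)] <- v
  }

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; offending column(s): ",
                 toString(dropped)))
  }
  rownames(X) <- smp$sample_id
  structure(X, coef = coef_name, comparison = comparison,
            sample_id = smp$sample_id)
}

#' Per-sample abundance of fragments in a length window
#'
#' Log2 of one plus the total count of features whose annotated fragment
#' length lies in the closed range, per sample. Used as an extra covariate to
#' test whether apparent tRNA-fragment differences merely track library
#' length composition (default window 30-33 nt, the tRNA-fragment lengths).
#'
#' @param ds An [srna_dataset()] with `fragment_length` annotation.
#' @param length_range Closed length window in nucleotides.
#' @return Named numeric vector (one value per sample) suitable for the
#'   `extra` argument of [build_design()].
#' @export
length_abundance_covariate <- function(ds, length_range = c(30, 33)) {
  len <- ds$annotation$fragment_length
  sel <- !is.na(len) & len >= length_range[1] & len <= length_range[2]
  if (!any(sel)) abort(paste0("no feature with fragment_length in [",
                              length_range[1], ", ", length_range[2], "]"))
  log2(1 + colSums(ds$counts[sel, , drop = FALSE]))
}

#' Precision weights from the mean-variance trend of log-counts
#'
#' Models the mean-variance relationship of log2-cpm values and derives
#' per-observation inverse-variance weights for linear modelling, so that
#' low-count observations (noisier on the log scale) are down-weighted.
#' The steps: (i) log2-cpm with prior count 0.5 against effective library
#' size + 1; (ii) per-feature ordinary least squares on the design;
#' (iii) lowess (span 0.5) of the square-root residual standard deviation
#' against average log2 count; (iv) each observation's fitted value mapped
#' back to the count scale and looked up on the trend, extrapolating flat
#' beyond its support; (v) weight = trend value to the power -4.
#'
#' @param ds A filtered [srna_dataset()] (no calibrator rows).
#' @param design Design matrix from [build_design()].
#' @param factors Normalization factors, or `NULL`.
#' @param span Lowess span for the trend (default 0.5).
#' @param lib_size Optional per-sample library-size override.
#' @return An object of class `srna_voom`: list with `E` (log2-cpm),
#'   `weights`, `trend` (tibble `x`, `y`), `design`, `lib_size`.
#' @export
voom_fit <- function(ds, design, factors = NULL, span = 0.5, lib_size = NULL) {
  sid <- attr(design, "sample_id") %||% rownames(design)
  ds <- subset_dataset(ds, samples = sid)
  n <- ncol(ds$counts)
  g <- nrow(ds$counts)
  if (g < 2) abort("need at least 2 features")
  df_resid <- n - ncol(design)
  if (df_resid <= 0) abort("no residual degrees of freedom")

  E <- cpm_matrix(ds, factors, log = TRUE, prior = 0.5, lib_size = lib_size)
  eff <- attr(E, "effective_lib_size")

  fit <- stats::lm.fit(design, t(E))
  coefs <- t(fit$coefficients)                     # g x p
  res <- t(fit$residuals)                          # g x n
  sigma <- sqrt(rowSums(res^2) / df_resid)

  # trend of sqrt-sd vs average log2 count
  amean <- rowMeans(E)
  sx <- amean + mean(log2(eff + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  ok <- is.finite(sx) & is.finite(sy)
  if (sum(ok) < 2) abort("too few finite points to fit the mean-variance trend")
  l <- lowess(sx[ok], sy[ok], f = span)
  trend_fun <- approxfun(l$x, l$y, rule = 2, ties = mean)

  fitted_logcpm <- coefs %*% t(design)
  fitted_logcount <- t(t(fitted_logcpm) + log2(eff + 1)) - log2(1e6)
  w <- matrix(trend_fun(fitted_logcount), g, n,
              dimnames = dimnames(E))^-4

  structure(list(E = E, weights = w,
                 trend = tibble::tibble(x = l$x, y = l$y),
                 design = design, lib_size = eff,
                 feature_id = rownames(ds$counts)),
            class = "srna_voom")
}

#' Moderated t-tests from a precision-weighted fit
#'
#' Per-feature weighted least squares on the design, followed by empirical
#' Bayes moderation of the residual variances: the prior degrees of freedom
#' `d0` and prior variance `s0^2` are estimated by matching the moments of
#' log residual variances (closed-form via trigamma inversion), each
#' posterior variance is `(d0 s0^2 + d s^2) / (d0 + d)`, and the moderated t
#' uses `d0 + d` degrees of freedom. Benjamini-Hochberg adjusted p-values
#' are included.
#'
#' @param fit An `srna_voom` object.
#' @param coef Coefficient to test; defaults to the design's group
#'   coefficient.
#' @param prior_df `"auto"` (estimate `d0` from the data), a number, `0`
#'   (no moderation: ordinary WLS t) or `Inf` (full shrinkage to `s0^2`).
#' @return A tibble of class `srna_de` with columns `feature_id`, `log2fc`,
#'   `ave_expr`, `t`, `df_total`, `p_value`, `q_value`, and attributes
#'   `s2_prior`, `df_prior`, `coef`, `comparison`.
#' @export
fit_moderated <- function(fit, coef = NULL, prior_df = "auto") {
  stopifnot(inherits(fit, "srna_voom"))
  X <- fit$design
  coef <- coef %||% attr(X, "coef") %||% colnames(X)[2]
  j <- match(coef, colnames(X))
  if (is.na(j)) abort(paste0("coefficient '", coef, "' not in the design"))

  E <- fit$E; W <- fit$weights
  g <- nrow(E); n <- ncol(E); p <- ncol(X)
  df_resid <- n - p

  beta <- numeric(g); su <- numeric(g); s2 <- numeric(g)
  for (i in seq_len(g)) {
    sw <- sqrt(W[i, ])
    Xw <- X * sw
    yw <- E[i, ] * sw
    qr_i <- qr(Xw)
    b <- qr.coef(qr_i, yw)
    r <- yw - Xw %*% b
    XtXinv <- chol2inv(qr_i$qr[seq_len(p), seq_len(p), drop = FALSE])
    beta[i] <- b[j]
    su[i] <- sqrt(XtXinv[j, j])
    s2[i] <- sum(r^2) / df_resid
  }

  if (identical(prior_df, "auto")) {
    sq <- squeeze_var(s2, df_resid)
  } else if (is.infinite(prior_df)) {
    s0 <- exp(mean(log(s2[s2 > 0])))
    sq <- list(df_prior = Inf, s2_prior = s0, s2_post = rep(s0, g))
  } else {
    d0 <- as.numeric(prior_df)
    s0 <- if (d0 > 0) exp(mean(log(s2[s2 > 0]))) else NA_real_
    post <- if (d0 > 0) (d0 * s0 + df_resid * s2) / (d0 + df_resid) else s2
    sq <- list(df_prior = d0, s2_prior = s0, s2_post = post)
  }

  df_total <- df_resid + sq$df_prior
  tstat <- beta / (su * sqrt(sq$s2_post))
  pval <- 2 * pt(-abs(tstat), df = df_total)

  res <- tibble::tibble(
    feature_id = fit$feature_id,
    log2fc = beta,
    ave_expr = rowMeans(E),
    t = tstat,
    df_total = df_total,
    p_value = pval,
    q_value = bh_adjust(pval)
  )
  structure(res, class = c("srna_de", class(res)),
            s2_prior = sq$s2_prior, df_prior = sq$df_prior, coef = coef,
            comparison = attr(X, "comparison"))
}

# Empirical Bayes squeezing of residual variances: fit a scaled inverse
# chi-square prior to s^2 by matching moments of log(s^2). All features here
# share the residual df. Degenerate spreads (log-variance variance no larger
# than the sampling variance trigamma(df/2)) give d0 = Inf.
squeeze_var <- function(s2, df) {
  ok <- is.finite(log(s2))
  z <- log(s2[ok])
  if (sum(ok) < 2) {
    s0 <- exp(mean(z))
    return(list(df_prior = Inf, s2_prior = s0,
                s2_post = rep(s0, length(s2))))
  }
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (d0 > 1e7) d0 <- Inf
  } else {
    d0 <- Inf
  }
  if (is.infinite(d0)) {
    s0 <- exp(emean)
    post <- rep(s0, length(s2))
  } else {
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s0 + df * s2) / (d0 + df)
    post[!ok] <- s0
  }
  list(df_prior = d0, s2_prior = s0, s2_post = post)
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing, convex).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min over j with p_(j) >= p_(i)'s rank of min(1, p_(j) * m / j)`,
#' returned in the original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Per-variable ANOVA screen across clinical groups
#'
#' For each numeric variable, a one-way ANOVA of the variable on the group
#' factor (the per-response F-tests a multivariate screen reduces to), with
#' Bonferroni correction over the variables tested in the same screen.
#'
#' @param samples A sample table.
#' @param variables Names of numeric columns in `samples` to screen.
#' @return A tibble with columns `variable`, `statistic` (F), `df1`, `df2`,
#'   `p_value`, `p_bonferroni`. Variables with no within-group variance get
#'   `NA` statistics.
#' @export
anova_screen <- function(samples, variables) {
  grp <- droplevels(factor(samples$group))
  if (nlevels(grp) < 2) abort("need at least 2 groups")
  rows <- purrr::map_dfr(variables, function(v) {
    x <- as.numeric(samples[[v]])
    keep <- !is.na(x)
    g <- droplevels(grp[keep])
    x <- x[keep]
    if (nlevels(g) < 2 || any(table(g) < 2)) {
      abort(paste0("variable '", v, "' needs >= 2 samples in >= 2 groups"))
    }
    fit <- stats::aov(x ~ g)
    tab <- summary(fit)[[1]]
    msw <- tab["Residuals", "Mean Sq"]
    no_within_var <- all(vapply(split(x, g), var, numeric(1)) == 0)
    if (!is.finite(msw) || no_within_var) {
      return(tibble::tibble(variable = v, statistic = NA_real_,
                            df1 = tab[1, "Df"], df2 = tab["Residuals", "Df"],
                            p_value = NA_real_))
    }
    tibble::tibble(variable = v, statistic = tab[1, "F value"],
                   df1 = tab[1, "Df"], df2 = tab["Residuals", "Df"],
                   p_value = tab[1, "Pr(>F)"])
  })
  rows$p_bonferroni <- pmin(1, rows$p_value * length(variables))
  rows
}

#' One-call differential expression for a comparison
#'
#' Convenience wrapper chaining [filter_features()], [build_design()],
#' [voom_fit()] and [fit_moderated()].
#'
#' @inheritParams build_design
#' @inheritParams filter_features
#' @param ds An [srna_dataset()].
#' @param factors Normalization factors; computed from the calibrators when
#'   `NULL` and calibrators are present.
#' @param extra Extra covariates as in [build_design()].
#' @param lib_size Optional library-size override for cpm.
#' @return An `srna_de` tibble (see [fit_moderated()]).
#' @export
de_analysis <- function(ds, comparison, covariates = c("age", "sex", "bmi"),
                        rule = c("frac50", "all_samples"), factors = NULL,
                        extra = NULL, lib_size = NULL) {
  rule <- match.arg(rule)
  if (is.null(factors) && length(calibrator_ids(ds)) >= 2) {
    factors <- calibrator_norm_factors(ds)
  }
  if (is.null(lib_size)) lib_size <- biological_libsize(ds)
  design <- build_design(ds$samples, comparison, covariates, extra)
  sub <- subset_dataset(ds, samples = attr(design, "sample_id"))
  filt <- filter_features(sub, factors, rule, lib_size = lib_size)
  if (nrow(filt$counts) == 0) abort("no feature passes the expression filter")
  vf <- voom_fit(filt, design, factors, lib_size = lib_size)
  fit_moderated(vf)
}
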