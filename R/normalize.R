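#' Spike-in calibrator TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors from the calibrator
#' (spike-in) submatrix. Because a fixed amount of each calibrator is added
#' to every sample before library preparation, variation in the calibrators'
#' share of the sequenced reads reflects technical yield, not biology.
#' Calibrator proportions are therefore taken relative to the *biological*
#' library size (all non-calibrator counts): a sample that recovered fewer
#' biological reads per unit input shows inflated calibrator proportions and
#' receives a correspondingly smaller factor.
#'
#' The TMM procedure follows the conventional defaults: the reference sample
#' is the column whose calibrator-cpm upper quartile is closest to the mean
#' upper quartile; per-sample log2 proportion ratios (M) and average log2
#' proportions (A) against the reference are doubly trimmed (30% on M, 5% on
#' A); the factor is 2 to the precision-weighted mean of the surviving M
#' values, and factors are rescaled to geometric mean 1.
#'
#' @param ds An [srna_dataset()] containing `>= 2` calibrator features.
#' @return A tibble with columns `sample_id` and `norm_factor`
#'   (geometric-mean-1, method recorded in the `method` attribute).
#' @export
#' @examples
#' ds <- make_fixture("small")
#' calibrator_norm_factors(ds)
calibrator_norm_factors <- function(ds) {
  cal <- calibrator_ids(ds)
  if (length(cal) < 2) abort("need at least 2 calibrator features for TMM")
  C <- ds$counts[cal, , drop = FALSE]
  L <- biological_libsize(ds)
  if (ncol(C) < 2) abort("need at least 2 samples")

  zero <- colSums(C) == 0
  if (any(zero)) {
    abort(paste0("all calibrator counts are zero in sample(s): ",
                 toString(head(colnames(C)[zero], 5))))
  }

  # reference: calibrator-cpm upper quartile closest to the mean
  f75 <- apply(C, 2, function(x) quantile(x, 0.75)) / L * 1e6
  ref <- which.min(abs(f75 - mean(f75)))

  f <- vapply(seq_len(ncol(C)), function(s) {
    tmm_pair(C[, s], L[s], C[, ref], L[ref], sample_id = colnames(C)[s])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(
    tibble::tibble(sample_id = colnames(C), norm_factor = f),
    method = "calibrator_tmm"
  )
}

# Doubly trimmed, precision-weighted mean of M-values of one sample against
# the reference; the trimming and weighting follow the conventional TMM
# constants (M-trim 0.30, A-trim 0.05, delta-method binomial weights).
tmm_pair <- function(x, lx, y, ly, logratio_trim = 0.3, sum_trim = 0.05,
                     sample_id = "?") {
  keep <- x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (!length(x)) abort(paste0("no calibrator is nonzero in both sample '",
                               sample_id, "' and the reference"))
  M <- log2(x / lx) - log2(y / ly)
  A <- (log2(x / lx) + log2(y / ly)) / 2
  w <- 1 / ((lx - x) / (lx * x) + (ly - y) / (ly * y))

  if (max(abs(M)) < 1e-6) return(1)   # identical compositions: exact unity

  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (sum(keep2) < 2) {
    warn(paste0("fewer than 2 calibrators survive trimming for sample '",
                sample_id, "'; using the untrimmed weighted mean"))
    keep2 <- rep(TRUE, n)
  }
  2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
}

#' Counts per million with calibrator-effective library sizes
#'
#' The effective library size of a sample is its biological (non-calibrator)
#' column sum times its normalization factor. Linear cpm is
#' `count / effective * 1e6`; log2-cpm is
#' `log2((count + prior) / (effective + 1) * 1e6)` with `prior = 0.5` by
#' default, the exact transform the precision-weighting step models.
#'
#' @param ds An [srna_dataset()].
#' @param factors Tibble from [calibrator_norm_factors()], or `NULL` for unit
#'   factors.
#' @param log Return log2-cpm instead of linear cpm.
#' @param prior Prior count added on the log scale (ignored for linear cpm).
#' @param lib_size Optional named per-sample library-size override; defaults
#'   to the dataset's biological column sums. Used by the pipeline so that
#'   per-class feature subsets keep whole-library cpm units.
#' @return A feature-by-sample matrix with a `scale` attribute
#'   (`"cpm"` or `"log2cpm"`) and an `effective_lib_size` attribute.
#' @export
cpm_matrix <- function(ds, factors = NULL, log = FALSE, prior = 0.5,
                       lib_size = NULL) {
  counts <- ds$counts
  if (is.null(lib_size)) lib_size <- biological_libsize(ds)
  lib_size <- lib_size[colnames(counts)]
  f <- norm_factor_vector(factors, colnames(counts))
  eff <- lib_size * f
  if (any(eff <= 0)) {
    abort(paste0("zero effective library size in sample(s): ",
                 toString(head(colnames(counts)[eff <= 0], 5))))
  }
  if (log) {
    if (prior < 0) abort("prior must be >= 0")
    x <- log2(t(t(counts + prior) / (eff + 1)) * 1e6)
    scale <- "log2cpm"
  } else {
    x <- t(t(counts) / eff) * 1e6
    scale <- "cpm"
  }
  structure(x, scale = scale, effective_lib_size = eff)
}

# Resolve a factors tibble (or NULL) into a named vector over sample_ids.
norm_factor_vector <- function(factors, sample_ids) {
  if (is.null(factors)) return(setNames(rep(1, length(sample_ids)), sample_ids))
  if (is.data.frame(factors)) {
    idx <- match(sample_ids, factors$sample_id)
    if (anyNA(idx)) {
      abort(paste0("normalization factors missing for sample(s): ",
                   toString(head(sample_ids[is.na(idx)], 5))))
    }
    f <- factors$norm_factor[idx]
  } else {
    f <- factors[sample_ids]
    if (anyNA(f)) abort("normalization factors missing for some samples")
  }
  if (any(f <= 0)) abort("normalization factors must be positive")
  setNames(as.numeric(f), sample_ids)
}

#' Row-wise z-score transform
#'
#' Each row is centered by its mean and scaled by its sample standard
#' deviation (n - 1 denominator), the transform used before plotting
#' expression heatmaps. Constant rows map to all-zero rows, never `NaN`.
#'
#' @param x A numeric matrix (features x samples).
#' @return The transformed matrix, `scale` attribute set to `"zscore"`.
#' @export
zscore_rows <- function(x) {
  if (ncol(x) < 2) abort("z-scoring needs at least 2 samples")
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  structure(z, scale = "zscore", effective_lib_size = NULL)
}

#' Per-group column means of an expression matrix
#'
#' Collapses samples to one column per clinical group (arithmetic mean), the
#' quantity shown in group-level expression heatmaps.
#'
#' @param x Feature-by-sample matrix; columns must be sample ids.
#' @param samples Sample table with `sample_id` and `group`.
#' @return Feature-by-group matrix, columns in canonical group order.
#' @export
group_means <- function(x, samples) {
  grp <- samples$group[match(colnames(x), samples$sample_id)]
  if (anyNA(grp)) abort("every column of x must appear in the sample table")
  grp <- droplevels(grp)
  if (any(table(grp) == 0)) abort("empty group")
  out <- vapply(levels(grp), function(g) {
    rowMeans(x[, grp == g, drop = FALSE])
  }, numeric(nrow(x)))
  dimnames(out) <- list(rownames(x), levels(grp))
  out
}
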