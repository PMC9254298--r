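#' Tidy a differential-expression result
#'
#' @param x An `srna_de` tibble.
#' @param sort_by_q Sort rows by adjusted p-value (default keeps the input
#'   feature order).
#' @param ... Unused.
#' @return A plain tibble with one row per tested feature.
#' @method tidy srna_de
#' @export
tidy.srna_de <- function(x, sort_by_q = FALSE, ...) {
  out <- tibble::as_tibble(unclass(x))
  if (sort_by_q) out <- dplyr::arrange(out, .data$q_value)
  out
}

#' @rdname tidy.srna_de
#' @method glance srna_de
#' @export
glance.srna_de <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_significant = sum(x$q_value < 0.05),
    s2_prior = attr(x, "s2_prior"),
    df_prior = attr(x, "df_prior"),
    coef = attr(x, "coef")
  )
}

#' Tidy a cross-validation result
#'
#' @param x An `srna_cv` object.
#' @param ... Unused.
#' @return The per-sample out-of-fold scores as a tibble.
#' @method tidy srna_cv
#' @export
tidy.srna_cv <- function(x, ...) {
  x$scores
}

#' @rdname tidy.srna_cv
#' @method glance srna_cv
#' @export
glance.srna_cv <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, ci_low = x$ci[1], ci_high = x$ci[2], p_value = x$p_value,
    n_pos = x$n_pos, n_neg = x$n_neg, n_folds = nrow(x$scores),
    empty_fold_fraction = x$empty_fold_fraction,
    comparison = x$settings$comparison, nested = x$settings$nested
  )
}

#' Tidy a signature
#'
#' @param x An `srna_signature`.
#' @param ... Unused.
#' @return A plain tibble of signature entries.
#' @method tidy srna_signature
#' @export
tidy.srna_signature <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
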