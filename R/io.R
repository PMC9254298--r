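#' Read a count matrix and its feature annotation
#'
#' Counts are a tab-delimited table whose header row holds sample ids and
#' whose first column holds feature ids; the annotation is a tab-delimited
#' table with columns `feature_id`, `feature_class`, `parent_id`,
#' `fragment_length`. All validation from [srna_dataset()] applies; cells
#' that are negative or non-integral are rejected with the offending
#' feature/sample named.
#'
#' @param path Path to the counts TSV.
#' @param annotation_path Path to the annotation TSV.
#' @return A list with elements `counts` (integer matrix) and `annotation`
#'   (tibble), validated against each other.
#' @export
read_counts <- function(path, annotation_path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2) abort("counts file must have a feature-id column and at least one sample column")
  counts <- suppressWarnings(
    vapply(raw[, -1, drop = FALSE], as.numeric, numeric(nrow(raw)))
  )
  counts <- matrix(counts, nrow = nrow(raw),
                   dimnames = list(raw[[1]], names(raw)[-1]))
  na_cell <- which(is.na(counts) & !is.na(as.matrix(raw[, -1])), arr.ind = TRUE)
  if (nrow(na_cell)) {
    abort(sprintf("non-numeric count at feature '%s', sample '%s'",
                  rownames(counts)[na_cell[1, 1]], colnames(counts)[na_cell[1, 2]]))
  }

  ann <- readr::read_tsv(annotation_path, col_types = readr::cols(
    feature_id = readr::col_character(),
    feature_class = readr::col_character(),
    parent_id = readr::col_character(),
    fragment_length = readr::col_double()
  ), progress = FALSE)

  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("non-integer or negative count at feature '%s', sample '%s'",
                  rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "double"
  # cross-validate via a throwaway sample table
  dummy <- tibble::tibble(sample_id = colnames(counts), group = "control",
                          age = 50, sex = "female", bmi = 25)
  ds <- srna_dataset(counts, ann, dummy)
  list(counts = ds$counts, annotation = ds$annotation)
}

#' Read a sample metadata table
#'
#' Tab-delimited with columns `sample_id`, `group`, `age`, `sex`, `bmi` and
#' optionally `duration` plus any further numeric covariates. Group labels are
#' matched case-insensitively to control/T1D/T2D/LADA. Missing age, sex or
#' BMI is a hard error: these enter every design matrix and are never imputed.
#'
#' @param path Path to the samples TSV.
#' @return A tibble with canonicalized `group` and `sex` factors.
#' @export
read_samples <- function(path) {
  smp <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    sex = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  normalize_sample_table(smp)
}

#' Read a full dataset from a directory or explicit paths
#'
#' @param counts_path,annotation_path,samples_path Paths to the three TSVs.
#' @return An [srna_dataset()].
#' @export
read_srna_dataset <- function(counts_path, annotation_path, samples_path) {
  cm <- read_counts(counts_path, annotation_path)
  smp <- read_samples(samples_path)
  srna_dataset(cm$counts, cm$annotation, smp)
}

#' Write a dataset's tables as TSV
#'
#' Writes `counts.tsv`, `annotation.tsv`, `samples.tsv` (and `truth.tsv` when
#' simulation ground truth is present) into `dir`. Counts round-trip exactly
#' through [read_srna_dataset()].
#'
#' @param ds An `srna_dataset`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_srna_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cm <- tibble::as_tibble(ds$counts, rownames = "feature_id")
  readr::write_tsv(cm, file.path(dir, "counts.tsv"), progress = FALSE)
  readr::write_tsv(ds$annotation, file.path(dir, "annotation.tsv"), progress = FALSE)
  readr::write_tsv(ds$samples, file.path(dir, "samples.tsv"), progress = FALSE)
  if (!is.null(ds$truth)) {
    readr::write_tsv(ds$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  }
  invisible(dir)
}

#' Write differential-expression results
#'
#' Columns, in fixed order: `feature_id`, `logFC`, `AveExpr`, `t`, `p`, `q`.
#' Feature order follows the input matrix; sort by `q` with dplyr if wanted.
#'
#' @param de An `srna_de` result from [fit_moderated()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_results <- function(de, path) {
  out <- tibble::tibble(
    feature_id = de$feature_id, logFC = de$log2fc, AveExpr = de$ave_expr,
    t = de$t, p = de$p_value, q = de$q_value
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write cross-validation scores and a JSON summary
#'
#' The TSV holds one row per sample (columns `sample_id`, `label`, `score`,
#' `fold_signature_size`); the JSON summary carries keys `auc`, `ci_low`,
#' `ci_high`, `p_value`, `n_folds`, `n_pos`, `n_neg`, `empty_fold_fraction`
#' plus the settings echo and seed.
#'
#' @param cv An `srna_cv` result from [loocv_signature()].
#' @param scores_path Output TSV path for the per-sample scores.
#' @param summary_path Output JSON path; default replaces the TSV extension.
#' @return `scores_path`, invisibly.
#' @export
write_cv_result <- function(cv, scores_path,
                            summary_path = sub("\\.tsv$", ".json", scores_path)) {
  sc <- tibble::tibble(
    sample_id = cv$scores$sample_id, label = cv$scores$label,
    score = cv$scores$score, fold_signature_size = cv$scores$signature_size
  )
  readr::write_tsv(sc, scores_path, progress = FALSE)
  summary <- c(list(
    auc = cv$auc, ci_low = cv$ci[1], ci_high = cv$ci[2],
    p_value = cv$p_value, n_folds = nrow(cv$scores),
    n_pos = cv$n_pos, n_neg = cv$n_neg,
    empty_fold_fraction = cv$empty_fold_fraction
  ), cv$settings)
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(scores_path)
}

#' Read a run configuration
#'
#' YAML key-value file understood by [run_full()]. Recognised keys:
#' `counts`, `annotation`, `samples` (input paths) or `sim` (a list of
#' [sim_params()] arguments); `comparisons` (list of two-element group
#' vectors; default all six pairwise contrasts); `covariates` (default age,
#' sex, bmi); `alpha` (default 0.05); `auc_threshold` (default 0.7); `seed`.
#'
#' @param path YAML file path.
#' @return A named list with defaults filled in, class `srna_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A named list of configuration values.
#' @export
as_run_config <- function(cfg) {
  defaults <- list(
    comparisons = utils::combn(SRNA_GROUPS, 2, simplify = FALSE),
    covariates = c("age", "sex", "bmi"),
    alpha = 0.05,
    auc_threshold = 0.7,
    seed = 1L
  )
  for (nm in names(cfg)) defaults[[nm]] <- cfg[[nm]]
  cfg <- defaults
  cfg$comparisons <- lapply(cfg$comparisons, as.character)
  for (cmp in cfg$comparisons) {
    if (length(cmp) != 2 || !all(tolower(cmp) %in% tolower(SRNA_GROUPS))) {
      abort(paste0("invalid comparison '", toString(cmp),
                   "'; groups must be two of: ", toString(SRNA_GROUPS)))
    }
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    abort("alpha must lie strictly between 0 and 1")
  }
  structure(cfg, class = "srna_config")
}
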