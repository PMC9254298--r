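#' Assemble and validate a small-RNA count dataset
#'
#' An `srna_dataset` bundles the three tables every stage of the pipeline
#' consumes: a feature-by-sample matrix of raw counts, a feature annotation
#' table (class, isomiR parent, fragment length) and a per-sample clinical
#' table (group, age, sex, BMI, optional diabetes duration and extra numeric
#' covariates). Validation is strict: silent repair of ids, counts or
#' covariates would change the downstream models, so every inconsistency is a
#' hard error naming the offending entry.
#'
#' @param counts Non-negative integer matrix, features in rows (rownames are
#'   feature ids), samples in columns (colnames are sample ids).
#' @param annotation Data frame with columns `feature_id`, `feature_class`
#'   (one of `r paste(SRNA_CLASSES, collapse = ", ")`), `parent_id` (required
#'   for isomiRs, `NA` otherwise) and `fragment_length` (nucleotides, may be
#'   `NA`).
#' @param samples Data frame with columns `sample_id`, `group` (control, T1D,
#'   T2D or LADA, matched case-insensitively), `age` (years), `sex`
#'   (male/female), `bmi` (kg/m^2); optional `duration` (years since
#'   diagnosis) and further numeric covariate columns.
#' @param truth Optional simulation ground-truth table (see
#'   [simulate_srna_dataset()]); `NULL` for real data.
#'
#' @return An object of class `srna_dataset`: a list with elements `counts`,
#'   `annotation` (tibble), `samples` (tibble) and `truth`.
#' @export
#' @examples
#' ds <- make_fixture("small")
#' ds
#' dplyr::count(ds$annotation, feature_class)
srna_dataset <- function(counts, annotation, samples, truth = NULL) {
  counts <- as.matrix(counts)
  annotation <- tibble::as_tibble(annotation)
  samples <- tibble::as_tibble(samples)
  ds <- structure(
    list(counts = counts, annotation = annotation, samples = samples,
         truth = truth),
    class = "srna_dataset"
  )
  validate_srna_dataset(ds)
}

#' Validate an `srna_dataset`
#'
#' Checks every invariant the pipeline relies on: unique matching ids,
#' integral non-negative counts, known feature classes and group labels,
#' isomiR parents that exist and are mature miRNAs, positive fragment
#' lengths, and complete mandatory covariates (age, sex, BMI).
#'
#' @param ds An `srna_dataset`.
#' @return `ds`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_srna_dataset <- function(ds) {
  counts <- ds$counts
  ann <- ds$annotation
  smp <- ds$samples

  fid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(fid) || is.null(sid)) {
    abort("count matrix must carry feature ids as rownames and sample ids as colnames")
  }
  dup <- unique(fid[duplicated(fid)])
  if (length(dup)) abort(paste0("duplicate feature id(s): ", toString(head(dup, 5))))
  dup <- unique(sid[duplicated(sid)])
  if (length(dup)) abort(paste0("duplicate sample id(s): ", toString(head(dup, 5))))

  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "counts must be non-negative integers; first offending cell: feature '%s', sample '%s' (value %s)",
      fid[bad[1, 1]], sid[bad[1, 2]], format(counts[bad[1, , drop = FALSE]])
    ))
  }

  req <- c("feature_id", "feature_class")
  miss <- setdiff(req, names(ann))
  if (length(miss)) abort(paste0("annotation is missing column(s): ", toString(miss)))
  if (!"parent_id" %in% names(ann)) ann$parent_id <- NA_character_
  if (!"fragment_length" %in% names(ann)) ann$fragment_length <- NA_real_

  unknown <- setdiff(ann$feature_class, SRNA_CLASSES)
  if (length(unknown)) {
    abort(paste0("unknown feature_class value(s): ", toString(unknown),
                 "; allowed: ", toString(SRNA_CLASSES)))
  }
  missing_ann <- setdiff(fid, ann$feature_id)
  if (length(missing_ann)) {
    abort(paste0("annotation missing for feature(s): ", toString(head(missing_ann, 5))))
  }
  extra_ann <- setdiff(ann$feature_id, fid)
  if (length(extra_ann)) {
    abort(paste0("annotation row(s) without a count row: ", toString(head(extra_ann, 5))))
  }
  # align annotation to count-matrix order; file order of features is preserved
  ann <- ann[match(fid, ann$feature_id), , drop = FALSE]

  iso <- ann$feature_class == "isomiR"
  if (any(iso & (is.na(ann$parent_id) | ann$parent_id == ""))) {
    abort(paste0("isomiR feature(s) without parent_id: ",
                 toString(head(ann$feature_id[iso & is.na(ann$parent_id)], 5))))
  }
  mature <- ann$feature_id[ann$feature_class == "mature_miRNA"]
  orphan <- setdiff(ann$parent_id[iso], mature)
  if (length(orphan)) {
    abort(paste0("isomiR parent_id(s) not found among mature miRNAs: ",
                 toString(head(orphan, 5))))
  }
  if (any(!is.na(ann$fragment_length) & ann$fragment_length <= 0)) {
    abort("fragment_length must be > 0 where present")
  }

  smp <- normalize_sample_table(smp)
  missing_smp <- setdiff(sid, smp$sample_id)
  if (length(missing_smp)) {
    abort(paste0("sample table missing sample(s): ", toString(head(missing_smp, 5))))
  }
  extra_smp <- setdiff(smp$sample_id, sid)
  if (length(extra_smp)) {
    abort(paste0("sample table row(s) without a count column: ", toString(head(extra_smp, 5))))
  }
  smp <- smp[match(sid, smp$sample_id), , drop = FALSE]

  ds$annotation <- ann
  ds$samples <- smp
  ds
}

# Canonicalize a sample table: group labels case-insensitively mapped to the
# four canonical names, sex to male/female, mandatory covariates complete.
normalize_sample_table <- function(smp) {
  req <- c("sample_id", "group", "age", "sex", "bmi")
  miss <- setdiff(req, names(smp))
  if (length(miss)) abort(paste0("sample table is missing column(s): ", toString(miss)))
  dup <- unique(smp$sample_id[duplicated(smp$sample_id)])
  if (length(dup)) abort(paste0("duplicate sample id(s): ", toString(head(dup, 5))))

  idx <- match(tolower(as.character(smp$group)), tolower(SRNA_GROUPS))
  if (anyNA(idx)) {
    bad <- unique(as.character(smp$group)[is.na(idx)])
    abort(paste0("unknown group label(s): ", toString(bad),
                 "; allowed: ", toString(SRNA_GROUPS)))
  }
  smp$group <- factor(SRNA_GROUPS[idx], levels = SRNA_GROUPS)

  sx <- tolower(as.character(smp$sex))
  sx_idx <- match(sx, c("female", "male"))
  if (anyNA(sx_idx)) {
    abort(paste0("sex must be male or female; offending sample(s): ",
                 toString(head(smp$sample_id[is.na(sx_idx)], 5))))
  }
  smp$sex <- factor(c("female", "male")[sx_idx], levels = c("female", "male"))

  for (v in c("age", "bmi")) {
    x <- smp[[v]]
    if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
      bad <- smp$sample_id[!is.finite(as.numeric(x)) | as.numeric(x) <= 0 | is.na(x)]
      abort(paste0("mandatory covariate '", v, "' must be positive and complete; ",
                   "offending sample(s): ", toString(head(bad, 5)),
                   " (missing covariates are never imputed)"))
    }
  }
  tibble::as_tibble(smp)
}

#' @export
print.srna_dataset <- function(x, ...) {
  cls <- table(x$annotation$feature_class)
  cat("srna_dataset: ", nrow(x$counts), " features x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  feature classes: ",
      paste(names(cls), cls, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  groups: ",
      paste(names(table(x$samples$group)), table(x$samples$group),
            sep = "=", collapse = ", "), "\n", sep = "")
  if (!is.null(x$truth)) {
    cat("  simulation truth: ", dplyr::n_distinct(x$truth$feature_id[x$truth$is_de]),
        " truly differential feature(s)\n", sep = "")
  }
  invisible(x)
}

#' Subset a dataset by feature and/or sample ids, preserving order
#'
#' @param ds An [srna_dataset()].
#' @param features,samples Character vectors of ids to keep (in the given
#'   order); `NULL` keeps everything.
#' @return The subsetted `srna_dataset`.
#' @export
subset_dataset <- function(ds, features = NULL, samples = NULL) {
  if (!is.null(features)) {
    ds$counts <- ds$counts[features, , drop = FALSE]
    ds$annotation <- ds$annotation[match(features, ds$annotation$feature_id), , drop = FALSE]
    if (!is.null(ds$truth)) {
      ds$truth <- ds$truth[ds$truth$feature_id %in% features, , drop = FALSE]
    }
  }
  if (!is.null(samples)) {
    ds$counts <- ds$counts[, samples, drop = FALSE]
    ds$samples <- ds$samples[match(samples, ds$samples$sample_id), , drop = FALSE]
  }
  ds
}

#' Biological (non-calibrator) library size of each sample
#'
#' @param ds An [srna_dataset()].
#' @return Named numeric vector of non-calibrator column sums.
#' @export
biological_libsize <- function(ds) {
  bio <- ds$annotation$feature_class != "calibrator"
  colSums(ds$counts[bio, , drop = FALSE])
}

#' Feature ids of the calibrator spike-ins
#'
#' @param ds An [srna_dataset()].
#' @return Character vector of calibrator feature ids.
#' @export
calibrator_ids <- function(ds) {
  ds$annotation$feature_id[ds$annotation$feature_class == "calibrator"]
}
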