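# Shared fixtures, built once per test run.

small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture("small")
    cache
  }
})

medium_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture("medium")
    cache
  }
})

# Hand-built dataset: n calibrators plus filler biological rows, fully
# controlled counts. `calib` is a calibrator x sample matrix; `bio` a
# biological x sample matrix (rows become class "other").
manual_dataset <- function(calib, bio, groups = NULL) {
  n <- ncol(calib)
  stopifnot(ncol(bio) == n)
  rownames(calib) <- sprintf("CAL-%02d", seq_len(nrow(calib)))
  rownames(bio) <- sprintf("BIO-%02d", seq_len(nrow(bio)))
  counts <- rbind(bio, calib)
  colnames(counts) <- sprintf("S%02d", seq_len(n))
  ann <- tibble::tibble(
    feature_id = rownames(counts),
    feature_class = c(rep("other", nrow(bio)), rep("calibrator", nrow(calib))),
    parent_id = NA_character_, fragment_length = NA_real_
  )
  if (is.null(groups)) groups <- rep(c("control", "T2D"), length.out = n)
  smp <- tibble::tibble(sample_id = colnames(counts), group = groups,
                        age = 40 + (seq_len(n) * 7) %% 23,
                        sex = rep(c("female", "male", "male"), length.out = n),
                        bmi = 22 + (seq_len(n) * 3) %% 9)
  srna_dataset(counts, ann, smp)
}

# Total biological (non-calibrator) reads per sample.
biological_total <- function(ds) {
  colSums(ds$counts[ds$annotation$feature_class != "calibrator", , drop = FALSE])
}

# Restrict a dataset to its biological (non-calibrator) features.
subset_ds_bio <- function(ds) {
  keep <- ds$annotation$feature_id[ds$annotation$feature_class != "calibrator"]
  subset_dataset(ds, features = keep)
}

# Independent brute-force step-up adjustment (kept deliberately naive).
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) min(1, ps[j] * m / j), numeric(1))
    q[i] <- min(cand)
  }
  q[order(o)]
}

# Independent brute-force AUC by concordant-pair counting.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) for (y in neg) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(pos) * length(neg))
}

# Trapezoidal area under an srna_roc curve.
trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}
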