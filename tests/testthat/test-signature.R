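fake_de <- function(feature_id, log2fc, q) {
  structure(tibble::tibble(feature_id = feature_id, log2fc = log2fc,
                           q_value = q),
            comparison = c("control", "T2D"))
}

test_that("signatures keep significant features with their directions", {
  logcpm <- rbind(A = c(1, 2, 3, 4), B = c(5, 5, 6, 6))
  colnames(logcpm) <- paste0("S", 1:4)

  sig <- build_signature(fake_de(c("A", "B"), c(1.2, -0.4), c(0.01, 0.2)), logcpm)
  expect_equal(sig$feature_id, "A")
  expect_equal(sig$direction, 1)
  expect_equal(sig$train_mean, 2.5, ignore_attr = TRUE)
  expect_equal(sig$train_sd, sd(c(1, 2, 3, 4)), ignore_attr = TRUE)

  # all q >= alpha -> legal empty signature
  sig0 <- build_signature(fake_de(c("A", "B"), c(1, 1), c(0.5, 0.9)), logcpm)
  expect_equal(nrow(sig0), 0)

  # negative effects point the direction down
  sigm <- build_signature(fake_de("B", -2, 0.001), logcpm)
  expect_equal(sigm$direction, -1)

  # zero-variance training features are excluded
  logcpm2 <- rbind(A = c(1, 2, 3, 4), B = rep(7, 4))
  colnames(logcpm2) <- paste0("S", 1:4)
  sig2 <- build_signature(fake_de(c("A", "B"), c(1, 2), c(0.01, 0.01)), logcpm2)
  expect_equal(sig2$feature_id, "A")
})

test_that("scores are direction-aligned standardized means", {
  logcpm <- rbind(A = c(0, 2), B = c(4, 6))
  colnames(logcpm) <- c("S1", "S2")
  sig <- tibble::tibble(feature_id = c("A", "B"), direction = c(1, -1),
                        train_mean = c(1, 5), train_sd = c(1, 1))

  # a sample sitting exactly at the training means scores 0
  test1 <- matrix(c(1, 5), 2, dimnames = list(c("A", "B"), "T1"))
  expect_equal(as.vector(score_samples(sig, test1)), 0)

  # standardized values (1, -1) with directions (+1, -1) average to 1
  test2 <- matrix(c(2, 4), 2, dimnames = list(c("A", "B"), "T2"))
  expect_equal(as.vector(score_samples(sig, test2)), 1)

  empty <- sig[0, ]
  sc <- score_samples(empty, test2)
  expect_equal(as.vector(sc), 0)
  expect_true(attr(sc, "empty"))

  expect_error(score_samples(sig, test2[1, , drop = FALSE]), "missing")
})

test_that("ROC curves are monotone, anchored and consistent with the AUC", {
  # perfect separation passes through (0, 1)
  roc <- roc_curve(c(5, 4, 3, 2, 1, 0), c(1, 1, 1, 0, 0, 0))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)

  # all scores tied: the diagonal
  roc0 <- roc_curve(rep(1, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(nrow(roc0), 2)
  expect_equal(trapezoid_area(roc0), 0.5)

  # worked 3v3 instance: area 8/9
  s <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  l <- c(1, 1, 1, 0, 0, 0)
  expect_equal(trapezoid_area(roc_curve(s, l)), 8 / 9, tolerance = 1e-12)

  # AUC = trapezoidal area on random tied instances
  set.seed(23)
  for (r in 1:200) {
    n <- sample(4:30, 1)
    sc <- sample(round(runif(n), 1))  # coarse grid forces ties
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc_mw(sc, lb), trapezoid_area(roc_curve(sc, lb)),
                 tolerance = 1e-12)
    expect_true(all(diff(roc_curve(sc, lb)$fpr) >= 0))
    expect_true(all(diff(roc_curve(sc, lb)$tpr) >= 0))
  }
})

test_that("the AUC estimator matches brute-force pair counting", {
  s <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  l <- c(1, 1, 1, 0, 0, 0)
  expect_equal(auc_mw(s, l), 8 / 9, tolerance = 1e-12)

  set.seed(31)
  for (r in 1:200) {
    n <- sample(4:25, 1)
    sc <- sample(round(runif(n), 1))
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc_mw(sc, lb), auc_brute(sc, lb), tolerance = 1e-12)
    expect_equal(auc_mw(-sc, lb), 1 - auc_mw(sc, lb), tolerance = 1e-12)
  }
  expect_error(auc_mw(1:3, c(1, 1, 1)), "both classes")
})

test_that("DeLong intervals behave at the edges and match pROC", {
  ci <- auc_ci_delong(c(5, 4, 3, 1, 0, -1), c(1, 1, 1, 0, 0, 0))
  expect_equal(as.numeric(ci), c(1, 1))
  expect_true(attr(ci, "flagged"))

  set.seed(41)
  sc <- rnorm(30); lb <- rbinom(30, 1, 0.5)
  lb[1:2] <- c(0, 1)
  ci1 <- auc_ci_delong(sc, lb)
  ci2 <- auc_ci_delong(-sc, lb)
  expect_equal(as.numeric(ci2), 1 - rev(as.numeric(ci1)), tolerance = 1e-12)

  skip_if_not_installed("pROC")
  for (r in 1:20) {
    n <- sample(12:40, 1)
    sc <- rnorm(n) + rbinom(n, 1, 0.5)
    lb <- c(0, 0, 1, 1, rbinom(n - 4, 1, 0.5))
    ours <- auc_ci_delong(sc, lb)
    ref <- suppressMessages(pROC::ci.auc(pROC::roc(lb, sc, quiet = TRUE,
                                                   direction = "<"),
                                         method = "delong"))
    expect_equal(as.numeric(ours), pmin(1, pmax(0, as.numeric(ref[c(1, 3)]))),
                 tolerance = 1e-9)
  }
})

test_that("DeLong intervals agree with a bootstrap oracle", {
  set.seed(53)
  x <- rnorm(20, 1); y <- rnorm(20)
  sc <- c(x, y); lb <- rep(c(1, 0), each = 20)
  ci <- auc_ci_delong(sc, lb)
  boot <- replicate(3000, {
    i <- sample(20, replace = TRUE); j <- sample(20, replace = TRUE)
    auc_mw(c(x[i], y[j]), lb)
  })
  bq <- quantile(boot, c(0.025, 0.975))
  expect_lt(max(abs(as.numeric(ci) - as.numeric(bq))), 0.05)
})

test_that("rank-test p-values match the worked normal approximation", {
  s <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  l <- c(1, 1, 1, 0, 0, 0)
  # U = 8, E[U] = 4.5, Var = 5.25
  expect_equal(auc_pvalue_mw(s, l),
               pnorm((8 - 4.5) / sqrt(5.25), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(auc_pvalue_mw(s, l), 0.0633, tolerance = 1e-3)

  # AUC exactly 0.5 -> z = 0 -> p = 0.5
  expect_equal(auc_pvalue_mw(c(1, 2, 2, 1), c(1, 1, 0, 0)), 0.5)

  # null p-values are roughly uniform (light version; the full check is in
  # the acceptance suite)
  set.seed(61)
  p <- replicate(300, auc_pvalue_mw(rnorm(40), rep(c(0, 1), 20)))
  # the U statistic is discrete, so ties among p-values are expected
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.001)
})

test_that("LOOCV scores a perfectly separating feature at AUC 1", {
  set.seed(71)
  n <- 12
  sep <- rep(c(40, 4000), each = n / 2)
  noise <- matrix(rpois(20 * n, 500), 20, n)
  bio <- rbind(sep, noise)
  calib <- matrix(rpois(10 * n, 800), 10, n)
  ds <- manual_dataset(calib, bio, groups = rep(c("control", "T2D"), each = n / 2))
  cv <- loocv_signature(ds, c("control", "T2D"))
  expect_equal(cv$auc, 1)
  expect_equal(cv$empty_fold_fraction, 0)
  expect_true(all(cv$scores$signature_size >= 1))
  expect_lt(cv$p_value, 0.01)
  expect_equal(cv$ci, c(1, 1))
})

test_that("LOOCV is deterministic and keeps one score per sample", {
  ds <- small_fixture()
  cv1 <- loocv_signature(ds, c("control", "T2D"), alpha = 0.5)
  cv2 <- loocv_signature(ds, c("control", "T2D"), alpha = 0.5)
  expect_identical(cv1$scores$score, cv2$scores$score)
  expect_identical(cv1$auc, cv2$auc)
  expect_equal(nrow(cv1$scores), 10)
  expect_setequal(cv1$scores$sample_id,
                  ds$samples$sample_id[ds$samples$group %in% c("control", "T2D")])
  # the ROC orientation is fixed: second-named group is the positive class
  expect_equal(cv1$scores$label,
               as.integer(cv1$scores$group == "T2D"))
})

test_that("the logistic predictor mode runs and ranks the separating feature", {
  set.seed(72)
  n <- 12
  sep <- rep(c(40, 4000), each = n / 2)
  noise <- matrix(rpois(10 * n, 500), 10, n)
  ds <- manual_dataset(matrix(rpois(10 * n, 800), 10, n), rbind(sep, noise),
                       groups = rep(c("control", "T2D"), each = n / 2))
  cv <- loocv_signature(ds, c("control", "T2D"), predictor = "logistic")
  expect_equal(cv$auc, 1)
  expect_equal(cv$settings$predictor, "logistic")
})
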