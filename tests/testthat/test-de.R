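# Dataset with one controlled biological feature at known cpm plus filler so
# every biological column sums to `lib` (default 1e7 -> counts are cpm * 10).
cpm_probe_dataset <- function(probe_counts, lib = 1e7) {
  n <- length(probe_counts)
  bio <- rbind(probe = probe_counts, filler = lib - probe_counts)
  calib <- matrix(rep(c(100, 200, 400), n), ncol = n)
  ds <- manual_dataset(calib, bio)
  ds
}

test_that("the expression filter applies the inclusive cpm boundary per rule", {
  # cpm (1.2, 1.5, 0.8, 2.0): fails all-samples, passes 50%-of-samples
  ds <- cpm_probe_dataset(c(12, 15, 8, 20))
  kept_all <- filter_features(ds, rule = "all_samples")
  kept_frac <- filter_features(ds, rule = "frac50")
  expect_false("BIO-01" %in% rownames(kept_all$counts))
  expect_true("BIO-01" %in% rownames(kept_frac$counts))

  # exactly 1 cpm everywhere is kept: "at least" is inclusive
  ds1 <- cpm_probe_dataset(c(10, 10, 10, 10))
  expect_true("BIO-01" %in% rownames(filter_features(ds1, rule = "all_samples")$counts))

  # an all-zero feature is dropped under both rules
  ds0 <- cpm_probe_dataset(c(0, 0, 0, 0))
  expect_false("BIO-01" %in% rownames(filter_features(ds0, rule = "frac50")$counts))

  # calibrators never survive filtering
  expect_false(any(grepl("^CAL", rownames(kept_frac$counts))))
})

test_that("design matrices follow the treatment-coding contract", {
  smp4 <- tibble::tibble(sample_id = paste0("S", 1:4),
                         group = c("control", "control", "T2D", "T2D"),
                         age = c(50, 60, 55, 65),
                         sex = c("female", "male", "female", "male"),
                         bmi = c(25, 27, 30, 31))
  X <- build_design(smp4, c("control", "T2D"), covariates = character(0))
  expect_equal(unname(X), cbind(1, c(0, 0, 1, 1)), ignore_attr = TRUE)
  expect_equal(attr(X, "coef"), "groupT2D")

  smp <- tibble::tibble(sample_id = paste0("S", 1:6),
                        group = rep(c("control", "T2D"), each = 3),
                        age = c(50, 60, 47, 55, 65, 71),
                        sex = c("female", "male", "male",
                                "female", "male", "female"),
                        bmi = c(25, 27, 24, 30, 31, 28))
  X5 <- build_design(smp, c("control", "T2D"))
  expect_equal(dim(X5), c(6, 5))
  expect_equal(unname(X5[, "sex"]), c(0, 1, 1, 0, 1, 0))  # female = 0, male = 1
  expect_equal(qr(X5)$rank, 5)

  # a requested covariate missing for one sample is a hard error
  smp$duration <- c(NA, NA, NA, 4.5, 10, 2)
  expect_error(build_design(smp, c("control", "T2D"),
                            covariates = c("age", "duration")),
               "duration")

  # constant columns are reported as rank deficiency
  smp$flat <- 1
  expect_error(build_design(smp, c("control", "T2D"),
                            covariates = c("flat")), "flat")
})

test_that("fragment-length abundance covariate uses the closed range", {
  counts <- rbind(t30 = c(10, 3), t33 = c(20, 5), t29 = c(7, 11),
                  CALX = c(50, 50))
  colnames(counts) <- c("S01", "S02")
  ann <- tibble::tibble(
    feature_id = rownames(counts),
    feature_class = c("tRNA", "tRNA", "tRNA", "calibrator"),
    parent_id = NA_character_,
    fragment_length = c(30, 33, 29, NA)
  )
  smp <- tibble::tibble(sample_id = colnames(counts),
                        group = c("control", "T2D"), age = c(50, 60),
                        sex = c("female", "male"), bmi = c(25, 30))
  ds <- srna_dataset(counts, ann, smp)
  v <- length_abundance_covariate(ds, c(30, 33))
  expect_equal(unname(v), c(log2(31), log2(9)))  # length-29 contributes nothing

  ds0 <- ds
  ds0$counts[c("t30", "t33"), "S02"] <- 0
  expect_equal(unname(length_abundance_covariate(ds0)[2]), 0)  # log2(1 + 0)

  expect_error(length_abundance_covariate(ds, c(40, 45)), "no feature")
})

test_that("precision weights are flat for homoskedastic log-counts and track
          an injected mean-variance trend", {
  set.seed(77)
  n <- 20; g <- 200
  mk <- function(sd_fun) {
    fm <- runif(g, 6, 12)
    logc <- sapply(seq_len(n), function(j) fm + rnorm(g, 0, sd_fun(fm)))
    counts <- round(2^logc)
    rownames(counts) <- sprintf("F%03d", seq_len(g))
    colnames(counts) <- sprintf("S%02d", seq_len(n))
    ann <- tibble::tibble(feature_id = rownames(counts),
                          feature_class = "other",
                          parent_id = NA_character_,
                          fragment_length = NA_real_)
    smp <- tibble::tibble(sample_id = colnames(counts),
                          group = rep(c("control", "T2D"), each = n / 2),
                          age = runif(n, 40, 70),
                          sex = sample(c("male", "female"), n, TRUE),
                          bmi = runif(n, 22, 33))
    srna_dataset(counts, ann, smp)
  }

  ds_hom <- mk(function(m) 0.3)
  X <- build_design(ds_hom$samples, c("control", "T2D"), covariates = character(0))
  vf <- voom_fit(ds_hom, X)
  expect_lt(sd(vf$weights) / mean(vf$weights), 0.15)

  # noisier at low counts -> weights increase with abundance
  ds_het <- mk(function(m) 1.3 - 0.1 * m)
  vf2 <- voom_fit(ds_het, X)
  expect_gt(cor(rowMeans(vf2$E), rowMeans(vf2$weights), method = "spearman"), 0.5)

  # rescaling all weights leaves moderated t-statistics unchanged
  de1 <- fit_moderated(vf2)
  vf3 <- vf2
  vf3$weights <- vf2$weights * 7.3
  de2 <- fit_moderated(vf3)
  expect_equal(de2$t, de1$t, tolerance = 1e-10)
})

# Hand-built precision-weighted fit over a 6-sample two-group instance.
toy_voom <- function(E, design, weights = 1) {
  structure(list(E = E,
                 weights = matrix(weights, nrow(E), ncol(E)),
                 trend = tibble::tibble(x = 0, y = 1),
                 design = design,
                 lib_size = setNames(rep(1e6, ncol(E)), colnames(E)),
                 feature_id = rownames(E)),
            class = "srna_voom")
}

test_that("with no moderation the statistic is the classical pooled t", {
  set.seed(5)
  E <- matrix(rnorm(8 * 6, mean = 8), 8, 6,
              dimnames = list(paste0("F", 1:8), paste0("S", 1:6)))
  X <- cbind(`(Intercept)` = 1, groupT2D = rep(c(0, 1), each = 3))
  attr(X, "coef") <- "groupT2D"
  de <- fit_moderated(toy_voom(E, X), prior_df = 0)

  for (i in 1:8) {
    a <- E[i, 1:3]; b <- E[i, 4:6]
    sp2 <- (2 * var(a) + 2 * var(b)) / 4
    tcl <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / 3 + 1 / 3))
    expect_equal(de$log2fc[i], mean(b) - mean(a), tolerance = 1e-10)
    expect_equal(de$t[i], tcl, tolerance = 1e-10)
    expect_equal(de$p_value[i], 2 * pt(-abs(tcl), df = 4), tolerance = 1e-10)
  }
})

test_that("infinite prior df collapses every posterior variance to s0^2", {
  set.seed(6)
  E <- matrix(rnorm(30 * 8, mean = 8), 30, 8,
              dimnames = list(paste0("F", 1:30), paste0("S", 1:8)))
  X <- cbind(`(Intercept)` = 1, groupT2D = rep(c(0, 1), each = 4))
  attr(X, "coef") <- "groupT2D"
  de_inf <- fit_moderated(toy_voom(E, X), prior_df = Inf)
  expect_equal(attr(de_inf, "df_prior"), Inf)
  expect_true(is.infinite(unique(de_inf$df_total)))
  # all features share one variance: t / log2fc ratio constant across features
  # with equal unscaled SEs
  ratio <- de_inf$t / de_inf$log2fc
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-10)
})

test_that("moderation hyper-parameters and p-values match the independent
          limma route", {
  skip_if_not_installed("limma")
  ds <- medium_fixture()
  f <- calibrator_norm_factors(ds)
  lib <- biological_libsize(ds)
  design <- build_design(ds$samples, c("control", "T2D"))
  sub <- subset_dataset(ds, samples = attr(design, "sample_id"))
  filt <- filter_features(sub, f, "frac50", lib_size = lib)
  vf <- voom_fit(filt, design, f, lib_size = lib)
  de <- fit_moderated(vf)

  fv <- srnasig:::norm_factor_vector(f, attr(design, "sample_id"))
  v <- limma::voom(filt$counts, design,
                   lib.size = lib[attr(design, "sample_id")] * fv)
  fit <- limma::eBayes(limma::lmFit(v, design))
  tt <- limma::topTable(fit, coef = "groupT2D", number = Inf, sort.by = "none")
  expect_equal(max(abs(vf$weights / v$weights - 1)), 0, tolerance = 1e-10)
  expect_equal(de$log2fc, tt$logFC, tolerance = 1e-10)
  expect_equal(de$p_value, tt$P.Value, tolerance = 1e-10)
  expect_equal(attr(de, "df_prior"), fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(de, "s2_prior"), fit$s2.prior, tolerance = 1e-8)
})

test_that("step-up adjustment matches the worked examples and brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, -0.1)), "0, 1")

  set.seed(19)
  for (r in 1:50) {
    m <- sample(1:40, 1)
    p <- round(runif(m), 3)  # ties included
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-14)
    expect_identical(q, p.adjust(p, "BH"))
    expect_true(all(q >= p))
  }
})

test_that("the group screen reproduces the hand-derived one-way ANOVA", {
  smp <- tibble::tibble(sample_id = paste0("S", 1:6),
                        group = rep(c("control", "T2D"), each = 3),
                        age = 50, sex = "female", bmi = 25,
                        v = c(1, 2, 3, 4, 5, 6),
                        w = c(1, 2, 3, 1, 2, 3))
  scr <- anova_screen(smp, c("v", "w"))
  # SSB = 13.5, MSW = 1 -> F(1,4) = 13.5
  expect_equal(scr$statistic[1], 13.5, tolerance = 1e-12)
  expect_equal(scr$df1[1], 1)
  expect_equal(scr$df2[1], 4)
  expect_equal(scr$p_value[1], pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical group distributions: F = 0, p = 1
  expect_equal(scr$statistic[2], 0, tolerance = 1e-12)
  expect_equal(scr$p_value[2], 1, tolerance = 1e-12)
  # Bonferroni multiplies by the number of variables screened together
  expect_equal(scr$p_bonferroni, pmin(1, scr$p_value * 2))

  smp$z <- rep(5, 6)
  scr0 <- anova_screen(smp, c("z", "v", "w"))
  expect_true(is.na(scr0$statistic[1]))
  expect_equal(scr0$p_bonferroni[2], pmin(1, scr0$p_value[2] * 3))
})

test_that("adjusting for a confounded covariate removes its false positives", {
  # ages differ by group and drive expression of a feature subset; no true
  # group effects exist
  mk <- function(seed) simulate_srna_dataset(sim_params(
    seed = seed, n_per_group = 20, groups = c("control", "LADA"),
    n_mature = 30, isomirs_per_mirna = 2, n_other = 60,
    frac_de = 0, covariate_effects = list(age = 0.06), confounded_age = TRUE))
  hits <- vapply(1:4, function(r) {
    ds <- mk(4000 + r)
    adj <- de_analysis(ds, c("control", "LADA"))
    raw <- de_analysis(ds, c("control", "LADA"), covariates = character(0))
    c(adj = sum(adj$q_value < 0.05), raw = sum(raw$q_value < 0.05))
  }, c(adj = 0, raw = 0))
  expect_lt(sum(hits["adj", ]), sum(hits["raw", ]))
  expect_gt(sum(hits["raw", ]), 0)
})
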