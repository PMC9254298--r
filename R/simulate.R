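#' Simulation parameters for synthetic small-RNA-seq datasets
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' negative-binomial counts (variance \eqn{\mu + \phi\mu^2}) with per-sample
#' depth variation, a per-sample technical yield factor that multiplies the
#' biological signal only, spike-in calibrators that track true input (and so
#' measure the technical factor), isomiRs as the primitive unit with each
#' mature miRNA the exact sum of its isomiRs, sparse group effects of a fixed
#' log2 fold-change, and clinical covariates (age, sex, BMI, duration) drawn
#' on realistic scales.
#'
#' @param seed Integer RNG seed; the same seed reproduces the dataset bit for
#'   bit.
#' @param n_per_group Samples per clinical group (default 50, the size the
#'   study design was powered for).
#' @param groups Which of control/T1D/T2D/LADA to simulate (default all four).
#' @param n_mature Number of mature miRNAs; each contributes
#'   `isomirs_per_mirna` isomiR rows plus one derived mature row.
#' @param isomirs_per_mirna IsomiRs per mature miRNA (>= 1).
#' @param n_other Number of other small RNAs (tRNA fragments, Y-RNAs, ...).
#' @param n_calibrators Number of spike-in calibrator RNAs (default 10).
#' @param frac_de Fraction of mature miRNAs and of other sRNAs carrying a true
#'   group effect (calibrators never do).
#' @param logfc Magnitude of the true log2 fold-change (default
#'   `log2(1.5) = 0.585`, the minimum fold change of the study's power
#'   calculation).
#' @param de_group Group in which true effects are expressed; `NULL` (default)
#'   picks a group at random per affected feature.
#' @param dispersion Negative-binomial dispersion `phi` of the biological
#'   features (variance `mu + phi mu^2`); 0 gives Poisson counts.
#' @param calib_dispersion Dispersion of the calibrator counts (default
#'   0.01): spike-ins are added in fixed known amounts, so their counts vary
#'   technically (near-Poisson) rather than biologically.
#' @param depth_mean,depth_cv Mean and coefficient of variation of the
#'   log-normal library-size distribution (default 1e6 reads, CV 0.3).
#' @param calib_frac Expected fraction of each library made of calibrator
#'   reads (default 0.02).
#' @param tech_sd Standard deviation (log2 scale) of the per-sample technical
#'   yield factor applied to biological features only (default 0.3).
#' @param covariate_effects Named list of per-unit log2 effects for `age`,
#'   `sex`, `bmi`, each applied to a random 10% feature subset; default all
#'   zero (no covariate signal).
#' @param confounded_age If `TRUE`, ages are drawn with the group-specific
#'   means seen in adult diabetes cohorts (controls younger than T2D/LADA) so
#'   tests can demonstrate the value of covariate adjustment; default `FALSE`
#'   (ages exchangeable across groups).
#'
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_per_group = 50L,
                       groups = SRNA_GROUPS,
                       n_mature = 100L,
                       isomirs_per_mirna = 3L,
                       n_other = 190L,
                       n_calibrators = 10L,
                       frac_de = 0.1,
                       logfc = log2(1.5),
                       de_group = NULL,
                       dispersion = 0.1,
                       calib_dispersion = 0.01,
                       depth_mean = 1e6,
                       depth_cv = 0.3,
                       calib_frac = 0.02,
                       tech_sd = 0.3,
                       covariate_effects = list(age = 0, sex = 0, bmi = 0),
                       confounded_age = FALSE) {
  p <- as.list(environment())
  p$groups <- match.arg(as.character(groups), SRNA_GROUPS, several.ok = TRUE)
  if (!is.null(de_group)) p$de_group <- match.arg(de_group, p$groups)
  if (p$frac_de < 0 || p$frac_de > 1) abort("frac_de must lie in [0, 1]")
  if (p$dispersion < 0 || p$calib_dispersion < 0) abort("dispersion must be >= 0")
  if (p$depth_mean <= 0) abort("depth_mean must be > 0")
  if (p$n_per_group < 3) abort("n_per_group must be >= 3")
  if (p$isomirs_per_mirna < 1) abort("isomirs_per_mirna must be >= 1")
  if (p$calib_frac <= 0 || p$calib_frac >= 1) abort("calib_frac must lie in (0, 1)")
  p$covariate_effects <- modifyList(list(age = 0, sex = 0, bmi = 0),
                                    as.list(covariate_effects))
  structure(p, class = "sim_params")
}

# NB draw with variance mu + phi mu^2; phi = 0 falls back to Poisson.
rnb <- function(n, mu, phi) {
  if (phi <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate a small-RNA-seq dataset with known ground truth
#'
#' See [sim_params()] for the generative model. IsomiRs and other sRNAs are
#' the simulated primitives; each mature miRNA row is set to the exact sum of
#' its isomiR rows, mirroring how mature counts arise from isomiR counts.
#' Calibrator means are proportional to `calib_frac * depth` and do not carry
#' the technical yield factor, so the spike-ins measure it. The returned
#' `truth` table lists, per non-calibrator feature and pairwise contrast, the
#' true log2 fold-change (second group vs first) and a DE flag.
#'
#' @param params A [sim_params()] object.
#' @return An [srna_dataset()] with a populated `truth` tibble.
#' @export
#' @examples
#' ds <- simulate_srna_dataset(sim_params(seed = 7, n_per_group = 5,
#'                                        n_mature = 10, n_other = 15))
#' ds
simulate_srna_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)

  groups <- p$groups
  n_samples <- p$n_per_group * length(groups)
  sample_id <- sprintf("S%03d", seq_len(n_samples))
  group <- factor(rep(groups, each = p$n_per_group), levels = SRNA_GROUPS)
  group <- droplevels(group)

  ## ---- clinical covariates (scales follow adult diabetes cohorts) ----
  if (p$confounded_age) {
    age_mean <- c(control = 52.8, T2D = 63.7, LADA = 67.9, T1D = 59.8)
    age_sd <- c(control = 15.7, T2D = 11.2, LADA = 9.3, T1D = 11.8)
    age <- rnorm(n_samples, age_mean[as.character(group)], age_sd[as.character(group)])
  } else {
    age <- rnorm(n_samples, 61, 12)
  }
  age <- pmax(age, 20)
  sex <- factor(ifelse(runif(n_samples) < 0.52, "male", "female"),
                levels = c("female", "male"))
  bmi <- pmax(rnorm(n_samples, 28.7, 4.4), 16)
  duration <- ifelse(group == "control", NA_real_,
                     round(exp(rnorm(n_samples, log(9), 0.7)), 1))
  samples <- tibble::tibble(sample_id, group, age = round(age, 1), sex,
                            bmi = round(bmi, 1), duration)

  ## ---- feature table ----
  mature_id <- sprintf("miR-%03d", seq_len(p$n_mature))
  iso_id <- as.vector(t(outer(mature_id, seq_len(p$isomirs_per_mirna),
                              function(m, k) paste0(m, ".iso", k))))
  iso_parent <- rep(mature_id, each = p$isomirs_per_mirna)
  other_classes <- sample(c("tRNA", "yRNA", "snRNA", "lncRNA", "antisense", "other"),
                          p$n_other, replace = TRUE,
                          prob = c(0.45, 0.15, 0.1, 0.1, 0.1, 0.1))
  other_id <- sprintf("sRNA-%03d", seq_len(p$n_other))
  calib_id <- sprintf("CAL-%02d", seq_len(p$n_calibrators))

  frag_len <- rep(NA_real_, p$n_other)
  frag_len[other_classes == "tRNA"] <- sample(28:36, sum(other_classes == "tRNA"),
                                              replace = TRUE)

  annotation <- tibble::tibble(
    feature_id = c(mature_id, iso_id, other_id, calib_id),
    feature_class = c(rep("mature_miRNA", p$n_mature),
                      rep("isomiR", length(iso_id)),
                      other_classes,
                      rep("calibrator", p$n_calibrators)),
    parent_id = c(rep(NA_character_, p$n_mature), iso_parent,
                  rep(NA_character_, p$n_other + p$n_calibrators)),
    fragment_length = c(rep(NA_real_, p$n_mature + length(iso_id)), frag_len,
                        rep(NA_real_, p$n_calibrators))
  )

  ## ---- baseline abundances (long-tailed) for the simulated primitives ----
  prim_id <- c(iso_id, other_id)
  base_log2 <- rnorm(length(prim_id), mean = 0, sd = 2)
  rel <- 2^base_log2
  rel <- rel / sum(rel)                       # biological composition

  ## ---- true group effects ----
  n_de_mature <- round(p$frac_de * p$n_mature)
  n_de_other <- round(p$frac_de * p$n_other)
  de_mature <- sample(mature_id, n_de_mature)
  de_other <- sample(other_id, n_de_other)
  # all isomiRs of an affected mature miRNA shift together, so the derived
  # mature row carries exactly the same log2 fold-change
  effect <- setNames(numeric(length(prim_id)), prim_id)
  target <- setNames(character(0), character(0))
  affected <- c(de_mature, de_other)
  if (length(affected)) {
    tg <- if (is.null(p$de_group)) sample(groups, length(affected), replace = TRUE)
          else rep(p$de_group, length(affected))
    sgn <- sample(c(-1, 1), length(affected), replace = TRUE)
    target <- setNames(tg, affected)
    eff_by_feature <- setNames(sgn * p$logfc, affected)
    for (m in de_mature) {
      effect[iso_id[iso_parent == m]] <- eff_by_feature[[m]]
    }
    effect[de_other] <- eff_by_feature[de_other]
  }

  ## ---- covariate effect features ----
  cov_eff <- p$covariate_effects
  cov_beta <- matrix(0, length(prim_id), 3,
                     dimnames = list(prim_id, c("age", "sex", "bmi")))
  for (v in c("age", "sex", "bmi")) {
    if (cov_eff[[v]] != 0) {
      hit <- sample(seq_along(prim_id), max(1, round(0.1 * length(prim_id))))
      cov_beta[hit, v] <- cov_eff[[v]]
    }
  }
  xcov <- cbind(age = age - mean(age),
                sex = as.numeric(sex == "male") - mean(sex == "male"),
                bmi = bmi - mean(bmi))

  ## ---- per-sample technical structure ----
  sdlog <- sqrt(log(1 + p$depth_cv^2))
  depth <- exp(rnorm(n_samples, log(p$depth_mean) - sdlog^2 / 2, sdlog))
  tech <- 2^rnorm(n_samples, 0, p$tech_sd)    # biological yield, log2-normal

  ## ---- biological primitive counts ----
  # log2 mu = baseline + group effect + covariate effects + depth + tech
  grp_chr <- as.character(group)
  eff_mat <- matrix(0, length(prim_id), n_samples,
                    dimnames = list(prim_id, NULL))
  if (length(affected)) {
    for (f in names(effect)[effect != 0]) {
      tgt <- target[[if (f %in% iso_id) iso_parent[match(f, iso_id)] else f]]
      eff_mat[f, grp_chr == tgt] <- effect[[f]]
    }
  }
  log2mu <- log2(rel) + eff_mat + cov_beta %*% t(xcov) +
    matrix(log2(depth * (1 - p$calib_frac) * tech), length(prim_id), n_samples,
           byrow = TRUE)
  mu <- 2^log2mu
  prim_counts <- matrix(rnb(length(mu), mu, p$dispersion),
                        nrow = length(prim_id),
                        dimnames = list(prim_id, sample_id))

  ## ---- derived mature rows and calibrators ----
  mature_counts <- rowsum(prim_counts[iso_id, , drop = FALSE], iso_parent,
                          reorder = FALSE)
  mature_counts <- mature_counts[mature_id, , drop = FALSE]

  calib_rel <- 2^rnorm(p$n_calibrators, 0, 0.5)
  calib_rel <- calib_rel / sum(calib_rel)
  calib_mu <- outer(calib_rel, depth * p$calib_frac)   # no tech factor
  calib_counts <- matrix(rnb(length(calib_mu), calib_mu, p$calib_dispersion),
                         nrow = p$n_calibrators,
                         dimnames = list(calib_id, sample_id))

  counts <- rbind(mature_counts,
                  prim_counts[iso_id, , drop = FALSE],
                  prim_counts[other_id, , drop = FALSE],
                  calib_counts)

  ## ---- ground truth per pairwise contrast ----
  all_bio <- c(mature_id, iso_id, other_id)
  tgt_of <- function(f) {
    base <- if (f %in% iso_id) iso_parent[match(f, iso_id)] else f
    if (base %in% names(target)) target[[base]] else NA_character_
  }
  lfc_of <- function(f) {
    if (f %in% mature_id) {
      k <- which(iso_parent == f)[1]
      effect[[iso_id[k]]]
    } else if (f %in% prim_id) effect[[f]] else 0
  }
  contrasts <- utils::combn(groups, 2, simplify = FALSE)
  truth <- purrr::map_dfr(contrasts, function(cmp) {
    lfc <- vapply(all_bio, function(f) {
      e <- lfc_of(f); if (e == 0) return(0)
      tgt <- tgt_of(f)
      if (is.na(tgt) || !tgt %in% cmp) return(0)
      # second-vs-first convention: effect expressed in the target group
      if (tgt == cmp[2]) e else -e
    }, numeric(1))
    tibble::tibble(feature_id = all_bio,
                   contrast = paste(cmp[1], cmp[2], sep = "_vs_"),
                   true_log2fc = lfc, is_de = lfc != 0)
  })

  ds <- srna_dataset(counts, annotation, samples, truth = truth)
  attr(ds, "sim") <- list(params = p, depth = setNames(depth, sample_id),
                          tech_log2 = setNames(log2(tech), sample_id))
  ds
}

#' Canned fixed-seed fixtures used throughout the test-suite
#'
#' `"small"` gives 4 groups x 5 samples and 60 features (10 mature miRNAs,
#' 20 isomiRs, 20 other sRNAs, 10 calibrators); `"medium"` gives
#' 4 groups x 50 samples and 600 features. Both are deterministic.
#'
#' @param name `"small"` or `"medium"`.
#' @param ... Overrides passed on to [sim_params()] (e.g. `frac_de`, `logfc`).
#' @return An [srna_dataset()].
#' @export
make_fixture <- function(name = c("small", "medium"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    small = list(seed = 101L, n_per_group = 5L, n_mature = 10L,
                 isomirs_per_mirna = 2L, n_other = 20L, n_calibrators = 10L),
    medium = list(seed = 202L, n_per_group = 50L, n_mature = 100L,
                  isomirs_per_mirna = 3L, n_other = 190L, n_calibrators = 10L)
  )
  args <- modifyList(base, list(...))
  simulate_srna_dataset(do.call(sim_params, args))
}
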