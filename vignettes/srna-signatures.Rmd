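---
title: "Methods: spike-in normalization, moderated differential expression and cross-validated small-RNA signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in normalization, moderated differential expression and cross-validated small-RNA signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnasig)
```

`srnasig` analyses serum small-RNA sequencing data to find RNAs whose
circulating levels separate clinical groups — its motivating use case is
distinguishing subgroups of diabetes (type 1, type 2, LADA) from each other
and from non-diabetic controls. This vignette is the package's account of
the statistics it implements: the models, their assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## Why spike-in calibrators, and what the factors mean

Serum small-RNA libraries suffer sample-to-sample variation in RNA recovery
and ligation efficiency that is purely technical. Because every biological
feature in a sample is multiplied by roughly the same yield factor, this
variation is invisible to composition-based normalization: the proportions
of biological reads are unchanged. Calibrators break this degeneracy. A
fixed amount of each of ten synthetic RNAs is added to every sample before
library preparation, so the *ratio of calibrator reads to biological reads*
moves inversely with the sample's biological yield.

`calibrator_norm_factors()` runs the trimmed-mean-of-M-values procedure on
the calibrator submatrix, with one deliberate choice: calibrator
proportions are taken relative to the **biological** (non-calibrator)
library size. Under this convention a sample with poor biological recovery
shows inflated calibrator proportions and receives a smaller factor, so the
effective library size (biological column sum × factor) tracks true RNA
input. This is the only reading under which the spike-ins measure what they
were added to measure; normalizing calibrators against calibrator-inclusive
totals would partially cancel the signal. Calibrator counts are excluded
from biological library sizes throughout.

The TMM tuning constants are the conventional defaults — 30% two-sided trim
on M-values, 5% on A-values, delta-method precision weights, reference
sample chosen by the upper-quartile rule — and factors are rescaled to
geometric mean 1. Two exact properties pin the implementation down:
identical columns give factors of exactly 1, and uniformly doubling one
sample's calibrators at equal biological library sizes gives the
closed-form pair (2^-1/2, 2^1/2). On simulated data with a log2-normal
technical factor (sd 0.3, 200 samples, 10 calibrators) the estimated log2
factors recover the simulated ones with RMSE below 0.1 when the biological
dispersion is moderate (φ ≲ 0.05); at φ = 0.1 the correlation stays above
0.9 but random composition noise in the biological library sums inflates
the RMSE — a genuine limit of spike-in normalization, not of the estimator.

## The differential-expression model

Counts are transformed to log2-cpm with prior count 0.5 against effective
library size + 1 — exactly the transform whose variance the precision
weights model. Each feature is then fit by weighted least squares on a
design holding an intercept, a treatment-coded group indicator (the
second-named group of a comparison is coded 1, so reported log2
fold-changes are second vs first), and the clinical covariates age, sex
(female = 0, male = 1; the group contrast is invariant to this arbitrary
but fixed coding) and BMI. Missing mandatory covariates are a hard error:
silently dropping or imputing them would change the adjustment, and the
models adjust for all three in every contrast. Additional per-sample
covariates plug into the same mechanism — diabetes duration for
within-diabetes sensitivity analyses, or `length_abundance_covariate()`,
the log2(1 + total count) of fragments 30–33 nt long, used to check whether
apparent tRNA-fragment differences merely track library length composition
(log2(1+x) rather than raw counts, for symmetry with everything else the
model sees; the choice is recorded in the result metadata).

Weights follow the mean–variance modelling approach of the limma-voom
family, implemented in-package: per-feature OLS residual standard
deviations on the log2-cpm scale are square-rooted, regressed by lowess
(span 0.5) on average log2 count, and each observation's weight is the
trend value at its fitted log2 count to the power −4, with flat
extrapolation beyond the trend's support. Empirical Bayes moderation then
shrinks residual variances toward a common prior: the prior degrees of
freedom d0 and prior variance s0² are estimated by matching the mean and
variance of log s² to a scaled-F model via closed-form trigamma inversion
(Newton iteration, relative tolerance 1e-8; d0 above 1e7 is reported as
infinite, which is also the degenerate answer when the spread of log s² is
no larger than its sampling variance). The moderated t uses posterior
variance (d0·s0² + d·s²)/(d0 + d) on d0 + d degrees of freedom. Two limits
anchor the implementation: at d0 = 0 it reproduces the classical pooled
two-sample t exactly, and as d0 → ∞ all posterior variances collapse to
s0². On shared fixtures the whole chain (weights, coefficients, moderation
hyper-parameters, p-values) agrees with the independent limma route to
10 significant digits in the test suite.

Expression filters are class-specific, mirroring the biology: mature
miRNAs must reach ≥ 1 cpm in *all* samples; isomiRs and other sRNAs — by
construction less abundant, since a mature miRNA's count is the sum of its
isomiRs' — must reach ≥ 1 cpm in at least half. Both boundaries are
inclusive ("at least 1 cpm"). Filtering uses calibrator-effective library
sizes and happens after factor computation but before weight estimation,
the standard order; when the pipeline analyses one feature class at a time
it keeps cpm in whole-library units by passing the full biological library
sizes through. Multiple testing is controlled per contrast by
Benjamini–Hochberg step-up, implemented directly and tested against a
brute-force evaluation of the step-up definition. The clinical screen that
accompanies such analyses — per-variable one-way ANOVA across the four
groups with Bonferroni correction over the variables screened together —
is `anova_screen()`.

The pipeline refits the model per pairwise comparison (designs contain only
the two compared groups) rather than fitting all four groups once; the
alternative pools variance across groups not under comparison and was
rejected to keep each contrast self-contained.

## Signatures and nested leave-one-out cross-validation

A signature is the set of features significant at q < α for a contrast,
each carrying the *sign* of its training fold-change and the mean/sd of its
training log2-cpm. A sample is scored by the direction-aligned standardized
mean of its signature features. This predictor was chosen deliberately:
it is parameter-free, monotone in every selected feature, and fits folds
with a handful of training samples without tuning. A logistic-regression
mode over the same standardized features is available behind
`predictor = "logistic"` for comparison; out-of-fold results are not
expected to match any particular external classifier numerically.

Validation is leave-one-out with feature selection nested inside every
fold: filter, weights, moderated tests, BH adjustment and signature
construction all see only the training samples. Normalization factors are
the one global quantity — they are per-sample technical measurements
derived from spike-ins without access to group labels, so computing them
once leaks nothing. Each sample's log2-cpm likewise depends only on its own
counts and factor. Empty-signature folds score the held-out sample 0 (the
class-ambiguous value) and are counted, preserving exactly one score per
sample; the empty-fold fraction is reported. The ROC orientation is fixed —
higher score predicts the second-named group — and AUCs below 0.5 are
reported as-is, since the direction is determined by training fold-change
signs, never flipped post hoc.

Out-of-fold scores are summarised by the Mann–Whitney AUC (mid-rank tie
handling), a DeLong structural-components 95% Wald interval truncated to
[0, 1] (degenerating, flagged, to a point at perfect separation), and a
one-sided tie-corrected normal-approximation rank-test p-value for
AUC > 0.5 (one-sided to match the convention of the rank-test functions
this workflow conventionally reports).

The value of nesting is demonstrated, not asserted: on global-null
simulations the nested procedure's mean AUC stays in [0.45, 0.55], while
deliberately selecting features once on all samples (`nested = FALSE`)
inflates it. The demonstration uses a liberal selection threshold
(α = 0.5), because under a global null BH selection at α = 0.05 fires so
rarely that both modes degenerate to all-tied scores; with selection
actually firing, the bias of the non-nested mode is visible (≈ +0.1 AUC in
the acceptance run) and the nested mode stays calibrated.

## What the generator emulates — and what it does not

`simulate_srna_dataset()` produces the structure the analysis assumes:
four groups of 50 samples by default (the design size the motivating
studies power for); negative-binomial counts with variance μ + φμ²
(edgeR-style common dispersion, default φ = 0.1, the regime the
mean–variance weighting is designed for); log-normal library sizes (mean
1e6, CV 0.3); a log2-normal technical yield factor (sd 0.3) multiplying
biological features only; calibrators at 2% of the library whose means
track true input and whose dispersion is low (φ = 0.01) because spike-ins
added in fixed amounts vary technically, not biologically; isomiRs as the
simulated primitives with each mature miRNA the exact sum of its isomiRs
(so a mature miRNA and its isomiRs shift together when affected);
long-tailed baseline abundances (log2-normal, sd 2); sparse group effects
of magnitude log2(1.5) by default — the minimum fold change conventionally
used in power planning for such designs — placed in one group per affected
feature; and clinical covariates on realistic scales (ages around 60,
BMI around 29, duration log-normal, missing for controls). Covariate
*effects* on expression are off by default; switching them on (optionally
with group-correlated ages via `confounded_age = TRUE`) lets the tests
demonstrate that covariate adjustment removes the resulting false
positives.

The generator does not emulate sequence-level artefacts (adapters,
alignment ambiguity), correlated feature blocks beyond the isomiR/mature
sum constraint, batch structure, or the real studies' unknown dispersion
and depth profiles. Tests passing on these simulations therefore verify
the statistical machinery — calibration, bias, recovery under known truth —
not performance on any particular cohort; in particular, simulated power
(essentially 1.0 at a 1.5-fold change with 50 per group under default
generator settings) describes these synthetic conditions, not any real
dataset, whose dispersions and depths are unknown to us.

## Numerical and degenerate-case decisions

* z-scoring (for heatmaps) uses the n−1 denominator and maps constant rows
  to zeros, never NaN.
* cpm at prior 0 of an all-zero feature is 0; the log transform's prior
  (0.5) and denominator (+1) follow the precision-weighting convention.
* TMM falls back to the untrimmed weighted mean, with a warning, if fewer
  than two calibrators survive trimming; a sample with all-zero calibrators
  is an error naming the sample.
* Rank-deficient designs error naming the offending column (a 2×2 group
  comparison with k covariates needs more than k + 2 samples).
* BH input outside [0, 1] is an error, never clamped.
* The degenerate ANOVA case (zero within-group variance everywhere) reports
  NA rather than an arbitrary F.
* Perfect separation gives a flagged point interval (auc, auc), and the
  tie-corrected rank-test variance of 0 returns p = 0.5 at AUC 0.5.
* All simulation seeds are explicit; the same seed reproduces datasets,
  analyses and cross-validation bit for bit.

## Problem sizes used by the checks

The test-suite and the acceptance script size their Monte-Carlo experiments
to be decisive yet quick: 1,000 random instances for the exact oracles
(BH, AUC), 100 null replicates of 500 features × 2×20 samples for FDR
control, 50 null LOOCV replicates at 2×20 samples × 110 features plus one
signal-recovery LOOCV at the full 4×50 × 600 scale, 1,000 replicates at
40 per class for DeLong coverage, and 1,000 at 20 per class for rank-test
uniformity. These sizes are the package's chosen trade-off between
Monte-Carlo resolution and a test run a developer will actually wait for.
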