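# srnasig

Circulating small RNAs (miRNAs, isomiRs, tRNA fragments and other sRNAs)
measured by small-RNA sequencing of serum are candidate biomarkers for
distinguishing clinical groups — here, subgroups of diabetes (type 1, type 2,
LADA) and non-diabetic controls. `srnasig` implements the statistical
workflow such a study needs, end to end and testable at desk scale:

* **Spike-in calibrator normalization.** Ten synthetic calibrator RNAs added
  in fixed amounts before library preparation measure per-sample technical
  yield. Scaling factors are computed by the trimmed-mean-of-M-values (TMM)
  procedure on the calibrator submatrix, with calibrator proportions taken
  relative to the biological library size, and rescaled to geometric mean 1.
* **Precision-weighted moderated differential expression.** Log2-cpm values
  are modelled per feature by weighted least squares on a design with the
  two compared groups plus age, sex and BMI (and optional extras such as
  diabetes duration or the 30–33 nt fragment-length abundance). Weights come
  from a lowess fit of sqrt residual standard deviation against average
  log2 count (weight = trend⁻⁴); residual variances are shrunk by empirical
  Bayes (moment matching of log variances with trigamma inversion), giving
  moderated t-statistics with `d0 + d` degrees of freedom and
  Benjamini–Hochberg adjusted q-values. Mature miRNAs are filtered at
  ≥ 1 cpm in all samples, isomiRs and other sRNAs at ≥ 1 cpm in half the
  samples.
* **Nested leave-one-out cross-validated signatures.** For every held-out
  sample, feature selection (filter → weights → moderated t → BH, keep
  q < α) is re-run on the remaining samples; the held-out sample is scored
  by the direction-aligned standardized mean of the selected features. The
  out-of-fold scores yield the ROC curve, the Mann–Whitney AUC
  (AUC = P(score⁺ > score⁻), concordant pairs with tie credit), a DeLong
  structural-components 95% confidence interval and a one-sided tie-corrected
  rank-test p-value.
* **A synthetic-data generator** producing negative-binomial count matrices
  (variance μ + φμ²) with per-sample depth and technical-yield variation,
  calibrators that track true input, isomiRs whose parent mature miRNA is
  their exact sum, sparse group effects of known log2 fold-change, clinical
  covariates, and a ground-truth table — so every stage of the pipeline has
  a known answer to be tested against.

## Worked example

```r
library(srnasig)
library(dplyr)

ds <- simulate_srna_dataset(sim_params(seed = 42, n_per_group = 50,
                                       frac_de = 0.1, logfc = 1,
                                       de_group = "T2D"))
ds
#> srna_dataset: 600 features x 200 samples
#>   feature classes: antisense=17, calibrator=10, isomiR=300, lncRNA=21,
#>     mature_miRNA=100, other=13, snRNA=24, tRNA=87, yRNA=28
#>   groups: control=50, T1D=50, T2D=50, LADA=50
#>   simulation truth: 59 truly differential feature(s)

factors <- calibrator_norm_factors(ds)   # spike-in TMM, geometric mean 1

de <- de_analysis(ds, c("control", "T2D"), rule = "frac50")
glance(de)
#> # A tibble: 1 × 5
#>   n_features n_significant s2_prior df_prior coef
#> 1        590            71    0.973     85.5 groupT2D

tidy(de, sort_by_q = TRUE) |> slice_head(n = 3)
#> # A tibble: 3 × 7
#>   feature_id log2fc ave_expr     t df_total  p_value  q_value
#> 1 miR-032     -1.24     9.26 -12.4     180. 5.43e-26 3.20e-23
#> 2 miR-092     -1.15    10.8  -12.1     180. 3.35e-25 9.89e-23
#> 3 miR-094     -1.12    12.5  -12.0     180. 1.24e-24 2.44e-22

cv <- loocv_signature(ds, c("control", "T2D"))
cv
#> Leave-one-out cross-validated signature (control_vs_T2D)
#>   AUC 1.000 (95% CI 1.000-1.000), one-sided p = 3.43e-18
#>   100 folds (50 vs 50); empty-signature folds: 0%

autoplot(cv)   # ROC curve of the out-of-fold scores
```

The `glance()` line says 590 of 600 features survived the expression filter
(the 10 calibrators are always removed before testing) and 71 were
significant at q < 0.05; the shrinkage prior contributed 85.5 extra degrees
of freedom per feature. The DE table's top features are the planted T2D
effects with log2 fold-changes near the simulated magnitude of 1. The
cross-validated AUC of 1.0 reflects how strong that planted signal is at
n = 50 per group; under a null simulation (`frac_de = 0`) the same nested
procedure stays at AUC ≈ 0.5.

The full multi-contrast analysis (six pairwise comparisons × three feature
classes, each with its own filter) runs from one configuration:

```r
cfg <- as_run_config(list(comparisons = list(c("control", "T2D"),
                                             c("T2D", "LADA")),
                          alpha = 0.05, seed = 1))
run <- run_full(cfg, ds)
run$summary    # n_de, AUC, CI, p and the AUC > 0.7 pass flag per analysis
```

A thin command-line wrapper is installed as `exec/srnasig`
(`srnasig simulate|de|cv|run|power ...`).

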