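# meglaterality

Lateralizing mesial temporal lobe epilepsy (MTLE) from resting-state MEG
band power, as a tested R pipeline.

In unilateral MTLE, oscillatory power is elevated on the hemisphere
hosting the epileptic focus. The package quantifies that asymmetry with
the laterality index of regional band power,

```
LI(f, r) = (P_L - P_R) / (P_L + P_R)   in (-1, 1),   +1 = left-dominant
```

for seven frequency bands (delta 0.3–3 Hz through HFO 81–120 Hz) crossed
with four regions (frontal, temporal, parietal, occipital), referenced to
a healthy-control baseline, and then asks two questions:

- **statistics** — do the left-focus and right-focus groups differ?
  Band-wise 2 (group) × 4 (region) factorial ANOVA whose F statistics are
  evaluated against a pooled bootstrap null (all observations resampled
  with replacement regardless of group/region, 20,000 times), plus
  per-cell one- and two-sample bootstrap tests with Benjamini–Hochberg
  FDR control;
- **prediction** — do the 28 standardized LIs lateralize individual
  patients? Linear SVM with fixed hyperparameters under leave-one-out
  cross-validation, with confusion metrics, Platt-posterior ROC curves,
  trapezoidal AUC, and a concordance summary against conventional
  equivalent-current-dipole (ECD) calls.

Upstream of the statistics, the package carries a desk-scale version of
the signal chain: 10-s epoching, 6,000 fT artifact rejection, zero-phase
notch/band-pass filtering, coherence-prior minimum-norm inversion on a
toy sensor/source geometry, Morlet band power, and regional
summarization. A synthetic cohort generator with known ground-truth
effects (log-normal powers; ipsilateral power elevations concentrated
temporo-parietally in theta/alpha) makes the whole pipeline testable
without patient data. It is intended for methods work, teaching and
reanalysis — not clinical use.

## Worked example

```r
library(meglaterality)
library(dplyr)

# a full-size synthetic cohort: 102 controls, 16 left-, 19 right-focus
cohort <- simulate_power_cohort(synth_config(seed = 42))

li  <- li_table(cohort)                                  # 28 LIs per subject
lic <- baseline_correct(filter(li, group != "CTR"),
                        ctr_baseline(li))                # CTR-referenced

# theta-band factorial ANOVA with pooled-bootstrap significance
a <- bootstrap_f_pvalue(li_anova(filter(lic, band == "theta")),
                        n_resamples = 20000, seed = 42)
a
#> 2 x 4 factorial ANOVA of laterality (band: theta)
#>       effect df         SS         MS          F p_parametric degenerate  p_boot
#>   group_main  1 2.90304195 2.90304195 66.2036430 2.637643e-13      FALSE 0.00000
#>  region_main  3 0.03436327 0.01145442  0.2612172 8.532224e-01      FALSE 0.14400
#>  interaction  3 0.65841094 0.21947031  5.0050032 2.555024e-03      FALSE 0.00225

# leave-one-out linear-SVM lateralization, left-focus vs control
m <- li_matrix(li); g <- attr(m, "groups")
keep <- g %in% c("LtMTLE", "CTR")
fit <- loocv_svm(m[keep, ], g[keep], positive = "LtMTLE", seed = 42)
glance(fit)
#> # A tibble: 1 × 7
#>   positive n_iterations n_features accuracy sensitivity specificity   auc
#> 1 LtMTLE            118         28    0.932       0.688       0.971 0.973

# concordance between SVM and dipole calls on the packaged patient table
ecd_concordance(load_table1())
#> # A tibble: 1 × 4
#>   both_lateralized_agree svm_only ecd_only neither
#> 1                     19        6        4       6
```

Reading the output: the theta-band group main effect is large (F ≈ 66)
and survives the pooled bootstrap (no resampled F among 20,000 exceeded
it), i.e. left- and right-focus patients have clearly separated
baseline-corrected laterality — the injected ground truth of the
synthetic cohort. The classifier predicts each of the 118 subjects
exactly once from the other 117 (93% accuracy, AUC 0.97 on this
cohort). Of the 35 packaged patients, 19 are lateralized identically by
SVM and dipole analysis, 6 by the SVM alone, 4 by the dipole alone, and
6 by neither.

`run_pipeline()` chains all stages and writes the result tables as CSV;
`plot_li_distribution()` and `autoplot()` methods draw the standard
box-plot and ROC displays. `vignettes/meg-laterality-methods.Rmd`
documents the model, the generator's assumptions, and every numerical
choice.

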