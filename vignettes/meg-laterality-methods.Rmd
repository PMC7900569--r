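---
title: "Band-power laterality analysis for epilepsy lateralization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-power laterality analysis for epilepsy lateralization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meglaterality)
library(dplyr)
```

## The problem

In unilateral mesial temporal lobe epilepsy (MTLE), deciding *which*
hemisphere hosts the epileptic focus drives surgical planning. Resting-state
MEG offers a non-invasive window: oscillatory power in classical frequency
bands is systematically elevated on the focus side, so a normalized
hemispheric asymmetry of regional band power carries lateralizing
information. This package implements that analysis chain as reusable,
tested R functions:

1. sensor preprocessing (10-s epochs, 6,000 fT artifact rejection,
   zero-phase notch and band-pass filtering);
2. a desk-scale source-power stage (coherence-prior minimum-norm inversion
   on a toy geometry, Morlet band power, trial averaging, regional
   summaries);
3. the laterality index and its healthy-control baseline correction;
4. bootstrap-evaluated group statistics with FDR control;
5. a fixed-hyperparameter linear-SVM classifier under leave-one-out
   cross-validation (LOOCV), with confusion metrics, ROC/AUC and a
   concordance summary against conventional dipole (ECD) calls.

Because no patient recordings are distributable, a synthetic-cohort
generator with known ground truth stands in for the clinical data; it is
first-class, tested code, and every downstream stage is exercised through
it.

## The laterality index

For band $f$ and region $r$ with hemispheric powers $P_{L,f,r}$ and
$P_{R,f,r} > 0$,

$$\mathrm{LI}_{f,r} = \frac{P_{L,f,r} - P_{R,f,r}}{P_{L,f,r} + P_{R,f,r}}
  \in (-1, 1),$$

with $+1$ meaning fully left-dominant power. Seven bands (delta 0.3–3,
theta 4–7, alpha 8–12, beta 13–25, low gamma 26–40, high gamma 41–80, HFO
81–120 Hz) crossed with four regions (frontal, temporal, parietal,
occipital) give a fixed band-major 28-vector per subject
(`li_feature_names()`). Healthy brains are themselves lateralized, so for
group comparisons the control-group mean LI per cell is subtracted
(`ctr_baseline()`, `baseline_correct()`); corrected values live in
$(-2, 2)$. The index is undefined at $P_L + P_R = 0$: powers below
$10^{-12}$ raise an error rather than being clamped, because a silent clamp
would fabricate an asymmetry of exactly $\pm 1$.

## The synthetic cohort generator

`simulate_power_cohort()` draws strictly positive powers from a log-normal
model. For subject $i$ in group $g$, cell $(f, r)$, hemisphere $h$:

$$\log P = \mu_{g,f,r,h} + \sigma Z, \qquad Z \sim N(0,1),$$

where $\mu$ encodes (a) a baseline control asymmetry $b_{f,r}$ as the
log-power offset $\pm\,\mathrm{atanh}(b_{f,r})$, and (b) for the patient
groups, a multiplicative elevation $e^{\delta_{f,r}}$ on the hemisphere
ipsilateral to the focus. Under this model the cell LI equals
$\tanh\!\big((\log P_L - \log P_R)/2\big)$, so in the noise-free limit the
generated LI is exactly the configured baseline, and an effect $\delta$
shifts it by $\tanh(\delta/2) = (e^\delta - 1)/(e^\delta + 1)$. With noise,
the expectation acquires a Jensen-type bias; the test suite therefore
checks the generator against the exact expectation computed by numerical
quadrature over the model's own law.

Defaults are the study conditions:

- group sizes 102 controls, 16 left-focus, 19 right-focus patients;
- ages uniform on [8, 75] years, covering the cohort ranges; sex is not
  modelled because no analysis consumes it;
- baseline LI 0.05 in every cell — small but nonzero, since healthy
  controls show measurable lateralization;
- the effect pattern `default_effect_delta()` concentrates ipsilateral
  elevations temporo-parietally with a theta/alpha peak ($\delta = 0.5$,
  i.e. a ~65% power elevation), tapering to 0.15 elsewhere, emulating the
  qualitative topography reported for unilateral MTLE;
- `noise_cv = 0.3`, the within-group coefficient of variation of power
  ($\sigma = \sqrt{\log(1 + \mathrm{cv}^2)} \approx 0.29$). This value was
  chosen to reproduce the residual LI scale implied by published factorial
  ANOVA summaries of baseline-corrected LI (mean square / F ratios give a
  residual SD of roughly 0.21 LI units); the within-group dispersion is
  otherwise unconstrained by published values and is an assumption, not an
  estimate.

What the generator does *not* emulate: spatially correlated noise across
cells, age- or duration-dependent effects, heavy-tailed outliers, site
effects between patient and control acquisitions, or any coupling between
bands. Passing tests on synthetic cohorts therefore demonstrate the
correctness and calibration of the *machinery*, not clinical performance
on real recordings.

## Preprocessing and the source stage

Recordings (channels × samples, fT) are cut into non-overlapping 10-s
epochs (trailing remainder dropped); an epoch is rejected when any channel
exceeds 6,000 fT in absolute value at any sample — the rule is
deliberately any-channel/any-sample since peak-to-peak variants are
slightly laxer and the printed rule names a single excursion threshold.
Power-line interference is removed with a zero-phase (forward–backward)
4th-order Butterworth band-stop, 2 Hz wide, at the site's utility
frequency (50 or 60 Hz); band-limiting uses the same filter family. The
delta band's lower edge is implemented at 0.3 Hz, the hardware high-pass
of the recording chain, since a 0-Hz IIR edge is unrealizable.

The source stage is an intentionally small analog of a clinical
minimum-norm pipeline. Sensors sit on a unit hemisphere, sources on a
concentric shell (radius 0.8) in fixed clusters per region × hemisphere
cell, and the gain is an inverse-square distance kernel — enough geometry
for inversion and regional summaries to have a ground truth, with no claim
to biophysical realism. Inversion is Tikhonov-regularized with a spatial
coherence prior $R_{ij} = \exp(-\lVert s_i - s_j\rVert^2 / 2\sigma^2)$:

$$J = R G^\top (G R G^\top + \lambda I)^{-1} B,$$

with $\sigma = 0.2 \times$ geometry radius and $\lambda = 0.1 \times$ the
mean diagonal of $G R G^\top$ by default — a fixed, deterministic stand-in
for hyperparameter-optimized coherence-prior inverses, preserving the
spatial-smoothness idea at desk scale. Band power uses 7-cycle complex
Morlet wavelets on a 1-Hz in-band grid, time-averaged with half a wavelet
support excluded at each edge, then averaged over trials (retained
epochs) and summarized as cell means per region × hemisphere.

## Statistics

**Factorial ANOVA.** Baseline-corrected LIs of the two patient groups
enter a 2 (group) × 4 (region) full factorial per band, each subject
contributing its four regional values as independent cells — the
between-cell reading of the published design (degrees of freedom were not
printed, so a repeated-measures treatment cannot be confirmed; it is out
of scope here). The design is unbalanced (16 vs 19), so sums of squares
are Type III with sum-to-zero contrasts, computed by `car::Anova()`.

**Pooled bootstrap.** Significance of each F is evaluated
non-parametrically: all observations are pooled and resampled with
replacement *regardless of group and region* (20,000 times by default),
redealt into the original design cells, and F recomputed. The reported
level is the smaller of the two strict tail proportions — the published
rule taken literally, not doubled. For a non-negative statistic this
smaller-tail rule is unusual (the upper tail is the natural one); the
package follows the printed procedure and exposes `two_sided = TRUE` for
the doubled, calibrated variant. Per-cell one-sample (against zero) and
two-sample (left vs right focus) bootstrap tests follow the same
smaller-tail convention, with resample statistics the group mean and the
difference of independently resampled group means. Ties at the reference
value count toward neither tail. Benjamini–Hochberg FDR is controlled at
$q = 0.05$ separately within each family of 28 band × region tests (one
family per test type; the published family structure is not stated, and
per-type families are the conservative reading that keeps the three test
types interpretable in isolation).

For speed, the bootstrap F loop evaluates resampled response vectors
through precomputed Type III projection matrices (three quadratic forms
per resample); the test suite pins this fast path to `car::Anova()` on
the original data.

**Mass-univariate contrast.** `mass_univariate_ancova()` implements the
source-level group comparison with age as a nuisance covariate: per
source, the extra-sum-of-squares F of `power ~ age + group` over
`power ~ age`, with family-wise error over sources controlled by
max-statistic permutation of group labels (1,000 permutations by
default). Random-field-theory correction is out of scope; permutation is
the standard assumption-light replacement.

## Classification

The 28 LI features are standardized (population SD; the two-point column
$(0,2)$ maps to $(-1,+1)$) and fed to a linear SVM with fixed
hyperparameters (cost 1, no class weights) via `e1071::svm`. Validation
is leave-one-out: $n$ iterations for $n$ subjects, each subject predicted
by a model never trained on it — 118 iterations for 16 patients + 102
controls. Posterior probabilities are a Platt-style sigmoid: a logistic
regression of training-fold labels on training-fold decision values,
evaluated at the held-out decision value. On separable folds that
logistic fit is degenerate (probabilities saturate); the posterior
remains a monotone transform of the decision value, which is all the ROC
needs, and the AUC is invariant to it.

Standardization is fit on the *whole dataset* before cross-validation by
default, reproducing the published "standardized over the dataset"
protocol; this leaks the held-out subject's contribution to the scaling
into training and typically flatters performance slightly.
`standardization = "per_fold"` is the leakage-free alternative and is the
variant to prefer for honest generalization estimates.

ROC curves sweep thresholds over the unique posterior values (ties enter
at one step), and AUC is the trapezoidal integral — equal, by
construction, to the Mann–Whitney statistic, which the tests assert.
`confusion_from_rates()` reconstructs integer confusion matrices from
published group sizes and sensitivity/specificity, which is how the
package cross-checks published accuracies (94.1% and 91.7%) without
patient data. `ecd_concordance()` cross-classifies the packaged
35-patient table's dipole and SVM calls into
agree / SVM-only / ECD-only / neither (19 / 6 / 4 / 6).

## Numerical choices and degenerate inputs

- Zero-variance ANOVA responses report F = 0 with a degenerate flag
  rather than 0/0.
- All-zero one-sample bootstrap input returns p = 0.5 with a degenerate
  flag (the statistic has no tails).
- Bootstrap p values are exactly order-invariant: inputs are put in
  canonical order before seeded resampling.
- The zero-phase filters are algebraically linear, but the narrow
  band-stop is numerically stiff (poles near the unit circle); float
  rounding between filtering a sum and summing filtered parts reaches
  ~$10^{-5}$ relative, so linearity is asserted at $10^{-3}$ of signal
  scale, not machine precision.
- Platt calibration warnings on separable folds are suppressed
  deliberately; see above.
- Constant feature columns abort standardization with the feature named.

## Problem sizes used in the tests

The packaged suites run at deliberately small scale chosen to keep the
checks sharp: bootstrap calibration uses 500–1,000 replicate null
cohorts at 300–1,000 resamples; the null-calibration and chance-level
classifier checks run at the study's group sizes (16/19 patients vs 102
controls), where the bootstrap granularity and LOOCV's known pessimism
on high-dimensional null data are negligible; enumeration oracles cover
$n \le 3$ exhaustively; the factorial-ANOVA fast path is pinned to
`car::Anova` exactly. The acceptance script regenerates a full-size
cohort (137 subjects) and runs both LOOCV scenarios and the theta-band
bootstrap ANOVA at the published 20,000 resamples in a few seconds.

## Known limitations

- The toy geometry and inverse-square gain are not a forward model;
  localization claims are limited to the synthetic setting.
- The between-cell ANOVA treats a subject's four regional values as
  independent; a repeated-measures variant would be more conservative.
- The literal smaller-tail bootstrap rule halves the effective level of
  every reported p relative to a two-sided test; comparisons across
  studies should use `two_sided = TRUE`.
- Whole-dataset standardization (the default, for fidelity) is mildly
  optimistic; per-fold mode exists for that reason.
- The generator's independence across cells makes the 28 features less
  collinear than real LI vectors, likely flattering the classifier's
  synthetic-data accuracy.
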