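---
title: "Methods: voxel-wise cerebrovascular reactivity and white matter damage progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise cerebrovascular reactivity and white matter damage progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrfate)
```

## The scientific problem

In cerebral small vessel disease — and in CADASIL, its monogenic model —
white matter damage accumulates over years: normal-appearing white matter
(NAWM) converts to white matter hyperintensities (WMH), and mean diffusivity
(MD) creeps upward even where lesions never form. A central question is
whether the *local* condition of the microvasculature predicts where that
damage will appear. `cvrfate` implements a voxel-wise analysis of that
question: baseline small vessel function is measured as the BOLD
cerebrovascular reactivity (CVR) response to a hypercapnic CO2 challenge,
and related to two-year tissue fate and MD change through voxel-concatenated
mixed models. Because the patient imaging such studies use is not openly
deposited, the package pairs the analysis chain with a seeded synthetic
cohort generator whose ground truth is known exactly, so every stage is
testable end to end.

## The measurement model

### CVR magnitude

For each voxel, the BOLD time series $S(t)$ is regressed on the end-tidal
CO2 (etCO2) regressor $x(t)$ with an intercept and polynomial drift terms
(default order 1):

$$ S(t) = \beta_0 + \beta_d t + \beta\, x(t) + \varepsilon(t). $$

The CVR magnitude is reported as percent signal change per mmHg,
$100\,\beta / \bar S$, with the voxel's temporal mean $\bar S$ as baseline.
The etCO2 regressor is resampled to the volume mid-times and centred on its
median — the median rather than the mean because block designs spend unequal
time at the two gas levels. The regressor entering the design matrix is
additionally mean-centred, which makes the "% of temporal mean" definition
exact (the stimulus then contributes nothing to $\bar S$).

The subject-level challenge amplitude, `delta_etco2()`, is the mean of the
top 25% of etCO2 samples minus the mean of the bottom 25%, with
$k = \max(1, \lfloor N/4 \rfloor)$ samples per tail; the rounding rule is a
package choice and is pinned by tests. It enters all voxel-wise models as a
fixed covariate. An optional `window` argument restricts the computation to
the challenge period; the default uses the full trace.

### Dispersion

Diseased white matter does not just respond less — it responds *slower and
more smeared*. That temporal blurring is modelled by convolving the etCO2
regressor with a causal exponential kernel of unknown time constant $\tau$:

$$ h_\tau[k] \propto e^{-k\,\mathrm{TR}/\tau}, \qquad \sum_k h_\tau[k] = 1, $$

and finding the $\tau$ whose convolved regressor best fits the voxel by
least squares. The implementation evaluates the residual sum of squares on a
40-point log-spaced grid over bounds of 1–120 s — bracketing white matter
dispersion of several tens of seconds and grey matter dispersion near 15 s
with margin — and then refines the grid minimum by bracketed Brent
minimisation to an absolute tolerance of $10^{-6}$ s. A single parabolic
refinement step was considered and rejected: it leaves residual $\tau$ error
of order 0.1 s, which propagates into magnitude error of order
$10^{-4}$ %/mmHg and would spoil the exact noiseless round trip that the
test suite guarantees (recovery to $10^{-6}$ %/mmHg and $10^{-3}$ s). Ties
in the grid profile resolve to the smaller $\tau$; a flat profile (e.g. a
constant time series) is flagged `converged = FALSE` rather than fitted.

Convolution is causal with zero padding before the first sample, i.e. the
centred trace is taken to sit at baseline before the acquisition starts; the
generator and the fitting side share this convention, which is what makes
the noiseless round trip exact rather than merely close.

### QC conventions

Voxels with constant or non-finite signal yield flagged invalid estimates
(`NA` in maps, code in `qc_map`), never exceptions — the fit must survive
being mapped over whole volumes. Downstream stages drop flagged voxels
listwise.

## Tissue fate and damage maps

The analysis mask is the white matter mask eroded by 2 mm minus a zone
dilated 6 mm around the ventricles. The erosion guards against grey matter
partial-volume and registration error at the WM boundary; the exclusion zone
removes the large subependymal veins that dominate periventricular BOLD.
Both operations use a *spherical* structuring element measured in physical
millimetres (anisotropic voxels are handled through true Euclidean
distance); the sphere is the isotropic choice where no element shape is
prescribed. Voxels whose element exits the image are eroded away —
conservative boundary handling. One practical consequence, visible in the
test fixtures: with a 2 mm erosion *and* a 6 mm exclusion, a simulated brain
must be comfortably larger than 8 mm in semi-axis or the surviving analysis
ring is empty.

Within the analysis mask each voxel is labelled by the 2x2 membership table
of the baseline and follow-up WMH masks: stable NAWM, NAWM converting to
WMH, WMH reverting to NAWM, stable WMH. The four labels partition the
analysis mask exactly (a property the suite checks against a brute-force
per-voxel loop). Inputs are assumed co-registered, with lesions protected
during any non-linear registration; registration itself is out of scope.
Mask membership is strict binary (> 0.5 after any resampling).

MD change maps are follow-up minus baseline inside the analysis mask, with
non-positive MD flagged missing. Global measures follow the conventions of
the field: WMH volume is normalised to intracranial volume and cube-root
transformed *before* differencing (so the cube root never sees a negative
argument), and PSMD — the peak width of skeletonised MD — is the 95th minus
5th percentile of MD on the skeleton, with linear interpolation between
order statistics (`quantile type 7`). Skeletonisation is upstream; in the
synthetic pipeline the 2 mm eroded WM core serves as the skeleton stand-in.

## The statistical layer

All baseline-NAWM voxels of all subjects are concatenated into one table.
Continuous outcomes (MD change, baseline MD) are fitted with a
random-intercept linear mixed model (REML, `lme4::lmer`): the CVR measure
as fixed effect, the challenge amplitude as subject-level fixed covariate,
participant as random intercept. Tissue fate is fitted with a logistic
mixed model (Laplace approximation, `lme4::glmer`) of the same structure —
conversion among baseline-NAWM voxels, reversion among baseline-WMH voxels.
Odds ratios are reported per 1 %/mmHg of magnitude and per 10 s of
dispersion; the 10 s scaling multiplies the per-second coefficient before
exponentiation, which is algebraically identical to refitting on rescaled
data (tested as an exact power identity). Confidence intervals are Wald
intervals with the asymptotic normal; at the voxel counts these models are
built for, the normal approximation is the appropriate reference, and its
calibration is verified empirically (below) rather than assumed. Singular
fits and suspected separation are flagged in the result, never silently
ignored. An `adjust_age` switch adds age as a fixed effect for sensitivity
analyses.

Supporting analyses use the standard machinery: per-subject regional means
compared by one-way ANOVA with Tukey HSD post-hocs, paired t-tests for
NAWM-vs-WMH and baseline-vs-follow-up contrasts, Spearman correlations
(deliberately unadjusted for age, which is collinear with disease burden in
CADASIL) for skewed cross-sectional associations, standardised univariate
regressions for global longitudinal associations (CVR models adjusted for
the challenge amplitude), and Holm step-down adjustment (Benjamini-Hochberg
selectable) across the family of reported models. Voxels are treated as
exchangeable within subject: no spatial autocorrelation model is fitted,
which means voxel-level CIs inherit the optimism of that assumption — a
known limitation shared with the analysis design this package implements.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; its defaults are the conditions
the analysis is designed for, not tuning knobs:

* 17 subjects with a completed hypercapnic BOLD exam; a block CO2 challenge
  (two 60 s blocks in a 6 min acquisition, TR 3 s) raising etCO2 by
  10 ± 1 mmHg over a 40 mmHg baseline, with 0.5 mmHg sample jitter.
* True CVR magnitude 0.054 ± 0.047 %/mmHg in NAWM falling to 0.013 inside
  lesions; true dispersion 46 ± 13 s rising to 59 s in lesions. The fields
  are Gaussian-smoothed white noise (4 mm FWHM) plus a lesion-centred
  deficit; the spatial covariance has no published counterpart and is a
  free parameter.
* Conversion of NAWM to WMH follows a logistic model whose coefficients are
  the documented odds ratios (0.81 per %/mmHg, 1.06 per 10 s) with the
  intercept set to a ~4% two-year conversion rate; reversion mirrors this
  (1.06 per %, 0.95 per 10 s, ~1.3% rate). Both models carry a per-subject
  random intercept (SD 0.3 logits).
* MD change is linear in the true fields (−1.17e−6 per %, +4.7e−8 per s,
  mean 0.13e−4 mm²/s) with a per-subject intercept (SD 1e−6) and voxel
  noise of 1.5e−6 mm²/s — the residual scale implied by the reported
  interval widths at the reported voxel counts. In voxels that convert, both
  slopes are multiplied by `dmd_converting_multiplier` (default 5),
  encoding the several-fold stronger vascular–microstructural coupling
  observed where lesions form.
* BOLD noise is 0.5% of baseline signal (temporal SNR 200, a realistic
  white matter figure at high field).

The simulated brain is a miniature ellipsoidal phantom (28 x 28 x 20 voxels
of 1 mm, nested ventricle / white matter compartments, periventricular
lesion seeds grown as spheres). It reproduces the *statistical* structure
the analysis assumes — co-registered grids, nested masks, lesion-centred
vascular deficits, two-timepoint outcomes with subject heterogeneity — and
deliberately omits scanner artefacts, motion, registration error,
anatomical realism and multi-site effects. Passing tests therefore
demonstrate correctness of the estimators and calibration of the inference
under the stated generative model, not robustness to the failure modes of
real acquisitions.

Seeding: one master seed; per-subject seeds derive deterministically as
`seed + 1000 * index`, so any subject can be regenerated in isolation and
the full pipeline is byte-reproducible (a property the suite asserts).
`simulate_voxel_table()` draws voxel tables directly from the same outcome
models without image formation — the fast path used for statistical
validation at scale.

## Numerical and design choices worth knowing

* **Magnitude baseline.** "% signal change" is anchored to the voxel's
  temporal mean. The generator mean-centres the dispersed stimulus so the
  configured CVR is exactly this estimand; equivalently, the block-plateau
  contrast of a noiseless voxel with CVR 0.2 %/mmHg under a 10 mmHg step is
  2% of baseline signal.
* **Dispersion refinement tolerance.** Brent to 1e−6 s inside the
  bracketing grid interval; the noiseless round trip recovers τ to better
  than 1e−5 s, and an exhaustive 0.1 s grid search agrees to within its own
  resolution.
* **Degenerate inputs.** Constant series → flagged, not errored; flat RSS
  profiles → `converged = FALSE`; zero-variance paired differences →
  degenerate flag; constant covariate columns → dropped with a recorded
  flag; reversion can be disabled outright with a −Inf intercept.
* **Erosion boundary rule.** Conservative (border voxels die); closing is
  only guaranteed to contain the original away from the image border.
* **Tie-breaks.** Dispersion grid ties resolve to the smaller τ; Holm is
  the default multiplicity correction because the reported model family is
  small and dependent.

## Validation strategy and what the numbers mean

Three layers of evidence, all recomputed by `scripts/acceptance.R`:

1. **Exactness where exactness is possible.** Noiseless synthetic BOLD
   round-trips magnitude to ≤1e−6 %/mmHg and τ to ≤1e−3 s over 1000 voxels
   spanning the physiological range; the dispersion fit matches an
   exhaustive 0.1 s grid on 100 random voxels; morphology matches per-voxel
   Euclidean-ball oracles; fate labels match a brute-force loop.
2. **Calibration where only calibration is meaningful.** Across 25
   replicate cohorts (10 subjects × 2000 voxels) the Wald 95% CI of the
   LMM slope (stable-NAWM subset, where the generative slope applies
   unmodified) and of the GLMM log-OR cover their generative values at the
   nominal rate; under within-subject permutation of the predictor the
   p < 0.05 rate over 200 replicates stays at 5% ± 3%.
3. **Direction at scale.** The weak per-voxel effects mean sign recovery is
   a large-N property: the conversion OR per 1 %/mmHg is a ~20-SD
   extrapolation of a ~0.01-logit-per-SD effect, so its sign is only
   resolved on cohorts of order a million voxels. The suite runs one such
   cohort (17 × 60k voxels) and confirms every documented direction:
   MD change falls with magnitude and rises with dispersion, the coupling
   is several-fold stronger in converting voxels, conversion odds fall with
   magnitude and rise with dispersion, reversion odds fall with dispersion.
   The reversion–magnitude direction is even weaker and is not sign-tested.

A corollary the end-to-end numbers make visible: when the mixed models are
fed *fitted* CVR maps at the default 0.5% BOLD noise (rather than the
generative truth), the per-% odds ratios are attenuated and noise-dominated
at desk-scale voxel counts — ordinary errors-in-variables behaviour, and the
reason parameter-recovery claims are made against the generative tables.
Similarly, the voxel-wise *baseline* MD association is amplified by lesion
proximity (low-CVR voxels cluster near lesions, where baseline MD is
elevated for other reasons): a reminder that these are marginal
associations, not causal effects.

## Problem sizes

Defaults were chosen so a full run is a desk-scale computation: the
17-subject image-space pipeline fits ~4700 WM voxels per subject
(~10 s/subject), the calibration experiments use 25 cohorts of 20k voxels
and 200 permutation replicates of 3k voxels, and the direction check uses
one ~1M-voxel table. The complete acceptance script runs in under ten
minutes on one CPU.

## Known limitations

* No spatial dependence between voxels, in either the generator or the
  models; voxel-level CIs are accordingly optimistic.
* The synthetic anatomy is a phantom; ICV and absolute volumes are
  miniature, so volume *percentages* and model coefficients, not absolute
  millilitres, are the comparable quantities.
* Dispersion maps at realistic BOLD noise are individually noisy (the
  response amplitude of a typical WM voxel is ~0.5% of baseline); they are
  informative in aggregate, across many voxels, which is exactly how the
  mixed models consume them.
* Registration, segmentation, denoising and skeletonisation are assumed
  done; real-data users must bring co-registered inputs and should treat
  the 6 mm exclusion as unconstrained (not geodesic) dilation.
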