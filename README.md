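# cvrfate

Voxel-wise cerebrovascular reactivity and white matter damage progression.

## What this package is for

In cerebral small vessel disease — including CADASIL, its monogenic form —
white matter damage accumulates silently: normal-appearing white matter
(NAWM) converts to white matter hyperintensities (WMH), and mean diffusivity
(MD) rises even where no lesion ever appears. `cvrfate` is for researchers
asking whether the **local** state of the microvasculature predicts where
that damage will occur. It implements the full analysis chain linking
baseline BOLD cerebrovascular reactivity (CVR) — the signal response to a
hypercapnic CO2 challenge — to longitudinal tissue fate and MD change,
together with a seeded synthetic-cohort generator with known ground truth,
so the whole chain is testable without access to patient data.

## The model at its core

Per voxel, two baseline quantities are estimated from the 4D BOLD series and
the end-tidal CO2 (etCO2) trace:

* **CVR magnitude** (%/mmHg): OLS of the BOLD series on the median-centred
  etCO2 regressor plus drift, reported as `100·β / mean(S)`.
* **CVR dispersion** τ (s): the time constant of the causal exponential
  kernel `h_τ[k] ∝ exp(−k·TR/τ)` (unit area) whose convolution with the
  etCO2 regressor best fits the voxel by least squares — temporal smearing
  of the vascular response. Fitted by a 40-point log-grid search on
  [1, 120] s with Brent refinement.

Longitudinal damage is encoded per WM voxel as a **tissue fate** (stable
NAWM, NAWM→WMH, WMH→NAWM, stable WMH; analysis restricted to WM eroded by
2 mm minus a 6 mm periventricular exclusion zone, spherical elements in
physical mm) and as **ΔMD** (follow-up − baseline). Voxels of all subjects
are concatenated and modelled with participant-random-intercept mixed
models (`lme4`), with the challenge amplitude ΔetCO2 (mean of the top 25%
of etCO2 samples minus mean of the bottom 25%) as fixed covariate:

* linear mixed model: `ΔMD ~ CVR measure + ΔetCO2 + (1 | participant)`
* logistic mixed model for fate, odds ratios per 1 %/mmHg of magnitude and
  per 10 s of dispersion.

Global measures (WMH volume normalised to intracranial volume and
cube-root transformed, PSMD as the 95th−5th percentile width of
skeletonised MD, mean NAWM MD) support the secondary, subject-level
analyses: paired t-tests, Spearman correlations, standardised univariate
regressions, ANOVA with Tukey HSD, Holm adjustment.

## Worked example

Simulate a six-subject cohort at the default study conditions, run the
voxel-wise pipeline, and fit the primary models:

```r
library(cvrfate)

cfg    <- sim_config(n_subjects = 6, seed = 11)
cohort <- generate_cohort(cfg)              # or generate_cohort(cfg, "out/")
fits   <- lapply(cohort$subjects, analyze_subject)
tab    <- build_voxel_table(fits)

fits[[1]]$fate
#> Tissue-fate map, 28 x 28 x 20 voxels of 1 x 1 x 1 mm
#>    EXCLUDED STABLE_NAWM NAWM_TO_WMH WMH_TO_NAWM  STABLE_WMH
#>       14128        1289          92           4         167

lmm_continuous(tab, "cvr_mag", "delta_md", "all_nawm")
#> Linear mixed model: delta_md ~ cvr_mag (subset: all_nawm)
#>   beta = -3.166e-06  [95% CI -4.045e-06 - -2.287e-06]  p = 1.64e-12
#>   7919 voxels, 6 subjects; random-intercept SD 3.95e-07

glmm_fate(tab, "conversion", "tau_s")
#> Logistic mixed model: conversion ~ tau_s
#>   OR (per 10 s) = 0.996  [95% CI 0.972 - 1.021]  p = 0.744
#>   7919 voxels (377 events), 6 subjects
```

Reading this: every fitted white matter voxel is labelled by its two-year
fate; the linear mixed model says that voxels with 1 %/mmHg less baseline
reactivity gained on the order of 3×10⁻⁶ mm²/s more diffusivity over
follow-up (lower vascular function, faster microstructural decline). The
dispersion odds ratio illustrates an honest negative: per-voxel fate
effects are weak, and at six subjects a fitted-map analysis cannot resolve
them — the direction emerges in the large-cohort validation runs. The
baseline NAWM-vs-WMH contrast is strong even here:

```r
g  <- do.call(rbind, Map(compute_subject_globals, cohort$subjects, fits))
gb <- g[g$timepoint == "baseline", ]
paired_tests(gb$cvr_mag_nawm, gb$cvr_mag_wmh)
#> NAWM vs WMH CVR magnitude: mean diff 0.053 %/mmHg, t = 12.28, p = 6.3e-05
```

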