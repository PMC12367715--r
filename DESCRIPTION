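Package: cvrfate
Title: Voxel-Wise Cerebrovascular Reactivity and White Matter Damage
    Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links baseline microvascular function, measured as the
    blood-oxygenation-level-dependent (BOLD) cerebrovascular reactivity
    (CVR) response to a hypercapnic end-tidal CO2 challenge, to
    longitudinal white matter damage in cerebral small vessel disease.
    Provides voxel-wise estimation of CVR magnitude (percent signal
    change per mmHg CO2) and of the hemodynamic dispersion time constant
    of an exponential convolution kernel; construction of longitudinal
    tissue-fate maps (stable normal-appearing white matter, conversion
    to white matter hyperintensity, reversion, stable lesion) with
    physical-unit morphological masking; global damage indices (lesion
    volume, peak width of skeletonised mean diffusivity); voxel-
    concatenated linear and logistic mixed models with a participant
    random intercept; and a seeded synthetic-cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
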