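#' Parameter-recovery experiment for the voxel-wise mixed models
#'
#' Simulates replicate cohorts from the generative model
#' ([simulate_voxel_table()]), fits the continuous linear mixed model (MD
#' change on CVR magnitude, in the stable-NAWM subset where the generative
#' slope applies unmodified) and the logistic mixed model (NAWM-to-WMH
#' conversion on CVR magnitude) to each, and records whether each Wald 95%
#' confidence interval covers the generative coefficient. Long-run coverage
#' near 95% is the calibration check for the interval construction.
#'
#' @param config A [sim_config()]; its fate and MD-change coefficients are
#'   the recovery targets.
#' @param n_replicates Number of replicate cohorts. Default 25.
#' @param n_subjects Subjects per cohort. Default 10.
#' @param n_voxels_per_subject Voxels per subject. Default 2000.
#' @param seed Seed for the replicate stream.
#' @return Data frame with one row per replicate: `lmm_beta`, `lmm_lo`,
#'   `lmm_hi`, `lmm_covered`, `glmm_coef`, `glmm_lo`, `glmm_hi`,
#'   `glmm_covered`. The generative coefficients are in attributes
#'   `truth_lmm` and `truth_glmm`.
#' @export
coverage_experiment <- function(config, n_replicates = 25, n_subjects = 10,
                                n_voxels_per_subject = 2000,
                                seed = config$seed) {
  cfg <- config
  cfg$n_subjects <- n_subjects
  truth_lmm <- unname(config$dmd_coefs[2])
  truth_glmm <- unname(config$fate_logit_coefs[2])
  rows <- lapply(seq_len(n_replicates), function(r) {
    tab <- simulate_voxel_table(cfg, n_voxels_per_subject,
                                seed = (seed + 7919 * r) %%
                                  .Machine$integer.max)
    lmm <- lmm_continuous(tab, "cvr_mag", "delta_md", "stable_nawm")
    glmm <- suppressWarnings(
      glmm_fate(tab, "conversion", "cvr_mag", scale_factor = 1))
    glo <- log(glmm$ci95)
    data.frame(lmm_beta = lmm$beta, lmm_lo = lmm$ci95[1],
               lmm_hi = lmm$ci95[2],
               lmm_covered = lmm$ci95[1] <= truth_lmm &
                 truth_lmm <= lmm$ci95[2],
               glmm_coef = glmm$coef, glmm_lo = glo[1], glmm_hi = glo[2],
               glmm_covered = glo[1] <= truth_glmm & truth_glmm <= glo[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "truth_lmm") <- truth_lmm
  attr(out, "truth_glmm") <- truth_glmm
  out
}

#' Type-I error calibration under within-subject permutation
#'
#' Permutes the CVR magnitude within each subject (destroying any voxel-wise
#' association while preserving the per-subject distributions), refits both
#' mixed models, and reports the fraction of replicates with p < 0.05. A
#' calibrated test keeps that fraction near the nominal 5%.
#'
#' @param config A [sim_config()].
#' @param n_replicates Permutation replicates. Default 200.
#' @param n_subjects,n_voxels_per_subject Size of each simulated cohort.
#'   Defaults 6 and 500 (the calibration property is size-free).
#' @param seed Seed for the replicate stream.
#' @return List: `lmm_rate`, `glmm_rate`, `n_replicates`, and the p-value
#'   vectors `lmm_p`, `glmm_p`.
#' @export
null_calibration <- function(config, n_replicates = 200, n_subjects = 6,
                             n_voxels_per_subject = 500,
                             seed = config$seed) {
  cfg <- config
  cfg$n_subjects <- n_subjects
  lmm_p <- glmm_p <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    rs <- (seed + 104729 * r) %% .Machine$integer.max
    tab <- simulate_voxel_table(cfg, n_voxels_per_subject, seed = rs)
    set.seed(rs + 1)
    tab$cvr_mag <- stats::ave(tab$cvr_mag, tab$subject_id,
                              FUN = function(v) v[sample.int(length(v))])
    lmm_p[r] <- lmm_continuous(tab, "cvr_mag", "delta_md", "all_nawm")$p
    glmm_p[r] <- suppressWarnings(
      glmm_fate(tab, "conversion", "cvr_mag")$p)
  }
  list(lmm_rate = mean(lmm_p < 0.05), glmm_rate = mean(glmm_p < 0.05),
       n_replicates = n_replicates, lmm_p = lmm_p, glmm_p = glmm_p)
}
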