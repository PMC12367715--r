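#' Run the voxel-wise analysis pipeline on a subject bundle
#'
#' Convenience wrapper chaining the per-subject stages: etCO2 regressor and
#' challenge amplitude, voxel-wise CVR magnitude/dispersion fit over the
#' white matter, periventricular exclusion and tissue-fate classification,
#' and the MD change map on the analysis mask.
#'
#' @param bundle A `subject_bundle` (from [generate_subject()] or
#'   [read_cohort()]).
#' @param erosion_radius_mm WM erosion radius, mm. Default 2.
#' @param exclusion_radius_mm Periventricular dilation radius, mm.
#'   Default 6.
#' @param drift_order,tau_bounds,tau_grid Passed to [fit_volume()].
#' @return List suitable as one element of the [build_voxel_table()] input:
#'   `subject_id`, `cvr`, `fate`, `dmd`, `md_baseline`, `delta_etco2`,
#'   `age_years`, plus `regressor` and `icv_ml`.
#' @export
analyze_subject <- function(bundle, erosion_radius_mm = 2,
                            exclusion_radius_mm = 6, drift_order = 1,
                            tau_bounds = c(1, 120), tau_grid = 40) {
  stopifnot(inherits(bundle, "subject_bundle"))
  n_t <- dim(bundle$bold$data)[4]
  reg <- to_regressor(bundle$etco2, bundle$tr_s, n_t)
  cvr <- fit_volume(bundle$bold, bundle$wm_mask, reg,
                    drift_order = drift_order, tau_bounds = tau_bounds,
                    tau_grid = tau_grid)
  excl <- periventricular_exclusion(bundle$ventricle_mask,
                                    exclusion_radius_mm,
                                    bundle$voxel_size_mm)
  fate <- classify_fate(bundle$wmh_baseline, bundle$wmh_followup,
                        bundle$wm_mask, excl, erosion_radius_mm,
                        bundle$voxel_size_mm)
  dmd <- delta_md(bundle$md_baseline, bundle$md_followup,
                  fate$labels > 0)
  list(subject_id = bundle$subject_id, cvr = cvr, fate = fate, dmd = dmd,
       md_baseline = bundle$md_baseline,
       delta_etco2 = delta_etco2(bundle$etco2),
       age_years = bundle$age_years, regressor = reg,
       icv_ml = bundle$icv_ml)
}

#' Subject-level global measures from a bundle and its CVR fit
#'
#' Computes the per-timepoint global record used by the secondary analyses:
#' WMH volume, mean NAWM MD, PSMD over a skeleton stand-in (the 2 mm eroded
#' WM core by default, since tract skeletonisation is out of scope), and
#' the baseline NAWM/WMH means of the fitted CVR maps.
#'
#' @param bundle A `subject_bundle`.
#' @param fit An [analyze_subject()] result for the bundle.
#' @param skeleton_mask Optional 3D mask for the PSMD; default: WM eroded
#'   by 2 mm.
#' @return Data frame with two rows (`timepoint` = "baseline", "followup").
#' @export
compute_subject_globals <- function(bundle, fit, skeleton_mask = NULL) {
  vox_ml <- prod(bundle$voxel_size_mm) / 1000
  if (is.null(skeleton_mask))
    skeleton_mask <- erode_wm(bundle$wm_mask, 2, bundle$voxel_size_mm)
  nawm_b <- bundle$wm_mask & !bundle$wmh_baseline
  nawm_f <- bundle$wm_mask & !bundle$wmh_followup
  wmh_b <- bundle$wmh_baseline
  mag <- fit$cvr$magnitude_map
  tau <- fit$cvr$tau_map
  row <- function(tp, wmh, nawm, md) data.frame(
    subject_id = bundle$subject_id, timepoint = tp,
    wmh_ml = sum(wmh) * vox_ml,
    wmh_pct_icv = 100 * sum(wmh) * vox_ml / bundle$icv_ml,
    md_nawm_mean = mean(md[nawm]),
    psmd_nawm = psmd_from_skeleton(md, skeleton_mask & nawm),
    cvr_mag_nawm = mean(mag[nawm_b], na.rm = TRUE),
    cvr_mag_wmh = if (any(wmh_b)) mean(mag[wmh_b], na.rm = TRUE) else NA,
    tau_nawm = mean(tau[nawm_b], na.rm = TRUE),
    tau_wmh = if (any(wmh_b)) mean(tau[wmh_b], na.rm = TRUE) else NA,
    delta_etco2 = fit$delta_etco2,
    icv_ml = bundle$icv_ml, age_years = bundle$age_years)
  rbind(row("baseline", bundle$wmh_baseline, nawm_b, bundle$md_baseline),
        row("followup", bundle$wmh_followup, nawm_f, bundle$md_followup))
}
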