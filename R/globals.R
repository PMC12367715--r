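#' Peak width of skeletonised mean diffusivity (PSMD)
#'
#' Dispersion of the MD values on the white matter skeleton, computed as the
#' difference between the 95th and 5th percentiles. Percentiles use the
#' standard linear interpolation between order statistics
#' (`quantile(type = 7)`). Skeletonisation itself is an upstream concern;
#' the skeleton mask is an input.
#'
#' @param md_map 3D MD map in mm^2/s.
#' @param skeleton_mask 3D binary skeleton mask, non-empty, with finite MD
#'   everywhere on it.
#' @return PSMD in mm^2/s (scalar, `>= 0`).
#' @export
psmd_from_skeleton <- function(md_map, skeleton_mask) {
  mask <- .as_mask(skeleton_mask)
  if (!all(dim(md_map) == dim(mask)))
    stop("MD map and skeleton mask are not on a common grid")
  v <- md_map[mask]
  if (length(v) == 0) stop("empty skeleton mask")
  if (any(!is.finite(v))) stop("non-finite MD values on the skeleton")
  unname(diff(quantile(v, c(0.05, 0.95), type = 7)))
}

#' Normalise and cube-root transform a global damage measure
#'
#' WMH volumes are first normalised to intracranial volume and then
#' cube-root transformed; PSMD is cube-root transformed directly. Transforms
#' are applied per timepoint *before* longitudinal differencing, so the cube
#' root never sees a negative argument.
#'
#' @param value Non-negative measure: WMH volume (mL) or PSMD (mm^2/s).
#' @param icv_ml Intracranial volume in mL (`> 0`); required for
#'   `measure = "wmh"`.
#' @param measure `"wmh"` or `"psmd"`.
#' @return Transformed value (strictly monotone in `value`).
#' @export
normalise_and_transform <- function(value, icv_ml = NULL,
                                    measure = c("wmh", "psmd")) {
  measure <- match.arg(measure)
  if (any(value < 0)) stop("negative ", measure, " value")
  if (measure == "wmh") {
    if (is.null(icv_ml)) stop("icv_ml is required for WMH normalisation")
    if (any(icv_ml <= 0)) stop("icv_ml must be positive")
    (value / icv_ml)^(1 / 3)
  } else {
    value^(1 / 3)
  }
}

#' Per-subject longitudinal change of global damage measures
#'
#' Matches baseline and follow-up subject tables, computes per-subject
#' changes (follow-up minus baseline) of WMH volume (raw mL, % of ICV, and
#' ICV-normalised cube-root transformed), PSMD (raw and cube-root), and mean
#' NAWM MD, and summarises the cohort: median with IQR width for the skewed
#' WMH changes and mean +/- SD for the MD-based changes.
#'
#' @param globals_base,globals_follow Data frames with one row per subject
#'   and columns `subject_id`, `wmh_ml`, `icv_ml`, and optionally
#'   `psmd_nawm` (mm^2/s) and `md_nawm_mean` (mm^2/s).
#' @return List of class `longitudinal_change`: `per_subject` (data frame of
#'   deltas) and `summary` (data frame with `measure`, `center`, `spread`,
#'   `center_type`).
#' @export
longitudinal_change <- function(globals_base, globals_follow) {
  req <- c("subject_id", "wmh_ml", "icv_ml")
  stopifnot(all(req %in% names(globals_base)),
            all(req %in% names(globals_follow)))
  if (anyDuplicated(globals_base$subject_id) ||
      anyDuplicated(globals_follow$subject_id))
    stop("duplicated subject ids")
  if (!setequal(globals_base$subject_id, globals_follow$subject_id))
    stop("subject ids do not match between timepoints")
  fu <- globals_follow[match(globals_base$subject_id,
                             globals_follow$subject_id), ]
  b <- globals_base
  icv <- b$icv_ml
  per <- data.frame(
    subject_id = b$subject_id,
    delta_wmh_ml = fu$wmh_ml - b$wmh_ml,
    delta_wmh_pct_icv = 100 * (fu$wmh_ml - b$wmh_ml) / icv,
    delta_wmh_cbrt = normalise_and_transform(fu$wmh_ml, icv, "wmh") -
      normalise_and_transform(b$wmh_ml, icv, "wmh")
  )
  if (!is.null(b$psmd_nawm) && !is.null(fu$psmd_nawm)) {
    per$delta_psmd <- fu$psmd_nawm - b$psmd_nawm
    per$delta_psmd_cbrt <- normalise_and_transform(fu$psmd_nawm, NULL, "psmd") -
      normalise_and_transform(b$psmd_nawm, NULL, "psmd")
  }
  if (!is.null(b$md_nawm_mean) && !is.null(fu$md_nawm_mean))
    per$delta_md_nawm <- fu$md_nawm_mean - b$md_nawm_mean

  iqr_w <- function(x) unname(diff(quantile(x, c(0.25, 0.75), type = 7)))
  rows <- list(
    data.frame(measure = "delta_wmh_ml", center = median(per$delta_wmh_ml),
               spread = iqr_w(per$delta_wmh_ml), center_type = "median_iqr"),
    data.frame(measure = "delta_wmh_pct_icv",
               center = median(per$delta_wmh_pct_icv),
               spread = iqr_w(per$delta_wmh_pct_icv),
               center_type = "median_iqr")
  )
  for (m in c("delta_psmd", "delta_md_nawm")) {
    if (!is.null(per[[m]]))
      rows <- c(rows, list(data.frame(measure = m, center = mean(per[[m]]),
                                      spread = sd(per[[m]]),
                                      center_type = "mean_sd")))
  }
  structure(list(per_subject = per, summary = do.call(rbind, rows)),
            class = "longitudinal_change")
}
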