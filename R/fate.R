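#' @name fate-labels
#' @title Tissue fate labels
#' @description Integer codes used in fate maps: 0 `EXCLUDED`,
#'   1 `STABLE_NAWM`, 2 `NAWM_TO_WMH`, 3 `WMH_TO_NAWM`, 4 `STABLE_WMH`.
#' @keywords internal
NULL

.FATE_LEVELS <- c("EXCLUDED", "STABLE_NAWM", "NAWM_TO_WMH",
                  "WMH_TO_NAWM", "STABLE_WMH")

# Integer voxel offsets whose physical Euclidean length is <= radius_mm.
.ball_offsets <- function(radius_mm, voxel_size_mm) {
  stopifnot(radius_mm >= 0, all(voxel_size_mm > 0))
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  r <- floor(radius_mm / voxel_size_mm)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * voxel_size_mm[1])^2 + (g$dy * voxel_size_mm[2])^2 +
    (g$dz * voxel_size_mm[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

# mask translated so out[v] = mask[v + d]; out-of-bounds reads are FALSE.
.translate_mask <- function(mask, d) {
  dm <- dim(mask)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    lo <- max(1L, 1L - d[a]); hi <- min(dm[a], dm[a] - d[a])
    if (lo > hi) return(out)
    dst[[a]] <- lo:hi
    src[[a]] <- (lo + d[a]):(hi + d[a])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    mask[src[[1]], src[[2]], src[[3]]]
  out
}

.as_mask <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 3)
    stop("masks must be 3D arrays")
  array(as.logical(x > 0.5 | x == TRUE), dim(x))
}

#' Erode a white matter mask with a spherical element in physical units
#'
#' Morphological erosion with a spherical structuring element of the given
#' physical radius: a voxel survives only if every voxel offset within
#' Euclidean distance `radius_mm` (in mm, honouring anisotropic voxels) is
#' inside the mask. Voxels whose element exits the image are eroded away
#' (conservative boundary handling). Used to trim the WM boundary against
#' grey matter partial-volume and registration errors.
#'
#' @param wm_mask 3D binary array.
#' @param radius_mm Erosion radius in mm (`0` returns the input unchanged).
#' @param voxel_size_mm Voxel dimensions in mm (length 1 or 3).
#' @return 3D logical array.
#' @export
erode_wm <- function(wm_mask, radius_mm = 2, voxel_size_mm = c(1, 1, 1)) {
  m <- .as_mask(wm_mask)
  off <- .ball_offsets(radius_mm, voxel_size_mm)
  out <- m
  for (k in seq_len(nrow(off))) {
    d <- off[k, ]
    if (all(d == 0)) next
    out <- out & .translate_mask(m, d)
    if (!any(out)) break
  }
  out
}

#' Periventricular exclusion zone by spherical dilation
#'
#' Morphological dilation of the ventricle mask with a spherical structuring
#' element of physical radius `radius_mm`; returns the exclusion zone
#' (ventricles included). This removes the rim around the ventricles where
#' large subependymal veins dominate the BOLD-CVR signal.
#'
#' @param ventricle_mask 3D binary array.
#' @param radius_mm Dilation radius in mm. Default 6.
#' @param voxel_size_mm Voxel dimensions in mm (length 1 or 3).
#' @return 3D logical array.
#' @export
periventricular_exclusion <- function(ventricle_mask, radius_mm = 6,
                                      voxel_size_mm = c(1, 1, 1)) {
  m <- .as_mask(ventricle_mask)
  off <- .ball_offsets(radius_mm, voxel_size_mm)
  out <- m
  for (k in seq_len(nrow(off))) {
    d <- off[k, ]
    if (all(d == 0)) next
    out <- out | .translate_mask(m, d)
  }
  out
}

#' Classify the two-timepoint fate of every white matter voxel
#'
#' Builds the analysis mask (eroded WM minus the periventricular exclusion
#' zone) and labels each voxel in it by the 2x2 membership table of the
#' baseline and follow-up WMH masks: stable NAWM, NAWM converting to WMH,
#' WMH reverting to NAWM, or stable WMH. WM voxels outside the analysis mask
#' are `EXCLUDED`.
#'
#' @param wmh_base,wmh_follow 3D binary WMH masks at baseline and follow-up,
#'   both subsets of `wm_mask`.
#' @param wm_mask 3D binary white matter mask.
#' @param exclusion Optional 3D binary exclusion zone (e.g. from
#'   [periventricular_exclusion()]).
#' @param erosion_radius_mm WM erosion radius in mm. Default 2.
#' @param voxel_size_mm Voxel dimensions in mm (length 1 or 3).
#' @return Object of class `fate_map`: list with `labels` (3D integer array,
#'   see `.FATE_LEVELS` codes 0-4), `voxel_size_mm`, and the label `levels`.
#' @export
classify_fate <- function(wmh_base, wmh_follow, wm_mask, exclusion = NULL,
                          erosion_radius_mm = 2, voxel_size_mm = c(1, 1, 1)) {
  wm <- .as_mask(wm_mask)
  b <- .as_mask(wmh_base)
  f <- .as_mask(wmh_follow)
  if (!all(dim(b) == dim(wm)) || !all(dim(f) == dim(wm)))
    stop("masks are not on a common grid")
  n_out <- sum(b & !wm)
  if (n_out > 0)
    stop(n_out, " baseline WMH voxel(s) outside the WM mask")
  n_out <- sum(f & !wm)
  if (n_out > 0)
    stop(n_out, " follow-up WMH voxel(s) outside the WM mask")
  excl <- if (is.null(exclusion)) array(FALSE, dim(wm)) else .as_mask(exclusion)
  analysis <- erode_wm(wm, erosion_radius_mm, voxel_size_mm) & !excl
  labels <- array(0L, dim(wm))
  labels[analysis & !b & !f] <- 1L
  labels[analysis & !b & f]  <- 2L
  labels[analysis & b & !f]  <- 3L
  labels[analysis & b & f]   <- 4L
  structure(list(labels = labels,
                 voxel_size_mm = rep_len(voxel_size_mm, 3L),
                 levels = .FATE_LEVELS),
            class = "fate_map")
}

#' Tissue-fate volumes and percentages
#'
#' Summarises a fate map as volumes (mL) and percentages of the baseline
#' NAWM, the baseline WMH, and the intracranial volume, the format used to
#' report lesion conversion and reversion loads.
#'
#' @param fate_map A [classify_fate()] result.
#' @param icv_ml Intracranial volume in mL, `> 0`.
#' @return Data frame, one row per fate label (the four non-excluded
#'   labels), with `n_voxels`, `volume_ml`, `pct_baseline_nawm`,
#'   `pct_baseline_wmh`, `pct_icv`. Percentages of NAWM apply to the two
#'   NAWM-origin labels and of WMH to the two WMH-origin labels (`NA`
#'   elsewhere); each family sums to 100 when its origin class is non-empty.
#' @export
fate_volumes <- function(fate_map, icv_ml) {
  stopifnot(inherits(fate_map, "fate_map"))
  if (icv_ml <= 0) stop("icv_ml must be positive")
  vox_ml <- prod(fate_map$voxel_size_mm) / 1000
  n <- vapply(1:4, function(k) sum(fate_map$labels == k), numeric(1))
  names(n) <- .FATE_LEVELS[2:5]
  n_nawm <- n["STABLE_NAWM"] + n["NAWM_TO_WMH"]
  n_wmh <- n["WMH_TO_NAWM"] + n["STABLE_WMH"]
  from_nawm <- c(TRUE, TRUE, FALSE, FALSE)
  data.frame(
    label = .FATE_LEVELS[2:5],
    n_voxels = as.integer(n),
    volume_ml = n * vox_ml,
    pct_baseline_nawm = ifelse(from_nawm & n_nawm > 0, 100 * n / n_nawm, NA),
    pct_baseline_wmh = ifelse(!from_nawm & n_wmh > 0, 100 * n / n_wmh, NA),
    pct_icv = 100 * n * vox_ml / icv_ml,
    row.names = NULL
  )
}

#' Voxel-wise mean diffusivity change map
#'
#' Subtracts the baseline MD map from the follow-up MD map inside the
#' analysis mask. Voxels where either input is missing, non-finite or
#' non-positive (MD is strictly positive in tissue) are flagged missing with
#' a warning.
#'
#' @param md_base,md_follow 3D MD maps in mm^2/s on a common grid.
#' @param analysis_mask 3D binary mask on the same grid.
#' @return Object of class `damage_maps`: list with `delta_md` (3D array,
#'   `NA` outside the mask and at flagged voxels) and `analysis_mask`.
#' @export
delta_md <- function(md_base, md_follow, analysis_mask) {
  mask <- .as_mask(analysis_mask)
  if (!all(dim(md_base) == dim(mask)) || !all(dim(md_follow) == dim(mask)))
    stop("MD maps are not on the analysis-mask grid")
  bad <- mask & (!is.finite(md_base) | !is.finite(md_follow) |
                   md_base <= 0 | md_follow <= 0)
  if (any(bad))
    warning(sum(bad), " voxel(s) with missing or non-positive MD inside ",
            "the analysis mask were flagged missing")
  d <- array(NA_real_, dim(mask))
  use <- mask & !bad
  d[use] <- md_follow[use] - md_base[use]
  structure(list(delta_md = d, analysis_mask = mask & !bad),
            class = "damage_maps")
}
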