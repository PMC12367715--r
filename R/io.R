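#' Write a synthetic cohort to disk
#'
#' One directory per subject containing NIfTI volumes (`bold.nii.gz`,
#' `true_cvr.nii.gz`, `true_tau.nii.gz`, `wm_mask.nii.gz`,
#' `ventricle_mask.nii.gz`, `wmh_baseline.nii.gz`, `wmh_followup.nii.gz`,
#' `md_baseline.nii.gz`, `md_followup.nii.gz`) with the voxel size in the
#' header, the etCO2 trace as a two-column CSV (`time_s`, `etco2_mmHg`), and
#' at the top level a cohort `manifest.csv` recording seeds and true
#' parameters.
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory (created recursively).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  vox <- cohort$config$voxel_size_mm
  wr <- function(arr, path, tdim = NULL) {
    img <- RNifti::asNifti(arr * 1)
    RNifti::pixdim(img) <- if (is.null(tdim)) vox else c(vox, tdim)
    RNifti::writeNifti(img, path)
  }
  for (s in cohort$subjects) {
    d <- file.path(out_dir, s$subject_id)
    dir.create(d, showWarnings = FALSE)
    wr(s$bold$data, file.path(d, "bold.nii.gz"), tdim = s$tr_s)
    wr(s$true_cvr_map, file.path(d, "true_cvr.nii.gz"))
    wr(s$true_tau_map, file.path(d, "true_tau.nii.gz"))
    wr(s$wm_mask, file.path(d, "wm_mask.nii.gz"))
    wr(s$ventricle_mask, file.path(d, "ventricle_mask.nii.gz"))
    wr(s$wmh_baseline, file.path(d, "wmh_baseline.nii.gz"))
    wr(s$wmh_followup, file.path(d, "wmh_followup.nii.gz"))
    wr(s$md_baseline, file.path(d, "md_baseline.nii.gz"))
    wr(s$md_followup, file.path(d, "md_followup.nii.gz"))
    write.csv(as.data.frame(s$etco2), file.path(d, "etco2.csv"),
              row.names = FALSE)
  }
  write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.csv` and per-subject
#'   subdirectories.
#' @return List of class `cohort` (without the generating config): subject
#'   bundles with the same volume and trace elements, plus the manifest.
#' @export
read_cohort <- function(dir) {
  mf <- read.csv(file.path(dir, "manifest.csv"))
  rd <- function(path) {
    img <- RNifti::readNifti(path)
    array(as.numeric(img), dim(img))
  }
  subjects <- lapply(mf$subject_id, function(id) {
    d <- file.path(dir, id)
    bold <- RNifti::readNifti(file.path(d, "bold.nii.gz"))
    tr_s <- RNifti::pixdim(bold)[4]
    tr <- read.csv(file.path(d, "etco2.csv"))
    structure(list(
      subject_id = id,
      etco2 = etco2_trace(tr$time_s, tr$etco2_mmHg),
      bold = structure(list(data = array(as.numeric(bold), dim(bold)),
                            tr_s = tr_s), class = "bold_series"),
      true_cvr_map = rd(file.path(d, "true_cvr.nii.gz")),
      true_tau_map = rd(file.path(d, "true_tau.nii.gz")),
      wm_mask = rd(file.path(d, "wm_mask.nii.gz")) > 0.5,
      ventricle_mask = rd(file.path(d, "ventricle_mask.nii.gz")) > 0.5,
      wmh_baseline = rd(file.path(d, "wmh_baseline.nii.gz")) > 0.5,
      wmh_followup = rd(file.path(d, "wmh_followup.nii.gz")) > 0.5,
      md_baseline = rd(file.path(d, "md_baseline.nii.gz")),
      md_followup = rd(file.path(d, "md_followup.nii.gz")),
      icv_ml = mf$icv_ml[mf$subject_id == id],
      age_years = mf$age_years[mf$subject_id == id],
      voxel_size_mm = RNifti::pixdim(bold)[1:3],
      tr_s = tr_s,
      seed = mf$seed[mf$subject_id == id]
    ), class = "subject_bundle")
  })
  structure(list(subjects = subjects, config = NULL, manifest = mf),
            class = "cohort")
}
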