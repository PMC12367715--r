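#' @export
print.lmm_result <- function(x, ...) {
  cat("Linear mixed model:", x$outcome, "~", x$predictor,
      sprintf("(subset: %s)\n", x$subset))
  cat(sprintf("  beta = %.4g  [95%% CI %.4g - %.4g]  p = %.3g\n",
              x$beta, x$ci95[1], x$ci95[2], x$p))
  cat(sprintf("  %d voxels, %d subjects; random-intercept SD %.3g%s\n",
              x$n_voxels, x$n_subjects, x$random_intercept_sd,
              if (x$singular) " [singular fit]" else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.or_result <- function(x, ...) {
  cat("Logistic mixed model:", x$event, "~", x$predictor, "\n")
  cat(sprintf("  OR (%s) = %.3f  [95%% CI %.3f - %.3f]  p = %.3g\n",
              x$scaling_unit, x$odds_ratio, x$ci95[1], x$ci95[2], x$p))
  cat(sprintf("  %d voxels (%d events), %d subjects%s\n",
              x$n_voxels, x$n_events, x$n_subjects,
              if (x$singular) " [singular fit]" else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.fate_map <- function(x, ...) {
  counts <- table(factor(.FATE_LEVELS[x$labels + 1L], levels = .FATE_LEVELS))
  cat("Tissue-fate map,", paste(dim(x$labels), collapse = " x "),
      "voxels of", paste(signif(x$voxel_size_mm, 3), collapse = " x "),
      "mm\n")
  print(counts)
  invisible(x)
}

#' @export
print.cvr_maps <- function(x, ...) {
  n <- sum(!is.na(x$qc_map))
  cat("CVR maps over", n, "fitted voxels;",
      sum(x$qc_map > 0, na.rm = TRUE), "flagged by QC\n")
  cat(sprintf("  magnitude: median %.3g %%/mmHg; dispersion: median %.3g s\n",
              median(x$magnitude_map, na.rm = TRUE),
              median(x$tau_map, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration:", x$n_subjects, "subjects,",
      paste(x$grid_shape, collapse = " x "), "grid,",
      x$n_volumes, "volumes at TR", x$tr_s, "s\n")
  invisible(x)
}
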