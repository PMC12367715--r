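# Small simulation configuration used across tests: a miniature subject that
# keeps voxel-wise fits fast while preserving every structural feature of the
# default conditions.
tiny_config <- function(...) {
  args <- list(n_subjects = 3,
               grid_shape = c(16, 16, 12),
               n_volumes = 60,
               tr_s = 3,
               block_design = list(c(45, 30), c(120, 36)),
               seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Noise-free single-voxel BOLD series with known CVR and dispersion.
make_voxel_series <- function(cvr, tau, config, trace) {
  config$grid_shape <- c(1, 1, 1)
  bold <- generate_bold(array(cvr, c(1, 1, 1)), array(tau, c(1, 1, 1)),
                        trace, config)
  as.vector(bold$data)
}

# Brute-force spherical morphology oracle: per-voxel Euclidean ball test.
brute_morph <- function(mask, radius_mm, voxel_size_mm, op = c("erode", "dilate")) {
  op <- match.arg(op)
  voxel_size_mm <- rep_len(voxel_size_mm, 3)
  dm <- dim(mask)
  r <- floor(radius_mm / voxel_size_mm)
  out <- array(NA, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    vals <- logical(0)
    for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
      d <- sqrt((dx * voxel_size_mm[1])^2 + (dy * voxel_size_mm[2])^2 +
                  (dz * voxel_size_mm[3])^2)
      if (d > radius_mm + 1e-9) next
      p <- c(i + dx, j + dy, k + dz)
      inside <- all(p >= 1) && all(p <= dm)
      vals <- c(vals, if (inside) mask[p[1], p[2], p[3]] else FALSE)
    }
    out[i, j, k] <- if (op == "erode") all(vals) else any(vals)
  }
  out
}
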