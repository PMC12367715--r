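test_that("erosion matches geometric expectations", {
  cube <- array(FALSE, c(14, 14, 14))
  cube[3:12, 3:12, 3:12] <- TRUE  # solid 10^3 cube
  er <- erode_wm(cube, 2, c(1, 1, 1))
  expect_equal(sum(er), 6^3)
  expect_true(all(which(er) %in% which(cube)))
  # radius 0 is the identity
  expect_equal(erode_wm(cube, 0), cube)
  # an isolated voxel is eroded away
  single <- array(FALSE, c(7, 7, 7)); single[4, 4, 4] <- TRUE
  expect_equal(sum(erode_wm(single, 2)), 0)
})

test_that("dilation matches geometric expectations", {
  empty <- array(FALSE, c(6, 6, 6))
  expect_equal(sum(periventricular_exclusion(empty, 6)), 0)
  single <- array(FALSE, c(7, 7, 7)); single[4, 4, 4] <- TRUE
  # radius 1 at 1 mm spacing: 6-neighbourhood plus centre
  expect_equal(sum(periventricular_exclusion(single, 1)), 7)
})

test_that("erosion and dilation match the per-voxel Euclidean-ball oracle", {
  set.seed(7)
  for (case in list(list(r = 2, vox = c(1, 1, 1)),
                    list(r = 2.5, vox = c(1, 1, 2)))) {
    m <- array(runif(12^3) < 0.65, c(12, 12, 12))
    expect_equal(erode_wm(m, case$r, case$vox),
                 brute_morph(m, case$r, case$vox, "erode"))
    expect_equal(periventricular_exclusion(m, case$r, case$vox),
                 brute_morph(m, case$r, case$vox, "dilate"))
  }
})

test_that("morphology is monotone, anti-extensive / extensive", {
  set.seed(8)
  m <- array(runif(10^3) < 0.6, c(10, 10, 10))
  e1 <- erode_wm(m, 1); e2 <- erode_wm(m, 2)
  d1 <- periventricular_exclusion(m, 1); d2 <- periventricular_exclusion(m, 2)
  expect_true(all(e1 <= m)); expect_true(all(e2 <= e1))
  expect_true(all(d1 >= m)); expect_true(all(d2 >= d1))
  # closing (dilate then erode by the same radius) contains the original,
  # away from the image border where the conservative boundary rule erodes
  m2 <- array(FALSE, c(12, 12, 12))
  m2[5:8, 5:8, 5:8] <- array(runif(64) < 0.6, c(4, 4, 4))
  expect_true(all(erode_wm(periventricular_exclusion(m2, 2), 2) >= m2))
})

test_that("fate classification reproduces the membership truth table", {
  sp <- c(4, 1, 1)
  wm <- array(TRUE, sp)
  base <- array(c(FALSE, FALSE, TRUE, TRUE), sp)
  fol <- array(c(FALSE, TRUE, FALSE, TRUE), sp)
  fm <- classify_fate(base, fol, wm, erosion_radius_mm = 0)
  expect_equal(as.vector(fm$labels), 1:4)
  # unchanged lesions: only the two stable labels occur
  fm2 <- classify_fate(base, base, wm, erosion_radius_mm = 0)
  expect_setequal(unique(as.vector(fm2$labels)), c(1L, 4L))
  # lesion voxels outside WM are a hard error with a count
  wm2 <- wm; wm2[3] <- FALSE
  expect_error(classify_fate(base, fol, wm2, erosion_radius_mm = 0),
               "1 baseline WMH")
})

test_that("fate labels partition the analysis mask and match a brute-force loop", {
  set.seed(9)
  for (rep in 1:5) {
    sp <- c(12, 12, 10)
    wm <- array(runif(prod(sp)) < 0.7, sp)
    base <- wm & array(runif(prod(sp)) < 0.3, sp)
    fol <- wm & array(runif(prod(sp)) < 0.3, sp)
    vent <- array(runif(prod(sp)) < 0.02, sp)
    excl <- periventricular_exclusion(vent, 2)
    fm <- classify_fate(base, fol, wm, excl, erosion_radius_mm = 1)
    analysis <- erode_wm(wm, 1) & !excl
    # partition of the analysis mask
    expect_equal(sum(fm$labels > 0), sum(analysis))
    expect_true(all((fm$labels > 0) == analysis))
    # brute-force per-voxel classification
    expected <- array(0L, sp)
    for (i in which(analysis)) {
      expected[i] <- if (!base[i] && !fol[i]) 1L else if (!base[i]) 2L else
        if (!fol[i]) 3L else 4L
    }
    expect_equal(fm$labels, expected)
  }
})

test_that("fate classification is idempotent on its own derived masks", {
  set.seed(10)
  sp <- c(10, 10, 8)
  wm <- array(runif(prod(sp)) < 0.7, sp)
  base <- wm & array(runif(prod(sp)) < 0.4, sp)
  fol <- wm & array(runif(prod(sp)) < 0.4, sp)
  fm <- classify_fate(base, fol, wm, erosion_radius_mm = 1)
  wm2 <- fm$labels > 0
  base2 <- fm$labels %in% c(3L, 4L)
  fol2 <- fm$labels %in% c(2L, 4L)
  fm2 <- classify_fate(array(base2, sp), array(fol2, sp), wm2,
                       erosion_radius_mm = 0)
  expect_equal(fm2$labels[wm2], fm$labels[wm2])
})

test_that("fate volumes convert units and close the percentage books", {
  sp <- c(20, 10, 10)
  wm <- array(TRUE, sp)
  base <- array(FALSE, sp); base[1:5, , ] <- TRUE      # 500 lesion voxels
  fol <- array(FALSE, sp); fol[2:6, , ] <- TRUE
  fm <- classify_fate(base, fol, wm, erosion_radius_mm = 0)
  fv <- fate_volumes(fm, icv_ml = 100)
  expect_equal(fv$volume_ml[fv$label == "NAWM_TO_WMH"], 100 * 1 / 1000)
  # 100 of 1500 baseline-NAWM voxels convert
  expect_equal(fv$pct_baseline_nawm[fv$label == "NAWM_TO_WMH"],
               100 * 100 / 1500)
  expect_equal(sum(fv$pct_baseline_nawm, na.rm = TRUE), 100)
  expect_equal(sum(fv$pct_baseline_wmh, na.rm = TRUE), 100)
  expect_error(fate_volumes(fm, icv_ml = 0), "positive")
})

test_that("MD change maps equal the element-wise oracle and flag bad voxels", {
  set.seed(11)
  sp <- c(8, 8, 6)
  mask <- array(runif(prod(sp)) < 0.8, sp)
  base <- array(runif(prod(sp), 5e-4, 9e-4), sp)
  fol <- base + array(rnorm(prod(sp), 1e-5, 5e-6), sp)
  dm <- delta_md(base, fol, mask)
  expect_equal(dm$delta_md[mask], (fol - base)[mask])
  expect_true(all(is.na(dm$delta_md[!mask])))
  # identical maps -> zero change
  expect_equal(unique(delta_md(base, base, mask)$delta_md[mask]), 0)
  # non-positive MD inside the mask is flagged with a warning
  bad <- base; bad[which(mask)[1]] <- -1
  expect_warning(dmb <- delta_md(bad, fol, mask), "non-positive")
  expect_true(is.na(dmb$delta_md[which(mask)[1]]))
})
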