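test_that("p-value adjustment matches the step-down hand computation", {
  expect_equal(adjust_pvalues(0.04), 0.04)
  # Holm on (0.01, 0.02, 0.03): 3*0.01, then max(0.03, 2*0.02), then carry
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(adjust_pvalues(rep(1, 4)), rep(1, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  expect_error(adjust_pvalues(c(0.5, 1.2)))
})

test_that("paired test matches the hand t formula and flags degeneracy", {
  x <- c(6.1, 6.4, 6.0, 6.7, 6.3)
  y <- c(6.0, 6.1, 6.2, 6.2, 6.1)
  res <- paired_tests(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4))
  expect_equal(res$mean_diff, mean(d))
  # identical pairs -> degenerate, not an error
  res0 <- paired_tests(x, x)
  expect_true(res0$degenerate)
  expect_equal(res0$mean_diff, 0)
  # constant non-zero differences are degenerate too
  expect_true(paired_tests(x, x + 1)$degenerate)
  expect_error(paired_tests(1:2, 2:3), "at least 3")
})

test_that("regional ANOVA equals hand-computed mean squares and Tukey", {
  toy <- data.frame(
    subject_id = rep(1:2, 3),
    region = rep(c("STABLE_NAWM", "NAWM_TO_WMH", "STABLE_WMH"), each = 2),
    value = c(1, 2, 2, 3, 6, 7))
  res <- regional_anova(toy)
  gm <- mean(toy$value)
  ssb <- 2 * sum((c(1.5, 2.5, 6.5) - gm)^2)
  ssw <- sum((toy$value - rep(c(1.5, 2.5, 6.5), each = 2))^2)
  expect_equal(res$f, (ssb / 2) / (ssw / 3))
  expect_equal(res$df, c(2, 3))
  # Tukey studentised-range oracle for one pair (equal n = 2)
  mse <- ssw / 3
  q <- abs(6.5 - 1.5) / sqrt(mse / 2)
  i <- grep("STABLE_WMH-STABLE_NAWM", res$tukey$pair)
  expect_equal(res$tukey$p_adj[i], ptukey(q, 3, 3, lower.tail = FALSE))

  # strong separation: only pairs involving the shifted group significant
  set.seed(12)
  big <- data.frame(
    subject_id = rep(1:20, 3),
    region = rep(c("STABLE_NAWM", "NAWM_TO_WMH", "STABLE_WMH"), each = 20),
    value = c(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1), rnorm(20, 1, 0.1)))
  rb <- regional_anova(big)
  expect_lt(rb$p, 0.001)
  sig <- rb$tukey$p_adj < 0.05
  expect_equal(sig, grepl("STABLE_WMH", rb$tukey$pair))

  # identical groups: F near 0 story -> all Tukey CIs cover 0
  flat <- toy; flat$value <- c(1, 2, 1, 2, 1, 2)
  rf <- regional_anova(flat)
  expect_true(all(rf$tukey$lwr <= 0 & rf$tukey$upr >= 0))
})

test_that("Spearman association matches the tie-corrected rank formula", {
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 3, 3, 4, 6)
  res <- spearman_assoc(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)))
  # perfectly monotone pair
  expect_equal(spearman_assoc(1:6, exp(1:6))$rho, 1)
  # constant column flagged, not an error
  expect_true(!is.null(spearman_assoc(rep(1, 6), 1:6)$flag))
})

test_that("standardised univariate regressions behave on constructed data", {
  set.seed(13)
  g <- data.frame(x = rnorm(12), delta_etco2 = rnorm(12, 10, 1))
  g$y <- g$x
  r <- suppressWarnings(  # y = x is an exact fit by construction
    global_regressions(g, predictors = "x", outcomes = "y",
                       etco2_adjust = FALSE))
  expect_equal(r$beta_std, 1)
  g$cvr_like <- rnorm(12)
  r2 <- global_regressions(g, predictors = "cvr_like", outcomes = "y")
  expect_true(r2$adjusted_etco2)
  # slope of a standardised univariate fit equals the Pearson correlation
  r3 <- global_regressions(g, predictors = "x", outcomes = "cvr_like",
                           etco2_adjust = FALSE)
  expect_equal(r3$beta_std, cor(g$x, g$cvr_like))
})

test_that("voxel table round-trips map values and drops flagged voxels", {
  cfg <- tiny_config()
  s <- generate_subject(cfg, 1)
  fit <- analyze_subject(s)
  tab <- build_voxel_table(list(fit))
  expect_gt(nrow(tab), 30)
  expect_equal(tab$cvr_mag, fit$cvr$magnitude_map[tab$voxel_index])
  expect_equal(tab$tau_s, fit$cvr$tau_map[tab$voxel_index])
  expect_equal(tab$delta_md, fit$dmd$delta_md[tab$voxel_index])
  expect_true(all(tab$fate %in% c("STABLE_NAWM", "NAWM_TO_WMH",
                                  "WMH_TO_NAWM", "STABLE_WMH")))
  expect_equal(length(unique(tab$delta_etco2)), 1)
  # QC-flagged voxel (constant signal) disappears from the table
  idx <- tab$voxel_index[1]
  pos <- arrayInd(idx, cfg$grid_shape)
  s2 <- s
  s2$bold$data[pos[1], pos[2], pos[3], ] <- 1000
  fit2 <- analyze_subject(s2)
  tab2 <- build_voxel_table(list(fit2))
  expect_equal(nrow(tab2), nrow(tab) - 1)
  expect_false(idx %in% tab2$voxel_index)
})

test_that("mixed-model slope reduces to pooled OLS without subject variance", {
  cfg <- sim_config(n_subjects = 6,
                    subject_intercept_sd = c(logit = 0.3, md = 0), seed = 3)
  tab <- simulate_voxel_table(cfg, n_voxels_per_subject = 800)
  res <- suppressMessages(lmm_continuous(tab, "cvr_mag", "delta_md",
                                         "all_nawm"))
  d <- tab[tab$fate %in% c("STABLE_NAWM", "NAWM_TO_WMH"), ]
  ols <- lm(delta_md ~ cvr_mag + delta_etco2, data = d)
  expect_equal(res$beta, unname(coef(ols)["cvr_mag"]), tolerance = 1e-4)
})

test_that("permuted predictors give null slopes and odds ratios", {
  cfg <- sim_config(n_subjects = 8, seed = 14)
  tab <- simulate_voxel_table(cfg, n_voxels_per_subject = 1500)
  set.seed(15)
  tab$cvr_mag <- ave(tab$cvr_mag, tab$subject_id,
                     FUN = function(v) v[sample.int(length(v))])
  res <- lmm_continuous(tab, "cvr_mag", "delta_md", "all_nawm")
  expect_true(res$ci95[1] <= 0 && 0 <= res$ci95[2])
  orr <- suppressWarnings(glmm_fate(tab, "conversion", "cvr_mag"))
  expect_true(orr$ci95[1] <= 1 && 1 <= orr$ci95[2])
})

test_that("odds-ratio scaling is the exact power identity", {
  cfg <- sim_config(n_subjects = 6, seed = 16)
  tab <- simulate_voxel_table(cfg, n_voxels_per_subject = 800)
  o1 <- suppressWarnings(glmm_fate(tab, "conversion", "tau_s",
                                   scale_factor = 1))
  o10 <- suppressWarnings(glmm_fate(tab, "conversion", "tau_s",
                                    scale_factor = 10))
  expect_equal(o10$odds_ratio, o1$odds_ratio^10, tolerance = 1e-12)
  expect_equal(o10$ci95, o1$ci95^10, tolerance = 1e-12)
  expect_equal(o10$p, o1$p)
  # a generator with a null CVR effect on conversion refits to a null OR
  cfg0 <- sim_config(n_subjects = 8,
                     fate_logit_coefs = c(-3.2, 0, log(1.06) / 10),
                     seed = 17)
  tab0 <- simulate_voxel_table(cfg0, n_voxels_per_subject = 1500)
  or0 <- suppressWarnings(glmm_fate(tab0, "conversion", "cvr_mag"))
  expect_true(or0$ci95[1] <= 1 && 1 <= or0$ci95[2])
})

test_that("models require both outcome classes and enough subjects", {
  cfg <- sim_config(n_subjects = 4,
                    reversion_logit_coefs = c(-Inf, 0, 0), seed = 18)
  tab <- simulate_voxel_table(cfg, n_voxels_per_subject = 300)
  expect_error(suppressWarnings(glmm_fate(tab, "reversion", "cvr_mag")),
               "both outcome classes")
  one <- tab[tab$subject_id == tab$subject_id[1], ]
  expect_error(lmm_continuous(one, "cvr_mag", "delta_md"), "2 subjects")
})
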