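#' Concatenate cohort voxels into a single analysis table
#'
#' Builds the long-format cross-subject table feeding the voxel-wise mixed
#' models: one row per analysed white matter voxel with its baseline CVR
#' magnitude and dispersion, the subject-level challenge amplitude, the
#' tissue fate, baseline MD and MD change, and the participant id. Voxels
#' outside the analysis mask (fate `EXCLUDED`), QC-flagged CVR voxels, and
#' rows with non-finite values are dropped listwise.
#'
#' @param subjects List with one entry per subject, each a list with
#'   elements `subject_id`, `cvr` (a `cvr_maps` from [fit_volume()]), `fate`
#'   (a `fate_map`), `dmd` (a `damage_maps` from [delta_md()]),
#'   `md_baseline` (3D array), `delta_etco2` (scalar, mmHg), and optionally
#'   `age_years`.
#' @return Data frame with columns `subject_id`, `voxel_index` (linear index
#'   into the subject grid), `cvr_mag`, `tau_s`, `delta_etco2`, `fate`
#'   (factor), `md_baseline`, `delta_md`, and `age_years` if supplied.
#'   The attribute `n_per_subject` records retained row counts.
#' @export
build_voxel_table <- function(subjects) {
  rows <- lapply(subjects, function(s) {
    stopifnot(inherits(s$cvr, "cvr_maps"), inherits(s$fate, "fate_map"),
              inherits(s$dmd, "damage_maps"))
    sp <- dim(s$fate$labels)
    if (!all(dim(s$cvr$magnitude_map) == sp) ||
        !all(dim(s$dmd$delta_md) == sp) ||
        !all(dim(s$md_baseline) == sp))
      stop("subject ", s$subject_id, ": maps are not on a common grid")
    lab <- s$fate$labels
    keep <- lab > 0 & !is.na(s$cvr$qc_map) & s$cvr$qc_map == 0
    idx <- which(keep)
    d <- data.frame(
      subject_id = rep(s$subject_id, length(idx)),
      voxel_index = idx,
      cvr_mag = s$cvr$magnitude_map[idx],
      tau_s = s$cvr$tau_map[idx],
      delta_etco2 = rep(as.numeric(s$delta_etco2), length(idx)),
      fate = factor(.FATE_LEVELS[lab[idx] + 1L], levels = .FATE_LEVELS[2:5]),
      md_baseline = s$md_baseline[idx],
      delta_md = s$dmd$delta_md[idx]
    )
    if (!is.null(s$age_years))
      d$age_years <- rep(as.numeric(s$age_years), nrow(d))
    num <- c("cvr_mag", "tau_s", "delta_etco2", "md_baseline", "delta_md")
    d[complete.cases(d[num]), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$subject_id <- factor(out$subject_id)
  attr(out, "n_per_subject") <- table(out$subject_id)
  out
}

.subset_rows <- function(table, subset) {
  switch(subset,
         all_nawm = table[table$fate %in% c("STABLE_NAWM", "NAWM_TO_WMH"), ],
         stable_nawm = table[table$fate == "STABLE_NAWM", ],
         converting = table[table$fate == "NAWM_TO_WMH", ],
         stop("unknown subset: ", subset))
}

# Shared covariate handling: returns the fixed-effect formula terms and a
# note when the challenge-amplitude covariate is constant and dropped.
.fixed_terms <- function(table, predictor, adjust_age) {
  terms <- predictor
  flags <- character(0)
  if (var(table$delta_etco2) > 0) {
    terms <- c(terms, "delta_etco2")
  } else {
    flags <- "delta_etco2 constant across subjects; covariate dropped"
  }
  if (adjust_age) {
    if (is.null(table$age_years)) stop("age_years column missing")
    terms <- c(terms, "age_years")
  }
  list(terms = terms, flags = flags)
}

#' Voxel-concatenated linear mixed model for MD outcomes
#'
#' Random-intercept linear mixed model (REML) of a per-voxel MD outcome on a
#' baseline CVR measure, with the subject-level challenge amplitude
#' (delta-etCO2) as fixed covariate and the participant id as random
#' intercept. The reported slope carries a Wald 95% confidence interval and
#' a normal-approximation p-value, appropriate at the voxel counts these
#' models are built for.
#'
#' @param table A [build_voxel_table()] data frame (or
#'   [simulate_voxel_table()] output).
#' @param predictor `"cvr_mag"` (%/mmHg) or `"tau_s"` (s).
#' @param outcome `"delta_md"` or `"md_baseline"` (mm^2/s).
#' @param subset `"all_nawm"` (default), `"stable_nawm"`, or `"converting"`
#'   (NAWM progressing to WMH).
#' @param adjust_age Add age as an additional fixed effect (sensitivity
#'   analysis).
#' @param min_rows_per_subject Subjects contributing fewer rows are dropped
#'   with a warning. Default 10.
#' @return List of class `lmm_result`: `beta` (outcome units per predictor
#'   unit), `se`, `ci95`, `p`, `n_voxels`, `n_subjects`,
#'   `random_intercept_sd`, `residual_sd`, `singular`, `flags`, `model`.
#' @export
lmm_continuous <- function(table,
                           predictor = c("cvr_mag", "tau_s"),
                           outcome = c("delta_md", "md_baseline"),
                           subset = c("all_nawm", "stable_nawm", "converting"),
                           adjust_age = FALSE,
                           min_rows_per_subject = 10) {
  predictor <- match.arg(predictor)
  outcome <- match.arg(outcome)
  subset <- match.arg(subset)
  d <- .subset_rows(table, subset)
  counts <- table(d$subject_id)
  small <- names(counts)[counts > 0 & counts < min_rows_per_subject]
  if (length(small)) {
    warning(length(small), " subject(s) with fewer than ",
            min_rows_per_subject, " rows dropped")
    d <- d[!(d$subject_id %in% small), ]
  }
  d$subject_id <- droplevels(d$subject_id)
  if (nlevels(d$subject_id) < 2) stop("need at least 2 subjects")
  ft <- .fixed_terms(d, predictor, adjust_age)
  form <- stats::as.formula(paste(outcome, "~",
                                  paste(ft$terms, collapse = " + "),
                                  "+ (1 | subject_id)"))
  fit <- lme4::lmer(form, data = d, REML = TRUE)
  beta <- lme4::fixef(fit)[predictor]
  se <- sqrt(diag(as.matrix(vcov(fit))))[predictor]
  z <- qnorm(0.975)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    beta = unname(beta), se = unname(se),
    ci95 = unname(c(beta - z * se, beta + z * se)),
    p = unname(2 * pnorm(-abs(beta / se))),
    n_voxels = nrow(d), n_subjects = nlevels(d$subject_id),
    random_intercept_sd = vc$sdcor[vc$grp == "subject_id"][1],
    residual_sd = vc$sdcor[vc$grp == "Residual"][1],
    singular = lme4::isSingular(fit),
    flags = ft$flags,
    predictor = predictor, outcome = outcome, subset = subset,
    model = fit
  ), class = "lmm_result")
}

#' Logistic mixed model for voxel tissue fate
#'
#' Logistic mixed model (maximum likelihood, Laplace approximation) with a
#' participant random intercept and the challenge amplitude as fixed
#' covariate, for either conversion (NAWM progressing to WMH, among baseline
#' NAWM voxels) or reversion (WMH reverting to NAWM, among baseline WMH
#' voxels). The odds ratio is reported per stated predictor unit: per 1
#' %/mmHg of CVR magnitude, or per 10 s of dispersion, obtained by scaling
#' the per-unit coefficient before exponentiation (algebraically identical
#' to refitting on rescaled data). Wald intervals transform the same way.
#'
#' @param table A [build_voxel_table()] data frame.
#' @param event `"conversion"` or `"reversion"`.
#' @param predictor `"cvr_mag"` or `"tau_s"`.
#' @param scale_factor Predictor units per reported OR unit; defaults to 10
#'   for `tau_s` ("per 10 s") and 1 for `cvr_mag` ("per %").
#' @param adjust_age Add age as fixed effect.
#' @return List of class `or_result`: `odds_ratio`, `ci95`, `p`,
#'   `scaling_unit`, `coef` (per predictor unit), `se`, `n_voxels`,
#'   `n_events`, `n_subjects`, `random_intercept_sd`, `singular`, `flags`,
#'   `model`.
#' @export
glmm_fate <- function(table,
                      event = c("conversion", "reversion"),
                      predictor = c("cvr_mag", "tau_s"),
                      scale_factor = NULL,
                      adjust_age = FALSE) {
  event <- match.arg(event)
  predictor <- match.arg(predictor)
  if (is.null(scale_factor))
    scale_factor <- if (predictor == "tau_s") 10 else 1
  scaling_unit <- if (predictor == "tau_s")
    paste("per", scale_factor, "s") else
      paste("per", scale_factor, "%/mmHg")
  if (event == "conversion") {
    d <- table[table$fate %in% c("STABLE_NAWM", "NAWM_TO_WMH"), ]
    d$y <- as.integer(d$fate == "NAWM_TO_WMH")
  } else {
    d <- table[table$fate %in% c("STABLE_WMH", "WMH_TO_NAWM"), ]
    d$y <- as.integer(d$fate == "WMH_TO_NAWM")
  }
  d$subject_id <- droplevels(d$subject_id)
  if (nlevels(d$subject_id) < 2) stop("need at least 2 subjects")
  if (length(unique(d$y)) < 2)
    stop("both outcome classes must be present for the ", event, " model")
  ft <- .fixed_terms(d, predictor, adjust_age)
  # z-scale fixed-effect columns for the optimiser (tau_s lives on a ~50 s
  # scale, cvr_mag on ~0.05), then transform the coefficient back
  scales <- vapply(ft$terms, function(cn) sd(d[[cn]]), numeric(1))
  for (cn in ft$terms) d[[cn]] <- (d[[cn]] - mean(d[[cn]])) / scales[cn]
  form <- stats::as.formula(paste("y ~", paste(ft$terms, collapse = " + "),
                                  "+ (1 | subject_id)"))
  fit <- suppressMessages(
    lme4::glmer(form, data = d, family = stats::binomial, nAGQ = 1L))
  flags <- ft$flags
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$messages)) flags <- c(flags, unlist(conv$messages))
  mu <- stats::fitted(fit)
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10))
    flags <- c(flags, "fitted probabilities at 0/1: possible separation")
  b <- lme4::fixef(fit)[predictor] / scales[predictor]
  se <- sqrt(diag(as.matrix(vcov(fit))))[predictor] / scales[predictor]
  z <- qnorm(0.975)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    odds_ratio = unname(exp(b * scale_factor)),
    ci95 = unname(exp(c(b - z * se, b + z * se) * scale_factor)),
    p = unname(2 * pnorm(-abs(b / se))),
    scaling_unit = scaling_unit, scale_factor = scale_factor,
    coef = unname(b), se = unname(se),
    n_voxels = nrow(d), n_events = sum(d$y),
    n_subjects = nlevels(d$subject_id),
    random_intercept_sd = vc$sdcor[vc$grp == "subject_id"][1],
    singular = lme4::isSingular(fit),
    flags = flags, event = event, predictor = predictor,
    model = fit
  ), class = "or_result")
}

#' Per-subject regional means of a baseline CVR measure
#'
#' Mean of a CVR measure per subject within each tissue-fate region, the
#' input of the exploratory regional comparison.
#'
#' @param table A [build_voxel_table()] data frame.
#' @param measure `"cvr_mag"` or `"tau_s"`.
#' @param regions Fate regions to keep. Default: stable NAWM, NAWM
#'   converting to WMH, stable WMH.
#' @return Data frame with `subject_id`, `region` (factor), `value`.
#' @export
regional_means <- function(table, measure = c("cvr_mag", "tau_s"),
                           regions = c("STABLE_NAWM", "NAWM_TO_WMH",
                                       "STABLE_WMH")) {
  measure <- match.arg(measure)
  d <- table[table$fate %in% regions, ]
  agg <- stats::aggregate(d[[measure]],
                          by = list(subject_id = d$subject_id,
                                    region = factor(as.character(d$fate),
                                                    levels = regions)),
                          FUN = mean)
  names(agg)[3] <- "value"
  agg
}

#' One-way ANOVA across tissue-fate regions with Tukey HSD post-hoc
#'
#' Compares per-subject regional means of a baseline CVR measure between
#' tissue-fate regions with a one-way ANOVA, followed by Tukey's honestly
#' significant difference test for the pairwise comparisons. A region with
#' no observations is dropped with a warning.
#'
#' @param regional A [regional_means()] data frame (`region`, `value`).
#' @return List of class `regional_anova`: `f`, `df` (c(between, within)),
#'   `p`, and `tukey` (data frame: `pair`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
regional_anova <- function(regional) {
  regional$region <- factor(regional$region)
  present <- table(regional$region)
  absent <- names(present)[present == 0]
  if (length(absent)) {
    warning("region(s) absent in all subjects dropped: ",
            paste(absent, collapse = ", "))
    regional$region <- droplevels(regional$region)
  }
  if (nlevels(regional$region) < 2) stop("need at least 2 regions")
  if (any(table(regional$region) < 2))
    stop("need at least 2 subjects per region")
  fit <- aov(value ~ region, data = regional)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$region
  structure(list(
    f = s$`F value`[1],
    df = c(s$Df[1], s$Df[2]),
    p = s$`Pr(>F)`[1],
    tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       lwr = tk[, "lwr"], upr = tk[, "upr"],
                       p_adj = tk[, "p adj"], row.names = NULL)
  ), class = "regional_anova")
}

#' Paired t-test with mean difference
#'
#' Two-sided paired t-test for per-subject paired measures (e.g. NAWM vs WMH
#' CVR means, or baseline vs follow-up MD), reporting the mean difference
#' and its SD alongside the test. A zero-variance difference vector is
#' flagged degenerate instead of erroring.
#'
#' @param x,y Paired numeric vectors (difference taken as `x - y`), at least
#'   3 complete pairs.
#' @return List of class `paired_test`: `t`, `df`, `p`, `mean_diff`,
#'   `sd_diff`, `n`, `degenerate`.
#' @export
paired_tests <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  d <- x - y
  if (sd(d) == 0) {
    return(structure(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                          mean_diff = mean(d), sd_diff = 0,
                          n = length(d), degenerate = TRUE),
                     class = "paired_test"))
  }
  ht <- t.test(x, y, paired = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = mean(d), sd_diff = sd(d),
                 n = length(d), degenerate = FALSE),
            class = "paired_test")
}

#' Spearman rank correlation between two subject-level measures
#'
#' Tie-corrected Spearman correlation (Pearson correlation of mid-ranks)
#' with an asymptotic p-value, the test used for skewed cross-sectional
#' associations. Constant columns are flagged, not errored.
#'
#' @param x,y Numeric vectors (complete cases used), at least 5 pairs.
#' @return List: `rho`, `p`, `n`, `flag` (`NULL` or a message).
#' @export
spearman_assoc <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) stop("need at least 5 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                flag = "constant column"))
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value, n = length(x), flag = NULL)
}

#' Univariate standardised regressions of global damage change
#'
#' For each predictor/outcome pair, fits a univariate linear regression on
#' z-scored variables and reports the standardised slope with a 95%
#' confidence interval. Models with a CVR-derived predictor are additionally
#' adjusted for the challenge amplitude (`delta_etco2`), mirroring the
#' treatment of the voxel-wise models; the reported slope is always that of
#' the predictor.
#'
#' @param globals Subject-level data frame (one row per subject).
#' @param predictors Character vector of predictor column names.
#' @param outcomes Character vector of outcome column names.
#' @param etco2_adjust Logical vector (recycled) saying which predictors get
#'   the `delta_etco2` covariate; defaults to those matching `cvr|tau`.
#' @return Data frame: `outcome`, `predictor`, `beta_std`, `ci_lo`, `ci_hi`,
#'   `p`, `n`, `adjusted_etco2`, `flag`.
#' @export
global_regressions <- function(globals, predictors, outcomes,
                               etco2_adjust = NULL) {
  if (is.null(etco2_adjust))
    etco2_adjust <- grepl("cvr|tau", predictors, ignore.case = TRUE)
  etco2_adjust <- rep_len(etco2_adjust, length(predictors))
  zs <- function(v) (v - mean(v)) / sd(v)
  out <- list()
  for (oc in outcomes) for (i in seq_along(predictors)) {
    pr <- predictors[i]
    cols <- c(oc, pr, if (etco2_adjust[i]) "delta_etco2")
    d <- globals[complete.cases(globals[cols]), cols, drop = FALSE]
    flag <- NA_character_
    if (nrow(d) < 5) stop("fewer than 5 complete subjects for ", pr,
                          " -> ", oc)
    if (any(vapply(d, sd, numeric(1)) == 0)) {
      res <- data.frame(outcome = oc, predictor = pr, beta_std = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                        n = nrow(d), adjusted_etco2 = etco2_adjust[i],
                        flag = "constant column")
      out <- c(out, list(res)); next
    }
    dz <- as.data.frame(lapply(d, zs))
    form <- stats::as.formula(paste(oc, "~",
                                    paste(cols[-1], collapse = " + ")))
    fit <- lm(form, data = dz)
    b <- coef(fit)[pr]
    se <- sqrt(diag(vcov(fit)))[pr]
    tq <- qt(0.975, fit$df.residual)
    pval <- 2 * stats::pt(-abs(b / se), fit$df.residual)
    out <- c(out, list(data.frame(
      outcome = oc, predictor = pr, beta_std = unname(b),
      ci_lo = unname(b - tq * se), ci_hi = unname(b + tq * se),
      p = unname(pval), n = nrow(d), adjusted_etco2 = etco2_adjust[i],
      flag = flag)))
  }
  do.call(rbind, out)
}

#' Global association report
#'
#' Convenience wrapper combining the cross-sectional Spearman correlations
#' (baseline small vessel function vs baseline damage burden, deliberately
#' unadjusted for age) and the longitudinal standardised univariate
#' regressions of damage change on baseline function.
#'
#' @param globals Subject-level data frame.
#' @param predictors Baseline function columns. Default: NAWM CVR magnitude
#'   and dispersion.
#' @param baseline_outcomes Baseline damage columns for the Spearman part.
#' @param change_outcomes Damage-change columns for the regression part.
#' @return List: `spearman` (data frame) and `regressions` (data frame).
#' @export
global_assoc <- function(globals,
                         predictors = c("cvr_mag_nawm", "tau_nawm"),
                         baseline_outcomes = c("wmh_ml", "psmd_nawm"),
                         change_outcomes = c("delta_wmh_cbrt",
                                             "delta_psmd_cbrt")) {
  sp <- list()
  for (oc in baseline_outcomes) for (pr in predictors) {
    r <- spearman_assoc(globals[[pr]], globals[[oc]])
    sp <- c(sp, list(data.frame(outcome = oc, predictor = pr, rho = r$rho,
                                p = r$p, n = r$n,
                                flag = if (is.null(r$flag)) NA_character_
                                       else r$flag)))
  }
  list(spearman = do.call(rbind, sp),
       regressions = global_regressions(globals, predictors, change_outcomes))
}

#' Multiple-comparison adjustment of p-values
#'
#' Holm-Bonferroni step-down adjustment by default (controls the family-wise
#' error rate with no independence assumptions); Benjamini-Hochberg false
#' discovery rate optionally.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"holm"` (default) or `"BH"`.
#' @return Adjusted p-values, monotone and in `[0, 1]`.
#' @export
adjust_pvalues <- function(p, method = c("holm", "BH")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = method)
}
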