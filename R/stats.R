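# Support-condition statistics on synergy muscle weightings: stacked-response
# ("multivariate") linear mixed models with a participant random intercept,
# reference coding of the support conditions, effect coding of muscles, and
# Bonferroni control.

bilateral_order <- function() {
  tab <- muscle_channel_table()
  c(unique(tab$muscle[!is.na(tab$side)]), "ES", "RA")
}

#' Average left/right channels into 16 muscle weightings
#'
#' The 30-channel weighting vector is reduced to 16 values: the mean of the
#' left and right channel for each of the 14 bilaterally recorded muscles,
#' plus the single erector spinae (ES) and rectus abdominis (RA) weightings.
#' The order is fixed (bilateral muscles in channel order, then ES, then
#' RA); RA is last so it is the natural reference level for effect coding.
#'
#' @param w numeric vector of 30 nonnegative channel weightings.
#' @return Named numeric vector of 16 weightings.
#' @export
average_bilateral <- function(w) {
  stopifnot(length(w) == 30)
  tab <- muscle_channel_table()
  out <- vapply(bilateral_order(), function(m)
    mean(w[tab$muscle == m]), 1)
  out
}

#' Stack per-trial synergy weightings into an observation table
#'
#' One multivariate response table per synergy: 16 rows per trial (one per
#' averaged muscle) with the weighting as response, participant id, support
#' condition and muscle label. This is the stacked-response realization of
#' the multivariate mixed model.
#'
#' @param weights matrix (trials x 30) of one synergy's trial-dependent
#'   muscle weightings.
#' @param meta data frame with one row per trial: `participant`, `support`
#'   and optionally `trial_id`.
#' @return Data frame with `trials * 16` rows: `response`, `participant`,
#'   `support` (factor UA/LT/FS), `muscle` (factor, RA last), `trial_id`.
#' @export
build_observation_table <- function(weights, meta) {
  weights <- as.matrix(weights)
  stopifnot(ncol(weights) == 30, nrow(weights) == nrow(meta))
  muscles <- bilateral_order()
  rows <- lapply(seq_len(nrow(weights)), function(i) {
    w16 <- average_bilateral(weights[i, ])
    data.frame(response = unname(w16),
               participant = meta$participant[i],
               support = meta$support[i],
               muscle = muscles,
               trial_id = if (!is.null(meta$trial_id)) meta$trial_id[i] else i,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$support <- factor(tab$support, levels = c("UA", "LT", "FS"))
  tab$support <- droplevels(tab$support)
  tab$muscle <- factor(tab$muscle, levels = muscles)
  tab$participant <- factor(tab$participant)
  tab
}

lmm_coef_table <- function(fit) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tval <- est / se
  df <- stats::nobs(fit) - length(est)  # residual degrees of freedom
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             t = unname(tval), df = df,
             p = 2 * pt(-abs(unname(tval)), df),
             stringsAsFactors = FALSE)
}

#' Fit the support-only mixed model to stacked weightings
#'
#' `response ~ LT + FS + (1 | participant)` with reference (dummy) coding of
#' the support condition against the chosen reference group, a random
#' intercept per participant, and maximum-likelihood estimation. Fixed
#' effects are tested with t statistics on residual degrees of freedom
#' (two-sided).
#'
#' @param table an observation table from [build_observation_table()].
#' @param reference reference support level, `"UA"` or `"LT"`.
#' @return Object of class `lmm_fit`: `model` (`"support-only"`),
#'   `reference`, `coefficients` (term/estimate/se/t/df/p), `varcorr`
#'   (random-intercept and residual variances), `fit` (the `lmerMod`),
#'   `n_obs`.
#' @export
fit_support_lmm <- function(table, reference = c("UA", "LT")) {
  reference <- match.arg(reference)
  if (nlevels(droplevels(table$participant)) < 2)
    stop("only one participant: the random intercept is unidentifiable; ",
         "fit a fixed-effects model instead")
  if (nlevels(droplevels(factor(table$support))) < 2)
    stop("at least two support levels are required")
  table$support <- stats::relevel(droplevels(table$support), ref = reference)
  fit <- suppressMessages(
    lme4::lmer(response ~ support + (1 | participant), data = table,
               REML = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(model = "support-only", reference = reference,
                 coefficients = lmm_coef_table(fit),
                 varcorr = setNames(vc$vcov, vc$grp),
                 fit = fit, n_obs = stats::nobs(fit)),
            class = "lmm_fit")
}

#' Fit the support-by-muscle interaction mixed model
#'
#' Second-stage model `response ~ (LT + FS) * muscle + (1 | participant)`
#' with effect coding of the muscle factor (sum-to-zero contrasts with
#' rectus abdominis as the implied reference level) and reference coding of
#' the support condition, fitted by maximum likelihood. The interaction
#' t-tests identify the muscles whose weighting changes with support
#' relative to the grand mean.
#'
#' @inheritParams fit_support_lmm
#' @param alpha_corrected corrected significance level used to flag
#'   interaction terms (informational).
#' @return Object of class `lmm_fit` with `model = "support-x-muscle"` and
#'   an extra element `interactions` (the interaction-term subset of the
#'   coefficient table with a `significant` flag).
#' @export
fit_muscle_interaction_lmm <- function(table, reference = c("UA", "LT"),
                                       alpha_corrected = 0.05) {
  reference <- match.arg(reference)
  table$support <- stats::relevel(droplevels(table$support), ref = reference)
  table$muscle <- droplevels(table$muscle)
  # effect coding; the last level (RA) is the implied reference
  stats::contrasts(table$muscle) <- stats::contr.sum(nlevels(table$muscle))
  fit <- suppressMessages(
    lme4::lmer(response ~ support * muscle + (1 | participant),
               data = table, REML = FALSE))
  coefs <- lmm_coef_table(fit)
  inter <- coefs[grepl(":muscle", coefs$term, fixed = TRUE), ]
  # map contrast indices back to muscle names (levels 1..k-1 of the factor)
  lev <- levels(table$muscle)
  idx <- as.integer(sub(".*:muscle", "", inter$term))
  inter$muscle <- lev[idx]
  inter$significant <- inter$p < alpha_corrected
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(model = "support-x-muscle", reference = reference,
                 coefficients = coefs, interactions = inter,
                 varcorr = setNames(vc$vcov, vc$grp),
                 fit = fit, n_obs = stats::nobs(fit)),
            class = "lmm_fit")
}

#' Bonferroni-corrected significance level
#'
#' @param base_alpha nominal two-sided level (default 0.05).
#' @param n_tests number of tests within one movement strategy.
#' @return `base_alpha / n_tests`.
#' @export
#' @examples
#' adjust_alpha(0.05, 14)  # seven synergies, two reference groups
adjust_alpha <- function(base_alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1)
  base_alpha / n_tests
}

#' Residual diagnostics for a mixed-model fit
#'
#' Advisory numeric summaries of the model residuals: skewness, a
#' Shapiro-Wilk normality test (on a subsample when n > 5000), and a
#' Spearman association between fitted values and absolute residuals as a
#' heteroscedasticity indicator. Never used to gate the analysis.
#'
#' @param fit an `lmm_fit`.
#' @return List with `skewness`, `shapiro_w`, `shapiro_p`, `heteroscedasticity_rho`,
#'   `heteroscedasticity_p`, `n`.
#' @export
residual_diagnostics <- function(fit) {
  if (is.null(fit$fit)) stop("empty model: nothing to diagnose")
  r <- residuals(fit$fit)
  f <- fitted(fit$fit)
  skew <- mean((r - mean(r))^3) / sd(r)^3
  idx <- if (length(r) > 5000) {
    with_seed(1, sample.int(length(r), 5000))
  } else seq_along(r)
  sh <- shapiro.test(r[idx])
  het <- suppressWarnings(cor.test(f, abs(r), method = "spearman"))
  list(skewness = skew, shapiro_w = unname(sh$statistic),
       shapiro_p = sh$p.value,
       heteroscedasticity_rho = unname(het$estimate),
       heteroscedasticity_p = het$p.value, n = length(r))
}

#' Two-stage support analysis for one strategy's temporal synergies
#'
#' Stage 1: for every synergy, the support-only model is fitted twice (UA
#' and LT as reference groups) so all pairwise support contrasts are tested;
#' the significance level is Bonferroni-corrected for the
#' `2 * n_synergies` tests within the strategy. Stage 2: for synergies with
#' at least one significant support effect, the support-by-muscle
#' interaction model is fitted (at most three pairwise tests, corrected
#' accordingly) to identify which muscles drive the change.
#'
#' @param trial_weights list (one element per trial) of `n_synergies x 30`
#'   trial-dependent weighting matrices.
#' @param meta data frame with one row per trial (`participant`, `support`).
#' @param alpha base significance level.
#' @return List with `alpha_corrected_stage1`, `n_tests_stage1`, and
#'   `synergies`: per synergy, the two stage-1 fits, a `significant` flag,
#'   and (when triggered) the stage-2 interaction fit.
#' @export
analyze_support_effects <- function(trial_weights, meta, alpha = 0.05) {
  n_syn <- nrow(trial_weights[[1]])
  n_tests <- 2 * n_syn
  alpha1 <- adjust_alpha(alpha, n_tests)
  out <- vector("list", n_syn)
  for (s in seq_len(n_syn)) {
    W <- t(vapply(trial_weights, function(m) m[s, ], numeric(30)))
    tab <- build_observation_table(W, meta)
    fit_ua <- fit_support_lmm(tab, "UA")
    fit_lt <- fit_support_lmm(tab, "LT")
    support_p <- c(fit_ua$coefficients$p[grepl("^support", fit_ua$coefficients$term)],
                   fit_lt$coefficients$p[grepl("^support", fit_lt$coefficients$term)])
    signif1 <- any(support_p < alpha1)
    stage2 <- NULL
    if (signif1) {
      alpha2 <- adjust_alpha(alpha, 3)
      stage2 <- fit_muscle_interaction_lmm(tab, "UA",
                                           alpha_corrected = alpha2)
    }
    out[[s]] <- list(synergy = s, stage1_ua = fit_ua, stage1_lt = fit_lt,
                     significant = signif1, stage2 = stage2)
  }
  list(alpha_corrected_stage1 = alpha1, n_tests_stage1 = n_tests,
       synergies = out)
}
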