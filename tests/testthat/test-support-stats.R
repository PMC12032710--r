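# Mixed-model statistics on synergy muscle weightings.

test_that("bilateral averaging reduces 30 channels to 16 muscles", {
  tab <- muscle_channel_table()
  w <- rep(0, 30)
  w[tab$code == "Pec_L"] <- 0.4
  w[tab$code == "Pec_R"] <- 0.6
  out <- average_bilateral(w)
  expect_equal(unname(out["Pec"]), 0.5)
  expect_length(out, 16)
  expect_equal(names(out)[16], "RA")
  expect_equal(unname(average_bilateral(rep(3.2, 30))), rep(3.2, 16))
  # brute-force oracle: average by muscle name
  set.seed(1)
  w <- runif(30)
  oracle <- vapply(unique(tab$muscle), function(m)
    mean(w[tab$muscle == m]), 1)
  expect_equal(unname(out <- average_bilateral(w)),
               unname(oracle[names(out)]))
})

test_that("observation tables stack 16 rows per trial and round-trip", {
  set.seed(2)
  W <- matrix(runif(10 * 30), 10, 30)
  meta <- data.frame(participant = rep(c("P1", "P2"), each = 5),
                     support = rep(c("UA", "LT", "FS", "UA", "LT"), 2),
                     trial_id = 1:10)
  tab <- build_observation_table(W, meta)
  expect_equal(nrow(tab), 160)
  expect_equal(levels(tab$muscle)[16], "RA")
  for (i in c(1, 7)) {
    rows <- tab[tab$trial_id == i, ]
    expect_true(all(rows$support == meta$support[i]))
    expect_equal(rows$response, unname(average_bilateral(W[i, ])))
  }
})

test_that("support LMM reparameterizes consistently across reference groups", {
  set.seed(3)
  tab <- simulate_lmm_table(n_participants = 10, lt = 0.1, fs = 0.3)
  fit_ua <- fit_support_lmm(tab, "UA")
  fit_lt <- fit_support_lmm(tab, "LT")
  co_ua <- setNames(fit_ua$coefficients$estimate, fit_ua$coefficients$term)
  co_lt <- setNames(fit_lt$coefficients$estimate, fit_lt$coefficients$term)
  expect_equal(unname(co_lt["supportFS"]),
               unname(co_ua["supportFS"] - co_ua["supportLT"]),
               tolerance = 1e-6)
  expect_equal(unname(co_lt["supportUA"]), -unname(co_ua["supportLT"]),
               tolerance = 1e-6)
  # single participant: random intercept unidentifiable
  one <- tab[tab$participant == "P01", ]
  expect_error(fit_support_lmm(one, "UA"), "participant")
})

test_that("planted support effects are recovered with correct coverage", {
  set.seed(4)
  covered <- vapply(1:60, function(r) {
    tab <- simulate_lmm_table(n_participants = 12, fs = 0.2)
    fit <- fit_support_lmm(tab, "UA")
    co <- fit$coefficients[fit$coefficients$term == "supportFS", ]
    abs(co$estimate - 0.2) <= 1.96 * co$se
  }, TRUE)
  expect_gte(mean(covered), 0.9)
})

test_that("muscle interaction model uses effect coding with RA implied", {
  set.seed(5)
  W <- matrix(rlnorm(24 * 30, sdlog = 0.3), 24, 30)
  meta <- data.frame(participant = rep(sprintf("P%02d", 1:4), each = 6),
                     support = rep(c("UA", "UA", "LT", "LT", "FS", "FS"), 4),
                     trial_id = 1:24)
  tab <- build_observation_table(W, meta)
  fit <- fit_muscle_interaction_lmm(tab, "UA")
  # sum-to-zero contrast columns: each muscle contrast sums to 0 over the
  # 16 muscles of one trial (effect coding), with RA the dropped level
  mm <- stats::model.matrix(fit$fit)
  muscle_cols <- grep("^muscle", colnames(mm), value = TRUE)
  one_trial <- mm[1:16, muscle_cols]
  expect_equal(unname(colSums(one_trial)), rep(0, length(muscle_cols)))
  expect_equal(nrow(fit$interactions), 2 * 15)
  expect_true(all(fit$interactions$muscle %in% synergykit:::bilateral_order()))
})

test_that("planted muscle-by-support interactions are flagged", {
  tab0 <- muscle_channel_table()
  arm <- tab0$muscle %in% c("Bic", "Tri")
  hits <- vapply(1:40, function(r) {
    set.seed(100 + r)
    meta <- data.frame(participant = rep(sprintf("P%02d", 1:10), each = 6),
                       support = rep(c("UA", "UA", "LT", "LT", "FS", "FS"), 10),
                       trial_id = 1:60)
    W <- matrix(rlnorm(60 * 30, sdlog = 0.2), 60, 30)
    W[meta$support == "FS", arm] <- W[meta$support == "FS", arm] * 1.5
    tab <- build_observation_table(W, meta)
    fit <- fit_muscle_interaction_lmm(tab, "UA",
                                      alpha_corrected = adjust_alpha(0.05, 3))
    flagged <- fit$interactions$muscle[fit$interactions$significant &
                                         grepl("FS", fit$interactions$term)]
    all(c("Bic", "Tri") %in% flagged)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("Bonferroni correction divides by the number of tests", {
  expect_equal(adjust_alpha(0.05, 14), 0.05 / 14)
  expect_equal(adjust_alpha(0.05, 1), 0.05)
  expect_equal(adjust_alpha(0.05, 3), 0.05 / 3)
  expect_error(adjust_alpha(0.05, 0))
})

test_that("residual diagnostics summarize normality and heteroscedasticity", {
  set.seed(6)
  tab <- simulate_lmm_table(n_participants = 8)
  fit <- fit_support_lmm(tab, "UA")
  d <- residual_diagnostics(fit)
  expect_true(is.finite(d$skewness))
  expect_gt(d$shapiro_p, 0.01)  # Gaussian simulation: no gross violation
  # inject heteroscedasticity: noise grows with the mean
  tab2 <- simulate_lmm_table(n_participants = 12, fs = 2, eps_sd = 0.01)
  tab2$response <- tab2$response +
    rnorm(nrow(tab2), 0, 0.02 + 0.4 * (tab2$support == "FS"))
  d2 <- residual_diagnostics(fit_support_lmm(tab2, "UA"))
  expect_lt(d2$heteroscedasticity_p, 0.01)
  expect_error(residual_diagnostics(list(fit = NULL)), "empty")
})

test_that("the two-stage orchestrator gates and corrects as documented", {
  gt <- small_gt(2)
  meta <- data.frame(participant = rep(sprintf("P%02d", 1:8), each = 9),
                     support = rep(rep(c("UA", "LT", "FS"), each = 3), 8))
  trials <- lapply(seq_len(nrow(meta)), function(i)
    generate_envelope_trial(gt, "solo", meta$support[i], seed = 1000 + i))
  weights <- lapply(trials, `[[`, "weights")
  res <- analyze_support_effects(weights, meta, alpha = 0.05)
  expect_equal(res$n_tests_stage1, 4)  # 2 synergies x 2 reference groups
  expect_equal(res$alpha_corrected_stage1, 0.05 / 4)
  # the default generator plants a net upper-body load shift under FS
  expect_true(any(vapply(res$synergies, `[[`, TRUE, "significant")))
  sig <- Filter(function(s) s$significant, res$synergies)
  expect_false(is.null(sig[[1]]$stage2))
})

test_that("stage 2 localizes the support effect to both muscle groups", {
  gt_channels <- muscle_channel_table()
  upper <- unique(gt_channels$muscle[gt_channels$group == "upper_body"])
  lower <- unique(gt_channels$muscle[gt_channels$group == "lower_limb"])
  hits <- vapply(1:25, function(rep) {
    gt <- small_gt(3)
    meta <- data.frame(participant = rep(sprintf("P%02d", 1:8), each = 9),
                       support = rep(rep(c("UA", "LT", "FS"), each = 3), 8))
    weights <- lapply(seq_len(nrow(meta)), function(i)
      generate_envelope_trial(gt, "solo", meta$support[i],
                              seed = split_seed(rep, paste0("w", i)))$weights)
    res <- analyze_support_effects(weights, meta, alpha = 0.05)
    # the mid-movement (seat-transition) synergy is index 2 of 3
    st <- res$synergies[[2]]
    if (!st$significant || is.null(st$stage2)) return(FALSE)
    flagged <- st$stage2$interactions$muscle[st$stage2$interactions$significant]
    any(flagged %in% upper) && any(flagged %in% lower)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
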