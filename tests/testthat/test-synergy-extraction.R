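# NMF extraction, R^2, cross-validation, model-order selection, compactness.

test_that("strategy datasets assemble and round-trip losslessly", {
  set.seed(3)
  trials <- lapply(1:2, function(i) matrix(runif(101 * 30), 101, 30))
  ds <- build_strategy_dataset(trials, "toy")
  expect_equal(dim(ds$temporal_matrix), c(101, 60))
  expect_equal(dim(ds$spatial_matrix), c(30, 202))
  expect_identical(unstack_trials(ds, "temporal"), trials)
  expect_identical(unstack_trials(ds, "spatial"), trials)
  expect_error(build_strategy_dataset(list(matrix(0, 10, 3))), "101 x 30")
})

test_that("multivariate R^2 follows the SSE/SST definition", {
  data <- rbind(c(1, 2, 3), c(2, 2, 2))
  expect_equal(compute_r_squared(data, data), 1)
  rowmean <- matrix(rowMeans(data), 2, 3)
  expect_equal(compute_r_squared(data, rowmean), 0)
  # hand-computed toy: SSE = 0 + (1-2)^2+(2-2)^2+(3-2)^2 = 2; SST = 2
  recon <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(compute_r_squared(data, recon), 1 - 2 / 2)
  # grand-mean variant: SST about mean(data) = 2.1666..
  sst_grand <- sum((data - mean(data))^2)
  expect_equal(compute_r_squared(data, recon, center = "grand"),
               1 - 2 / sst_grand)
  expect_error(compute_r_squared(matrix(1, 2, 2), matrix(1, 2, 2)), "SST")
})

test_that("NMF solves exact low-rank problems and is deterministic", {
  profile <- bump_profile(40, 8)
  w <- runif(12) + 0.1
  V <- profile %*% t(w)
  m1 <- nmf_extract(V, 1, restarts = 5, max_iter = 500, seed = 2)
  expect_gte(m1$r2_train, 1 - 1e-6)
  expect_equal(max(m1$trial_independent), 1)
  m2 <- nmf_extract(V, 1, restarts = 5, max_iter = 500, seed = 2)
  expect_identical(m1$trial_independent, m2$trial_independent)
  # objective trace is monotone non-increasing
  expect_true(all(diff(m1$objective_trace) <= 1e-12))
  expect_error(nmf_extract(matrix(0, 10, 10), 2), "all zero")
  expect_error(nmf_extract(abs(matrix(rnorm(30), 10, 3)), 5), "n must lie")
})

test_that("NMF recovers planted profiles from noiseless multi-trial data", {
  gt <- small_gt(3)
  ds <- noiseless_dataset(gt, n_trials = 8)
  m <- nmf_extract(ds, 3, kind = "temporal", restarts = 5, max_iter = 2000,
                   seed = 3)
  C_true <- sapply(1:3, function(i)
    bump_profile(gt$strategies$solo$peaks[i], gt$strategies$solo$widths[i]))
  expect_true(all(best_pair_cosine(m$trial_independent, C_true) > 0.99))
  expect_gte(m$r2_train, 1 - 1e-4)
  # per-trial weighting blocks have the right shape
  expect_length(m$trial_dependent, 8)
  expect_equal(dim(m$trial_dependent[[1]]), c(3, 30))
})

test_that("training R^2 is non-decreasing in the number of synergies", {
  gt <- small_gt(4)
  ds <- noiseless_dataset(gt, strategy = "solo", n_trials = 6)
  r2 <- vapply(1:5, function(n)
    nmf_extract(ds, n, kind = "temporal", restarts = 3, max_iter = 500,
                seed = 7)$r2_train, 1)
  expect_true(all(diff(r2) > -1e-3))
})

test_that("fixed-factor fits match closed-form NNLS on single profiles", {
  profile <- bump_profile(30, 6)
  trial <- matrix(0, 101, 30)
  set.seed(5)
  w_true <- runif(30)
  trial <- profile %*% t(w_true)
  fit <- fit_fixed_factors(cbind(profile), list(trial), kind = "temporal")
  # 1-D NNLS: w = max(0, <c, m> / <c, c>)
  expected <- pmax(0, as.numeric(crossprod(profile, trial)) / sum(profile^2))
  expect_equal(as.numeric(fit$trial_dependent[[1]]), expected,
               tolerance = 1e-10)
  expect_gte(fit$r2, 1 - 1e-6)
  # disjoint supports: coefficient clamps to 0 and R^2 <= 0 is reported
  early <- c(bump_profile(10, 3)[1:50], rep(0, 51))
  late <- c(rep(0, 60), bump_profile(80, 3)[61:101])
  late_trial <- late %*% t(runif(30) + 0.2)
  fit2 <- fit_fixed_factors(cbind(early), list(late_trial), kind = "temporal")
  expect_true(all(fit2$trial_dependent[[1]] == 0))
  expect_lte(fit2$r2, 0)
  expect_error(fit_fixed_factors(cbind(early)[1:50, , drop = FALSE],
                                 list(late_trial), kind = "temporal"),
               "101")
})

test_that("cross-validation yields high held-out R^2 on noiseless data", {
  gt <- small_gt(3)
  ds <- noiseless_dataset(gt, n_trials = 10)
  ds$meta <- data.frame(support = rep(c("UA", "LT"), 5))
  curve <- cross_validated_curve(ds, "temporal", n_range = 1:4, folds = 5,
                                 restarts = 3, max_iter = 800, seed = 6)
  expect_gte(curve$r2_mean["3"], 0.99)
  # folds partition the trials
  expect_equal(sort(unique(curve$fold_assignment)), 1:5)
  expect_length(curve$fold_assignment, 10)
  # mean curve is non-decreasing up to noise tolerance
  expect_true(all(diff(curve$r2_mean) > -0.02))
  small <- build_strategy_dataset(ds$trials[1:4], "small")
  expect_error(cross_validated_curve(small, "temporal", folds = 5), "small")
})

test_that("knee selection finds the breakpoint of piecewise-linear curves", {
  # slopes 0.1 then 0.001 with the breakpoint at n = 6
  n <- 1:30
  curve <- ifelse(n <= 6, 0.1 * n, 0.6 + 0.001 * (n - 6))
  sel <- select_n_knee(curve)
  expect_equal(sel$n_knee, 6)
  # oracle: exhaustive MSE of the line fits, checked independently
  mse_at <- function(k) mean(residuals(lm(curve[k:30] ~ n[k:30]))^2)
  expect_true(all(vapply(1:5, mse_at, 1) >= 1e-4))
  expect_lt(mse_at(6), 1e-4)
  # perfectly linear curve: knee at 1; offsets do not change the knee
  expect_equal(select_n_knee(0.02 * n + 0.1)$n_knee, 1)
  expect_equal(select_n_knee(curve + 0.05)$n_knee, 6)
})

test_that("global/local criterion picks the documented n*", {
  # reaches 0.9 at n = 8 with small increments afterwards
  curve <- c(seq(0.35, 0.87, length.out = 7), 0.91, 0.914, 0.918,
             rep(0.92, 20))
  expect_equal(select_n_star(curve)$n_star, 8)
  # flat high curve: the jump from r2(0) = 0 fails the local criterion at 1
  flat <- rep(0.95, 30)
  expect_equal(select_n_star(flat)$n_star, 2)
  # capped below the global criterion
  expect_error(select_n_star(rep(0.85, 30)), "global")
})

test_that("compactness arithmetic matches the parameter-count definitions", {
  cs <- compactness_summary(7, 15)
  expect_equal(cs$trial_independent_temporal, 707)
  expect_equal(cs$trial_dependent_temporal, 210)
  expect_equal(cs$sum_temporal, 917)
  expect_equal(cs$trial_independent_spatial, 450)
  expect_equal(cs$trial_dependent_spatial, 1515)
  expect_equal(cs$sum_spatial, 1965)
  expect_equal(compactness_summary(6, 16)$sum_spatial, 2096)
  one <- compactness_summary(1, 1)
  expect_equal(one$sum_temporal, 131)
  expect_equal(one$sum_spatial, 131)
})

test_that("synergy-count differences aggregate with sample SD", {
  res <- compare_model_counts(c(4, 4), c(8, 10))
  expect_equal(res$mean, 5)
  expect_equal(res$sd, sd(c(4, 6)))
  expect_equal(compare_model_counts(c(3, 3, 3), c(3, 3, 3))$sd, 0)
})

test_that("model-order selection recovers the planted synergy count", {
  G <- 3
  hits <- vapply(1:25, function(rep) {
    gt <- small_gt(G)
    trials <- lapply(1:8, function(i)
      generate_envelope_trial(gt, "solo", "UA",
                              seed = split_seed(rep, paste0("t", i)))$envelope)
    ds <- build_strategy_dataset(trials, "solo")
    curve <- cross_validated_curve(ds, "temporal", n_range = 1:6, folds = 5,
                                   restarts = 2, max_iter = 300,
                                   seed = split_seed(rep, "cv"))
    sel <- tryCatch(select_n_knee(curve)$n_knee, error = function(e) NA)
    !is.na(sel) && abs(sel - G) <= 1
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
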