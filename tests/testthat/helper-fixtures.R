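# Fixtures built in code: small ground truths and profile sets reused
# across the test files.

# One-strategy ground truth with n synergies on one task.
small_gt <- function(n = 3, movement = "sit_to_stand",
                     floor = "non_challenging", name = "solo", ...) {
  strategies <- list()
  strategies[[name]] <- list(n_synergies = n, ...)
  make_ground_truth(list(tasks = list(list(
    movement = movement, floor = floor, strategies = strategies))))
}

# Matrix of unit-max Gaussian bump profiles (rows), one per peak.
bump_set <- function(peaks, width = 5) {
  t(sapply(peaks, function(p) bump_profile(p, width)))
}

# Best-pairing cosine similarity between the columns of two profile
# matrices (greedy over the similarity matrix; adequate for well-separated
# test profiles).
best_pair_cosine <- function(A, B) {
  norm_cols <- function(M) apply(M, 2, function(x) x / sqrt(sum(x^2)))
  S <- abs(crossprod(norm_cols(A), norm_cols(B)))
  apply(S, 2, max)
}

# A small noiseless strategy dataset generated from known profiles.
noiseless_dataset <- function(gt, strategy = "solo", n_trials = 8,
                              jitter_sd = 0.2, seed_base = 100) {
  trials <- lapply(seq_len(n_trials), function(i)
    generate_envelope_trial(gt, strategy, "UA", seed = seed_base + i,
                            noise_sd = 0, jitter_sd = jitter_sd)$envelope)
  build_strategy_dataset(trials, strategy)
}

# Simulate a stacked-weightings observation table from the mixed model's own
# generative process: response = intercept + lt*LT + fs*FS + u_p + eps.
simulate_lmm_table <- function(n_participants = 20, trials_per_support = 2,
                               n_muscles = 16, intercept = 1, lt = 0, fs = 0,
                               u_sd = 0.3, eps_sd = 0.2) {
  muscles <- paste0("m", seq_len(n_muscles))
  rows <- list()
  trial_id <- 0
  for (p in seq_len(n_participants)) {
    u <- rnorm(1, 0, u_sd)
    for (sup in c("UA", "LT", "FS")) {
      for (r in seq_len(trials_per_support)) {
        trial_id <- trial_id + 1
        mu <- intercept + u + lt * (sup == "LT") + fs * (sup == "FS")
        rows[[length(rows) + 1]] <- data.frame(
          response = mu + rnorm(n_muscles, 0, eps_sd),
          participant = sprintf("P%02d", p), support = sup,
          muscle = muscles, trial_id = trial_id,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$support <- factor(tab$support, levels = c("UA", "LT", "FS"))
  tab$muscle <- factor(tab$muscle, levels = muscles)
  tab$participant <- factor(tab$participant)
  tab
}
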