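# Synthetic study generator: cohorts of sit-to-stand / stand-to-sit trials
# with known ground-truth temporal synergies, planted support effects on the
# muscle weightings, and event-bearing kinetic traces.

#' Default synthetic study configuration
#'
#' Mirrors the structure of the motivating study: 20 participants, two
#' movements (sit-to-stand, stand-to-sit), two floor conditions
#' (non-challenging, challenging), three support conditions (unassisted UA,
#' light touch LT, full support FS), three repetitions per condition
#' combination (18 trials per participant and movement), and a
#' movement-strategy inventory per movement-by-floor task with synergy counts
#' (7, 6, 6), (10, 8), (8, 8, 8) and (7, 7).
#'
#' @param participants number of participants.
#' @param movements which movements to simulate.
#' @param floors which floor conditions to simulate.
#' @param level `"envelope"` (trials are 101 x 30 envelope matrices) or
#'   `"raw"` (full multirate raw recordings).
#' @return A config list accepted by [generate_cohort()].
#' @export
default_study_config <- function(participants = 20,
                                 movements = c("sit_to_stand", "stand_to_sit"),
                                 floors = c("non_challenging", "challenging"),
                                 level = c("envelope", "raw")) {
  level <- match.arg(level)
  list(
    participants = participants,
    movements = movements,
    floors = floors,
    supports = c("UA", "LT", "FS"),
    reps = 3,
    level = level,
    strategy_rule = "fixed",
    ground_truth = list(
      tasks = list(
        list(movement = "sit_to_stand", floor = "non_challenging",
             strategies = list(forward_leaning = 7, hybrid = 6, vertical_rise = 6)),
        list(movement = "sit_to_stand", floor = "challenging",
             strategies = list(exagg_forward_leaning = 10, forward_leaning_ch = 8)),
        list(movement = "stand_to_sit", floor = "non_challenging",
             strategies = list(backward_lowering = 8, hybrid_sts = 8, vertical_lowering = 8)),
        list(movement = "stand_to_sit", floor = "challenging",
             strategies = list(exagg_forward_leaning_sts = 7, forward_leaning_sts = 7))
      )
    )
  )
}

# Handle support shifts load into the arms: upper-body weightings rise
# steeply (arm muscles go from near-unloaded to weight-bearing) while
# lower-limb weightings drop moderately, so full support also changes the
# overall weighting magnitude, not just its distribution.
default_support_effects <- function() {
  list(
    UA = c(upper_body = 1, lower_limb = 1, trunk = 1),
    LT = c(upper_body = 1.3, lower_limb = 0.95, trunk = 1),
    FS = c(upper_body = 2.2, lower_limb = 0.75, trunk = 1)
  )
}

default_noise_model <- function() {
  list(
    envelope_sd = 0.03,      # additive envelope noise, fraction of trial max
    weight_jitter_sd = 0.2,  # lognormal sdlog of trial-level weighting jitter
    ecg_amplitude = 0.3,     # ECG artifact amplitude, fraction of trial max
    hum_amplitude = 0.02,    # 50 Hz hum, fraction of trial max
    heart_rate_hz = 1.2,
    baseline_frac = 0.02     # resting activity floor, fraction of trial max
  )
}

default_event_times <- function() {
  list(
    sit_to_stand = c(start = 1.0, seat = 1.5, end = 2.4),
    stand_to_sit = c(start = 1.0, seat = 1.9, end = 2.4),
    duration = 4.0
  )
}

# Widths grow towards the movement boundaries: narrow activation near the
# middle of the cycle (seat-off/seat-on region), broad at start and end.
default_profile_width <- function(peak) 4 + 7 * (abs(peak - 50) / 50)^1.5

#' Build a fully specified ground truth for the synthetic generator
#'
#' Constructs unit-maximum truncated-Gaussian activation profiles (narrower
#' near mid-movement than at the boundaries), nonnegative baseline muscle
#' weightings per synergy, multiplicative support effects per muscle group,
#' and the noise/event model that drives raw-signal synthesis.
#'
#' @param config list with element `tasks`: a list of task specs, each a list
#'   with `movement`, `floor` and `strategies` (named list mapping strategy
#'   name to a synergy count in `[1, 30]`, or to a list with elements
#'   `n_synergies` and optionally `peaks`, `widths`, `weightings`).
#'   Optional elements `support_effects`, `noise`, `events` override the
#'   defaults.
#' @param seed integer seed for the baseline-weighting draws.
#' @return An object of class `synergy_ground_truth`.
#' @export
#' @examples
#' gt <- make_ground_truth(list(tasks = list(list(
#'   movement = "sit_to_stand", floor = "non_challenging",
#'   strategies = list(solo = 3)))))
#' names(gt$strategies)
make_ground_truth <- function(config, seed = 1) {
  if (is.null(config$tasks)) stop("config$tasks must list at least one task")
  channels <- muscle_channel_table()
  strategies <- list()
  for (task in config$tasks) {
    if (is.null(task$movement) || is.null(task$floor))
      stop("each task needs 'movement' and 'floor' fields")
    for (sname in names(task$strategies)) {
      spec <- task$strategies[[sname]]
      if (is.numeric(spec)) spec <- list(n_synergies = spec)
      n <- spec$n_synergies
      if (is.null(n) || n < 1 || n > 30 || n != round(n))
        stop("strategy '", sname, "': n_synergies must be an integer in [1, 30]")
      peaks <- spec$peaks %||% seq(5, 95, length.out = n)
      widths <- spec$widths %||% default_profile_width(peaks)
      if (length(peaks) != n || length(widths) != n)
        stop("strategy '", sname, "': peaks/widths must have length n_synergies")
      if (any(widths <= 0)) stop("strategy '", sname, "': widths must be > 0")
      if (any(peaks < 0 | peaks > 100))
        stop("strategy '", sname, "': peaks must lie in [0, 100]")
      W <- spec$weightings
      if (is.null(W)) {
        # sparse nonnegative weightings: each synergy engages a muscle
        # subset, which also makes the factorization identifiable
        W <- with_seed(split_seed(seed, paste0("weights/", sname)), {
          w <- matrix(rlnorm(n * 30, meanlog = 0, sdlog = 0.7), n, 30)
          mask <- matrix(runif(n * 30) < 0.6, n, 30)
          for (ch in which(colSums(mask) == 0)) mask[sample.int(n, 1), ch] <- TRUE
          for (sy in which(rowSums(mask) == 0)) mask[sy, sample.int(30, 1)] <- TRUE
          w * mask
        })
      }
      W <- as.matrix(W)
      if (!all(dim(W) == c(n, 30)))
        stop("strategy '", sname, "': weightings must be an n x 30 matrix")
      if (any(W < 0)) stop("strategy '", sname, "': weightings must be >= 0")
      colnames(W) <- channels$code
      strategies[[sname]] <- list(
        name = sname, movement = task$movement, floor = task$floor,
        n_synergies = n, peaks = peaks, widths = widths, weightings = W
      )
    }
  }
  support <- config$support_effects %||% default_support_effects()
  for (lv in names(support)) {
    if (any(support[[lv]] <= 0)) stop("support factors must be > 0")
  }
  if (!all(support$UA == 1)) stop("unassisted (UA) support factors must all be 1")
  gt <- list(
    strategies = strategies,
    channels = channels,
    support_effects = support,
    noise = utils::modifyList(default_noise_model(), config$noise %||% list()),
    events = utils::modifyList(default_event_times(), config$events %||% list()),
    body = list(mass_kg = 67.6, height_m = 1.71, seat_weight_frac = 0.7),
    seed = seed
  )
  class(gt) <- "synergy_ground_truth"
  gt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gt_profiles <- function(gt, strategy) {
  st <- gt$strategies[[strategy]]
  if (is.null(st)) stop("unknown strategy '", strategy, "'")
  sapply(seq_len(st$n_synergies),
         function(i) bump_profile(st$peaks[i], st$widths[i]))
}

#' Generate one envelope-level trial from ground truth
#'
#' Realizes the temporal synergy model `M = sum_n C_n w_n` for one trial:
#' the strategy's activation profiles are combined with baseline weightings
#' scaled by the muscle-group support factors and trial-level lognormal
#' jitter (unit mean), additive Gaussian noise is applied, and the result is
#' clipped at zero.
#'
#' @param gt a `synergy_ground_truth`.
#' @param strategy strategy name in `gt$strategies`.
#' @param support one of `"UA"`, `"LT"`, `"FS"`.
#' @param seed integer seed for this trial's draws.
#' @param noise_sd,jitter_sd overrides for the ground truth noise model
#'   (set both to 0 for an exactly rank-`n` noiseless trial).
#' @return List with `envelope` (101 x 30), `weights` (the realized n x 30
#'   trial weightings), `profiles` (101 x n), `strategy`, `support`.
#' @export
generate_envelope_trial <- function(gt, strategy, support, seed,
                                    noise_sd = NULL, jitter_sd = NULL) {
  st <- gt$strategies[[strategy]]
  if (is.null(st)) stop("unknown strategy '", strategy, "'")
  if (!support %in% names(gt$support_effects))
    stop("unknown support level '", support, "'")
  noise_sd <- noise_sd %||% gt$noise$envelope_sd
  jitter_sd <- jitter_sd %||% gt$noise$weight_jitter_sd
  C <- gt_profiles(gt, strategy)                       # 101 x n
  fac <- gt$support_effects[[support]][gt$channels$group]  # length 30
  with_seed(seed, {
    jit <- if (jitter_sd > 0) {
      matrix(rlnorm(st$n_synergies * 30, meanlog = -jitter_sd^2 / 2,
                    sdlog = jitter_sd), st$n_synergies, 30)
    } else {
      matrix(1, st$n_synergies, 30)
    }
    W <- st$weightings * matrix(fac, st$n_synergies, 30, byrow = TRUE) * jit
    M <- C %*% W
    if (noise_sd > 0) {
      # noise scales with each channel's own activity range
      ch_scale <- pmax(apply(M, 2, max), 1e-12)
      M <- M + matrix(rnorm(length(M)), nrow(M), ncol(M)) *
        matrix(noise_sd * ch_scale, nrow(M), ncol(M), byrow = TRUE)
    }
    M[M < 0] <- 0
    colnames(M) <- gt$channels$code
    list(envelope = M, weights = W, profiles = C,
         strategy = strategy, support = support)
  })
}

# QRS-like artifact waveform on a time axis centered at 0 (seconds).
ecg_waveform <- function(t) {
  -0.15 * exp(-0.5 * ((t + 0.025) / 0.008)^2) +
    exp(-0.5 * (t / 0.006)^2) -
    0.2 * exp(-0.5 * ((t - 0.03) / 0.010)^2)
}

# Trapezoidal velocity profile over [t0, t1] (ramp fraction of duration),
# scaled so the integral equals `delta`.
trapezoid_displacement <- function(t, t0, t1, delta, ramp = 0.1) {
  dur <- t1 - t0
  r <- min(ramp, dur / 3)
  v <- rep(0, length(t))
  u <- t - t0
  inside <- u >= 0 & u <= dur
  vu <- pmin(pmin(u / r, 1), pmin((dur - u) / r, 1))
  v[inside] <- pmax(vu[inside], 0)
  # cumulative integral, then scale to delta
  dt <- c(0, diff(t))
  pos <- cumsum(v * dt)
  if (max(pos) > 0) pos <- pos / max(pos) * delta
  pos
}

#' Generate one raw multirate recording from ground truth
#'
#' Synthesizes what the measurement chain would record for one trial: each
#' EMG channel is a zero-mean band-limited (20-450 Hz) noise carrier
#' amplitude-modulated by the trial's envelope mapped onto wall-clock time
#' between the configured events, plus 50 Hz hum; trunk channels (ES, RA)
#' additionally carry periodic QRS-shaped ECG artifacts. Vertical ground
#' reaction force, seat force and vertical CoM position follow
#' piecewise-smooth templates consistent with the configured event times.
#' Upper-body and trunk channels are sampled at 1500 Hz, lower-limb channels
#' at 4000 Hz (two acquisition-system rate groups).
#'
#' @inheritParams generate_envelope_trial
#' @param movement `"sit_to_stand"` or `"stand_to_sit"`; defaults to the
#'   strategy's movement.
#' @param ecg_amplitude,hum_amplitude,noise_sd,jitter_sd noise-model
#'   overrides (fractions of the trial envelope maximum).
#' @return An object of class `raw_trial`: `emg` (list of 30 numeric
#'   vectors), `emg_rates`, `grf`, `seat_force`, `com` (each a list with
#'   `x` and `rate`), `events` (true event times, seconds), `envelope`
#'   (the generating 101 x 30 envelope), `true_weights`, `meta`.
#' @export
generate_raw_recording <- function(gt, strategy, support, seed,
                                   movement = NULL,
                                   ecg_amplitude = NULL, hum_amplitude = NULL,
                                   noise_sd = NULL, jitter_sd = NULL) {
  st <- gt$strategies[[strategy]]
  if (is.null(st)) stop("unknown strategy '", strategy, "'")
  movement <- movement %||% st$movement
  env_trial <- generate_envelope_trial(gt, strategy, support,
                                       split_seed(seed, "envelope"),
                                       noise_sd = noise_sd, jitter_sd = jitter_sd)
  ev <- gt$events[[movement]]
  duration <- gt$events$duration
  # hum, resting floor and ECG amplitudes scale with each channel's own
  # activity so weak muscles are not drowned by a global scale
  ecg_frac <- ecg_amplitude %||% gt$noise$ecg_amplitude
  hum_frac <- hum_amplitude %||% gt$noise$hum_amplitude
  ch_max <- pmax(apply(env_trial$envelope, 2, max), 1e-12)
  rates <- ifelse(gt$channels$group == "lower_limb", 4000, 1500)
  grid_times <- seq(ev["start"] - 0.2, ev["end"], length.out = 101)

  emg <- vector("list", 30)
  with_seed(split_seed(seed, "raw"), {
    beat_period <- 1 / gt$noise$heart_rate_hz
    beat_offset <- runif(1, 0, beat_period)
    beat_times <- seq(beat_offset, duration, by = beat_period)
    for (ch in 1:30) {
      rate <- rates[ch]
      n <- round(duration * rate)
      t <- (seq_len(n) - 1) / rate
      modulator <- approx(grid_times, env_trial$envelope[, ch], xout = t,
                          rule = 2)$y
      modulator <- pmax(modulator, gt$noise$baseline_frac * ch_max[ch])
      band <- c(20, min(450, 0.45 * rate))
      carrier <- zerophase_butter(rnorm(n), rate, band, type = "pass")
      carrier <- carrier / max(sqrt(mean(carrier^2)), .Machine$double.eps)
      x <- carrier * modulator + hum_frac * ch_max[ch] * sin(2 * pi * 50 * t)
      if (gt$channels$group[ch] == "trunk" && ecg_frac > 0) {
        ecg_amp <- ecg_frac * ch_max[ch]
        for (bt in beat_times) {
          idx <- which(abs(t - bt) <= 0.08)
          x[idx] <- x[idx] + ecg_amp * ecg_waveform(t[idx] - bt)
        }
      }
      emg[[ch]] <- x
    }

    weight_n <- gt$body$mass_kg * 9.81
    seat_sitting <- gt$body$seat_weight_frac * weight_n
    mk <- function(rate, f, noise) {
      n <- round(duration * rate)
      t <- (seq_len(n) - 1) / rate
      list(x = f(t) + rnorm(n, sd = noise), rate = rate)
    }
    if (movement == "sit_to_stand") {
      seat_f <- function(t) seat_sitting * (1 - smoothstep(t, ev["start"], ev["seat"]))
      grf_f <- function(t) weight_n - seat_f(t) +
        0.08 * weight_n * exp(-0.5 * ((t - ev["seat"]) / 0.12)^2)
      com_f <- function(t) 0.75 + trapezoid_displacement(t, ev["start"], ev["end"], 0.20)
    } else {
      seat_f <- function(t) seat_sitting * smoothstep(t, ev["seat"], ev["end"])
      grf_f <- function(t) weight_n - seat_f(t) +
        0.08 * weight_n * exp(-0.5 * ((t - ev["seat"]) / 0.12)^2)
      com_f <- function(t) 0.95 - trapezoid_displacement(t, ev["start"], ev["end"], 0.20)
    }
    grf <- mk(1000, grf_f, 1.5)
    seat <- mk(142, seat_f, 0.8)
    com <- mk(150, com_f, 0.0005)

    out <- list(
      emg = emg, emg_rates = rates,
      grf = grf, seat_force = seat, com = com,
      events = c(movement_start = unname(ev["start"]),
                 seat_transition = unname(ev["seat"]),
                 movement_end = unname(ev["end"])),
      envelope = env_trial$envelope,
      true_weights = env_trial$weights,
      meta = list(strategy = strategy, support = support, movement = movement,
                  floor = st$floor)
    )
    class(out) <- "raw_trial"
    out
  })
}

#' Generate a synthetic study cohort
#'
#' Emits `participants x reps x supports x floors` trials per movement with a
#' per-participant movement-strategy assignment, either fixed per
#' participant-by-task (default, each participant keeps one strategy for all
#' supports and repetitions of a task) or re-drawn per support condition
#' (`strategy_rule = "per_support"`), emulating strategy switching under
#' rollator support.
#'
#' @param config configuration list as produced by [default_study_config()];
#'   `config$ground_truth` may be a ready-made `synergy_ground_truth` or a
#'   config list for [make_ground_truth()].
#' @param seed master integer seed.
#' @return List with `trials` (list of trial objects; envelope-level trials
#'   carry `envelope`, `weights`, `meta`), `metadata` (one row per trial) and
#'   `ground_truth`.
#' @export
#' @examples
#' cfg <- default_study_config(participants = 1, movements = "sit_to_stand",
#'                             floors = "non_challenging")
#' cohort <- generate_cohort(cfg, seed = 7)
#' nrow(cohort$metadata)  # 9: 3 supports x 3 reps, one movement, one floor
generate_cohort <- function(config, seed) {
  gt <- config$ground_truth
  if (!inherits(gt, "synergy_ground_truth")) {
    gt <- make_ground_truth(gt, seed = split_seed(seed, "ground_truth"))
  }
  level <- config$level %||% "envelope"
  supports <- config$supports %||% c("UA", "LT", "FS")
  reps <- config$reps %||% 3
  rule <- config$strategy_rule %||% "fixed"
  trials <- list()
  meta <- list()
  trial_id <- 0L
  for (p in seq_len(config$participants)) {
    pid <- sprintf("P%02d", p)
    for (movement in config$movements) {
      for (floor in config$floors) {
        task_strats <- names(Filter(function(s)
          s$movement == movement && s$floor == floor, gt$strategies))
        if (length(task_strats) == 0)
          stop("ground truth has no strategies for ", movement, " / ", floor)
        fixed_strat <- with_seed(
          split_seed(seed, paste("strategy", pid, movement, floor)),
          sample(task_strats, 1))
        for (support in supports) {
          strat <- if (rule == "per_support") {
            with_seed(split_seed(seed, paste("strategy", pid, movement,
                                             floor, support)),
                      sample(task_strats, 1))
          } else fixed_strat
          for (rep in seq_len(reps)) {
            trial_id <- trial_id + 1L
            tseed <- split_seed(seed, paste("trial", pid, movement, floor,
                                            support, rep))
            trial <- if (level == "raw") {
              generate_raw_recording(gt, strat, support, tseed)
            } else {
              generate_envelope_trial(gt, strat, support, tseed)
            }
            trial$meta <- utils::modifyList(trial$meta %||% list(), list(
              trial_id = trial_id, participant = pid, movement = movement,
              floor = floor, support = support, rep = rep, strategy = strat))
            trials[[trial_id]] <- trial
            meta[[trial_id]] <- data.frame(
              trial_id = trial_id, participant = pid, movement = movement,
              floor = floor, support = support, rep = rep, strategy = strat,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  list(trials = trials, metadata = do.call(rbind, meta), ground_truth = gt)
}
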