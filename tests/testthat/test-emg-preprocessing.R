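# Preprocessing chain: filters, ECG template subtraction, event detection,
# segmentation, amplitude normalization.

test_that("band-pass/notch filter attenuates mains and sub-band content", {
  rate <- 1500
  t <- (0:(4 * rate - 1)) / rate
  rms <- function(x) sqrt(mean(x^2))
  mains <- sin(2 * pi * 50 * t)
  expect_lt(rms(bandpass_notch_filter(mains, rate)), 0.05 * rms(mains))
  slow <- sin(2 * pi * 5 * t)
  expect_lt(rms(bandpass_notch_filter(slow, rate)), 0.10 * rms(slow))
  # passband content survives
  mid <- sin(2 * pi * 120 * t)
  expect_gt(rms(bandpass_notch_filter(mid, rate)), 0.9 * rms(mid))
  # zero lag: a symmetric pulse keeps its peak position
  pulse <- exp(-0.5 * ((seq_along(t) - 3000) / 8)^2) * sin(2 * pi * 100 * t)
  expect_lt(abs(which.max(abs(bandpass_notch_filter(pulse, rate))) - 3000), 10)
  expect_error(bandpass_notch_filter(mains, 900), "1000")
})

test_that("zero-lag filtering commutes with time reversal on the interior", {
  set.seed(4)
  rate <- 1500
  x <- rnorm(8 * rate)
  # symmetric-passband band-pass: essentially exact away from the ends
  f1 <- synergykit:::zerophase_butter(x, rate, c(20, 500), "pass")
  f2 <- rev(synergykit:::zerophase_butter(rev(x), rate, c(20, 500), "pass"))
  idx <- (rate %/% 2):(length(x) - rate %/% 2)
  expect_lt(max(abs(f1[idx] - f2[idx])) / max(abs(f1)), 1e-8)
  # full chain including the ringing notch: interior beyond the ring-in
  g1 <- bandpass_notch_filter(x, rate)
  g2 <- rev(bandpass_notch_filter(rev(x), rate))
  idx <- (2 * rate):(length(x) - 2 * rate)
  expect_lt(max(abs(g1[idx] - g2[idx])) / max(abs(g1)), 1e-8)
})

test_that("ECG template building detects planted periodic artifacts", {
  rate <- 1000
  set.seed(7)
  n <- 60 * rate
  t <- (0:(n - 1)) / rate
  noise <- rnorm(n)
  beat_t <- seq(0.5, 59.5, by = 1)  # exactly 1 Hz
  artifact <- rep(0, n)
  for (bt in beat_t) {
    idx <- which(abs(t - bt) <= 0.06)
    artifact[idx] <- artifact[idx] + 5 * synergykit:::ecg_waveform(t[idx] - bt)
  }
  tpl <- build_ecg_template(noise + artifact, rate)
  detected_rate <- 1 / median(diff(tpl$beat_times[[1]]))
  expect_lt(abs(detected_rate - 1), 0.02)
  # essentially all planted beats are found
  expect_gte(tpl$n_beats, 58)
  expect_lte(tpl$n_beats, 66)
  # template shape resembles the injected waveform
  half <- (length(tpl$template) - 1) / 2
  shape <- 5 * synergykit:::ecg_waveform(((-half):half) / rate)
  expect_gt(cor(tpl$template, shape), 0.9)
  # nothing to detect
  expect_error(build_ecg_template(rnorm(40 * rate), rate), "beats")
  # too short for a stable template
  expect_error(build_ecg_template(rnorm(5 * rate), rate), "duration")
})

test_that("template subtraction removes injected artifact energy", {
  rate <- 1000
  set.seed(8)
  n <- 30 * rate
  clean <- as.numeric(stats::filter(rnorm(n), rep(0.2, 5), sides = 2))
  clean[is.na(clean)] <- 0
  half <- round(0.06 * rate)
  template <- 4 * synergykit:::ecg_waveform(((-half):half) / rate)
  beat_times <- seq(1, 29, by = 0.9)
  x <- clean
  for (bt in beat_times) {
    i <- round(bt * rate) + 1
    x[(i - half):(i + half)] <- x[(i - half):(i + half)] + template
  }
  cleaned <- remove_ecg_artifacts(x, template, beat_times, rate)
  injected_energy <- sum((x - clean)^2)
  residual_energy <- sum((cleaned - clean)^2)
  expect_lte(residual_energy, 0.1 * injected_energy)
  # no-op cases
  expect_identical(remove_ecg_artifacts(x, template, numeric(0), rate), x)
  expect_identical(remove_ecg_artifacts(x, rep(0, length(template)),
                                        beat_times, rate), x)
})

test_that("rectify-and-smooth is a full-wave envelope", {
  rate <- 1500
  x <- rep(0.7, 3 * rate)
  env <- rectify_and_smooth(x, rate)
  expect_equal(env[rate:(2 * rate)], rep(0.7, rate + 1), tolerance = 1e-6)
  set.seed(2)
  y <- rnorm(3 * rate)
  expect_equal(rectify_and_smooth(y, rate), rectify_and_smooth(-y, rate))
  expect_true(all(rectify_and_smooth(y, rate) >= 0))
  expect_error(rectify_and_smooth(y, 10), "20")
})

test_that("event detection recovers the true events within 0.1 s", {
  gt <- small_gt(3)
  errs <- t(vapply(1:10, function(s) {
    raw <- generate_raw_recording(gt, "solo", "UA", seed = s)
    pt <- preprocess_raw_trial(raw, skip_ecg = TRUE, seed = s + 50)
    c(pt$events$movement_start, pt$events$seat_transition,
      pt$events$movement_end)
  }, numeric(3)))
  truth <- c(1.0, 1.5, 2.4)
  expect_lt(max(abs(sweep(errs, 2, truth))), 0.1)
})

test_that("event detection errors on still signals and shifts with time", {
  still <- list(x = rep(100, 400), rate = 100)
  expect_error(detect_events(still, still, list(x = rep(0.8, 400), rate = 100),
                             "sit_to_stand"), "no movement")
  gt <- small_gt(2)
  raw <- generate_raw_recording(gt, "solo", "LT", seed = 6)
  lp <- function(s) list(x = synergykit:::zerophase_butter(s$x, s$rate, 10,
                                                           type = "low"),
                         rate = s$rate)
  e0 <- detect_events(lp(raw$grf), lp(raw$seat_force), lp(raw$com),
                      "sit_to_stand", t0 = 0, seed = 5)
  e1 <- detect_events(lp(raw$grf), lp(raw$seat_force), lp(raw$com),
                      "sit_to_stand", t0 = 1.25, seed = 5)
  expect_equal(e1$movement_start - e0$movement_start, 1.25)
  expect_equal(e1$movement_end - e0$movement_end, 1.25)
  expect_equal(e0$pre_window, 0.2)
})

test_that("segmentation resamples each channel onto the 101-point grid", {
  events <- structure(list(movement_start = 1.0, seat_transition = 1.5,
                           movement_end = 2.4, pre_window = 0.2),
                      class = "event_times")
  rate <- c(1500, 4000)
  t1 <- (0:(4 * rate[1] - 1)) / rate[1]
  t2 <- (0:(4 * rate[2] - 1)) / rate[2]
  # constant channel stays constant; a linear ramp is interpolated exactly
  out <- segment_and_normalize_time(list(rep(2.5, length(t1)), 3 * t2 + 1),
                                    rate, events)
  expect_equal(nrow(out), 101)
  expect_equal(out[, 1], rep(2.5, 101), tolerance = 1e-9)
  grid <- seq(0.8, 2.4, length.out = 101)
  expect_equal(out[, 2], 3 * grid + 1, tolerance = 1e-9)
  # window exceeding the recording errors
  bad <- structure(list(movement_start = 0.1, seat_transition = 0.5,
                        movement_end = 2.0, pre_window = 0.2),
                   class = "event_times")
  expect_error(segment_and_normalize_time(list(rep(1, 100)), 100, bad),
               "exceeds")
})

test_that("amplitude normalization is per muscle and participant", {
  set.seed(10)
  trials <- lapply(1:4, function(i) matrix(runif(101 * 30), 101, 30))
  trials[[1]][, 5] <- 0; trials[[2]][, 5] <- 0
  trials[[3]][, 5] <- 0; trials[[4]][, 5] <- 0
  nrm <- normalize_amplitude(trials)
  maxima <- Reduce(pmax, lapply(nrm$envelopes, function(m) apply(m, 2, max)))
  expect_equal(unname(maxima[-5]), rep(1, 29))
  expect_true(nrm$flagged[5])
  # scale invariance: scaling all trials by 3 changes nothing
  nrm3 <- normalize_amplitude(lapply(trials, function(m) 3 * m))
  expect_equal(nrm3$envelopes, nrm$envelopes, tolerance = 1e-12)
  # single trial: that muscle's max becomes exactly 1
  one <- normalize_amplitude(trials[1])
  expect_equal(max(one$envelopes[[1]][, 7]), 1)
})

test_that("end-to-end preprocessing tracks the generating envelopes", {
  cfg <- default_study_config(participants = 1, movements = "sit_to_stand",
                              floors = "non_challenging", level = "raw")
  cfg$ground_truth <- list(tasks = list(list(
    movement = "sit_to_stand", floor = "non_challenging",
    strategies = list(solo = 3))))
  cohort <- generate_cohort(cfg, seed = 4)
  pp <- preprocess_cohort(cohort, seed = 11)
  pool_proc <- do.call(rbind, lapply(pp$trials, `[[`, "envelope"))
  pool_true <- do.call(rbind, lapply(cohort$trials, `[[`, "envelope"))
  cors <- vapply(1:30, function(ch) cor(pool_proc[, ch], pool_true[, ch]), 1)
  expect_gt(min(cors), 0.9)
  # idempotence: re-running yields identical processed trials
  pp2 <- preprocess_cohort(cohort, seed = 11)
  expect_identical(pp$trials[[1]]$envelope, pp2$trials[[1]]$envelope)
})
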