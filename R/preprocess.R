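# EMG preprocessing: zero-lag Butterworth filtering, ECG-artifact template
# subtraction, envelope computation, kinetic event detection, segmentation to
# the 101-point time-normalized grid, and amplitude normalization.

# Forward-backward filtering with odd-reflection end padding (absorbs filter
# start-up transients; the pad length grows with the filter's ring time).
zerophase_filter <- function(filt, x, pad = NULL) {
  b <- filt$b
  a <- filt$a
  nfilt <- max(length(a), length(b))
  if (is.null(pad)) pad <- 12 * (nfilt - 1)
  pad <- min(pad, length(x) - 1)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)])
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + length(x))]
}

# Butterworth design + zero-lag application. `order` is the order of the
# underlying one-pass filter; forward-backward application doubles it, so
# order = 2 realizes a 4th-order zero-lag response.
zerophase_butter <- function(x, rate, band, type = c("pass", "low", "high", "stop"),
                             order = 2, pad = NULL) {
  type <- match.arg(type)
  W <- band / (rate / 2)
  filt <- signal::butter(order, W, type = type)
  zerophase_filter(filt, x, pad = pad)
}

#' Band-pass and notch filter raw EMG
#'
#' 20-500 Hz band-pass plus 50 Hz notch (implemented as a narrow 49-51 Hz
#' band-stop), both Butterworth filters applied forward-backward so the net
#' response is 4th-order with zero phase lag. Output length equals input
#' length.
#'
#' @param x numeric sample series.
#' @param rate sampling rate in Hz; must exceed 1000 Hz so the 500 Hz band
#'   edge is below Nyquist.
#' @param band band-pass edges in Hz.
#' @param notch notch center frequency in Hz (half-width 1 Hz).
#' @return Filtered series, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 1500)
#' mains <- sin(2 * pi * 50 * t)
#' filtered <- bandpass_notch_filter(mains, 1500)
#' sqrt(mean(filtered^2))  # strongly attenuated
bandpass_notch_filter <- function(x, rate, band = c(20, 500), notch = 50) {
  if (rate <= 1000)
    stop("sampling rate must exceed 1000 Hz for a 500 Hz band edge, got ", rate)
  y <- zerophase_butter(x, rate, band, type = "pass")
  # narrow band-stop needs a long pad: its impulse response rings ~rate/BW
  zerophase_butter(y, rate, c(notch - 1, notch + 1), type = "stop",
                   pad = min(length(x) - 1, 2 * rate))
}

#' Build an ECG artifact template from trunk EMG recordings
#'
#' Detects QRS-like events by peak-picking on a smoothed rectified signal
#' with a refractory period, then averages beat-aligned windows into a
#' muscle- and participant-specific template.
#'
#' @param signals a numeric vector or list of filtered trunk-channel series
#'   (e.g. all of one participant's trials for one muscle).
#' @param rate sampling rate in Hz (common to all series).
#' @param min_duration minimum total signal duration in seconds required for
#'   a stable template.
#' @param refractory minimum inter-beat interval in seconds.
#' @param window template half-width in seconds around the detected peak.
#' @param threshold detection threshold in robust SD units of the smoothed
#'   rectified signal.
#' @return List with `template` (numeric vector of `2 * window * rate + 1`
#'   samples), `beat_times` (list of beat times in seconds, one element per
#'   input series), `rate`, `n_beats`.
#' @export
build_ecg_template <- function(signals, rate, min_duration = 30,
                               refractory = 0.4, window = 0.06,
                               threshold = 3.5) {
  if (is.numeric(signals)) signals <- list(signals)
  total_dur <- sum(vapply(signals, length, 1L)) / rate
  if (total_dur < min_duration)
    stop("total signal duration ", round(total_dur, 1),
         " s is below the ", min_duration, " s required for a stable template")
  half <- round(window * rate)
  refr <- round(refractory * rate)
  smooth_n <- max(3, round(0.05 * rate))
  beat_idx <- vector("list", length(signals))
  beat_height <- vector("list", length(signals))
  for (si in seq_along(signals)) {
    x <- signals[[si]]
    env <- as.numeric(stats::filter(abs(x), rep(1 / smooth_n, smooth_n),
                                    sides = 2))
    env[is.na(env)] <- 0
    thr <- median(env) + threshold * mad(env)
    cand <- which(env > thr)
    # greedy peak picking with refractory period
    beats <- integer(0)
    cand <- cand[order(env[cand], decreasing = TRUE)]
    for (i in cand) {
      if (all(abs(i - beats) > refr)) beats <- c(beats, i)
    }
    beats <- sort(beats)
    heights <- env[beats]
    # refine to the local rectified maximum
    beats <- vapply(beats, function(i) {
      lo <- max(1L, i - half)
      hi <- min(length(x), i + half)
      as.integer(lo + which.max(abs(x[lo:hi])) - 1L)
    }, 1L)
    keep <- !duplicated(beats)
    beat_idx[[si]] <- beats[keep]
    beat_height[[si]] <- heights[keep]
  }
  # prune borderline detections well below the typical beat prominence
  med_height <- median(unlist(beat_height))
  windows <- list()
  for (si in seq_along(signals)) {
    keep <- beat_height[[si]] >= 0.6 * med_height
    beat_idx[[si]] <- beat_idx[[si]][keep]
    x <- signals[[si]]
    for (i in beat_idx[[si]]) {
      if (i - half >= 1 && i + half <= length(x)) {
        windows[[length(windows) + 1]] <- x[(i - half):(i + half)]
      }
    }
  }
  if (length(windows) < 10)
    stop("only ", length(windows),
         " beats detected; at least 10 are required for a template")
  template <- rowMeans(do.call(cbind, windows))
  list(template = template,
       beat_times = lapply(beat_idx, function(b) (b - 1) / rate),
       rate = rate, n_beats = length(windows))
}

#' Subtract a scaled ECG template at detected beat times
#'
#' At every beat the template is scaled by its least-squares fit to the local
#' window and subtracted; the signal is unchanged outside beat windows.
#' Beats whose window would cross a signal edge are skipped.
#'
#' @param x numeric series.
#' @param template template waveform (odd length, centered on the beat).
#' @param beat_times beat times in seconds.
#' @param rate sampling rate in Hz.
#' @return Cleaned series, same length as `x`.
#' @export
remove_ecg_artifacts <- function(x, template, beat_times, rate) {
  if (length(beat_times) == 0 || all(template == 0)) return(x)
  half <- (length(template) - 1) %/% 2
  tt <- sum(template^2)
  if (tt == 0) return(x)
  for (bt in beat_times) {
    i <- round(bt * rate) + 1
    if (i - half < 1 || i + half > length(x)) next
    idx <- (i - half):(i + half)
    scale <- sum(x[idx] * template) / tt
    x[idx] <- x[idx] - scale * template
  }
  x
}

#' Full-wave rectification and envelope smoothing
#'
#' Absolute value followed by a 4th-order zero-lag low-pass Butterworth
#' filter (10 Hz); small negative excursions introduced by the low-pass are
#' clipped at zero so downstream non-negative factorization is well posed.
#'
#' @param x numeric series.
#' @param rate sampling rate in Hz (> 20).
#' @param cutoff low-pass cutoff in Hz.
#' @return Nonnegative envelope series, same length as `x`.
#' @export
rectify_and_smooth <- function(x, rate, cutoff = 10) {
  if (rate <= 20) stop("sampling rate must exceed 20 Hz, got ", rate)
  env <- zerophase_butter(abs(x), rate, cutoff, type = "low",
                          pad = min(length(x) - 1, round(rate)))
  pmax(env, 0)
}

#' Detect movement events from kinetic and CoM traces
#'
#' Per-sample feature vectors (standardized vertical GRF, seat force, CoM
#' vertical position and CoM vertical velocity, all resampled to a common
#' grid) are clustered into three movement phases with k-means++; labels are
#' median-smoothed and the boundaries of the contiguous middle phase give
#' movement start and end. The seat transition is the time the seat force
#' crosses a near-zero threshold (reaching zero for seat-off in sit-to-stand,
#' leaving zero for seat-on in stand-to-sit) within the middle phase.
#'
#' @param grf,seat_force,com lists with elements `x` (numeric series,
#'   low-pass filtered at 10 Hz) and `rate` (Hz).
#' @param movement `"sit_to_stand"` or `"stand_to_sit"`.
#' @param t0 wall-clock time of the first sample (seconds).
#' @param seat_threshold_frac seat-force threshold as a fraction of the
#'   seated weight on the seat.
#' @param grid_rate common resampling rate for the feature grid (Hz).
#' @param seed seed for the k-means++ restarts.
#' @return List of class `event_times`: `movement_start`, `seat_transition`,
#'   `movement_end` (seconds), `pre_window` (fixed 0.2 s).
#' @export
detect_events <- function(grf, seat_force, com,
                          movement = c("sit_to_stand", "stand_to_sit"),
                          t0 = 0, seat_threshold_frac = 0.02,
                          grid_rate = 100, seed = 1) {
  movement <- match.arg(movement)
  dur <- min(length(grf$x) / grf$rate, length(seat_force$x) / seat_force$rate,
             length(com$x) / com$rate)
  tg <- seq(0, dur - 1 / grid_rate, by = 1 / grid_rate)
  res <- function(s) approx((seq_along(s$x) - 1) / s$rate, s$x, xout = tg,
                            rule = 2)$y
  g <- res(grf); sf <- res(seat_force); cm <- res(com)
  vel <- c(0, diff(cm)) * grid_rate
  feats <- cbind(g, sf, cm, vel)
  sds <- apply(feats, 2, sd)
  if (any(sds[3:4] < 1e-9) || all(sds < 1e-9))
    stop("no movement detectable: kinetic/CoM traces show no transition")
  sds[sds < 1e-12] <- 1
  z <- scale(feats, scale = sds)
  km <- with_seed(seed, {
    best <- NULL
    for (r in 1:10) {
      fit <- kmeans_lloyd(z, 3, iter_max = 100)
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
    best
  })
  lab <- runmed(km$cluster, k = max(3, 2 * floor(0.05 * grid_rate) + 1))
  # order cluster labels by their median time of occurrence
  med_t <- vapply(1:3, function(j) median(which(lab == j)), 1)
  if (any(!is.finite(med_t)))
    stop("fewer than 3 distinct movement phases found after smoothing")
  middle <- order(med_t)[2]
  runs <- rle(lab == middle)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  mid_runs <- which(runs$values)
  if (length(mid_runs) == 0)
    stop("no contiguous middle movement phase found")
  longest <- mid_runs[which.max(runs$lengths[mid_runs])]
  i0 <- starts[longest]; i1 <- ends[longest]
  if (i0 <= 1 || i1 >= length(tg))
    stop("middle phase touches the recording boundary; no resting phases found")
  # refine the phase boundaries: cluster boundaries are biased towards the
  # middle of the transition, so expand outward while the CoM still moves
  # (above a noise-aware fraction of the mid-phase peak velocity)
  vs <- runmed(abs(vel), 5)
  rest_idx <- c(seq_len(max(i0 - 1, 1)), seq(min(i1 + 1, length(vs)), length(vs)))
  thr_v <- max(0.05 * max(vs[i0:i1]), median(vs[rest_idx]) + 4 * mad(vs[rest_idx]))
  while (i0 > 2 && vs[i0 - 1] > thr_v) i0 <- i0 - 1
  while (i1 < length(tg) - 1 && vs[i1 + 1] > thr_v) i1 <- i1 + 1
  movement_start <- tg[i0]
  movement_end <- tg[i1]
  # seat transition: threshold crossing of the seat force
  seated_level <- if (movement == "sit_to_stand") {
    median(sf[seq_len(max(i0 - 1, 1))])
  } else {
    median(sf[seq(min(i1 + 1, length(sf)), length(sf))])
  }
  thr <- seat_threshold_frac * seated_level
  inside <- i0:i1
  cross_time <- function(idx_first) {
    if (is.na(idx_first)) stop("seat force never crosses its threshold ",
                               "within the middle phase")
    i <- inside[idx_first]
    if (i > 1) {
      # linear interpolation of the crossing
      x1 <- sf[i - 1]; x2 <- sf[i]
      frac <- if (x2 != x1) (thr - x1) / (x2 - x1) else 0
      tg[i - 1] + frac / grid_rate
    } else tg[i]
  }
  seat_transition <- if (movement == "sit_to_stand") {
    cross_time(which(sf[inside] <= thr)[1])
  } else {
    cross_time(which(sf[inside] >= thr)[1])
  }
  structure(list(movement_start = t0 + movement_start,
                 seat_transition = t0 + seat_transition,
                 movement_end = t0 + movement_end,
                 pre_window = 0.2),
            class = "event_times")
}

#' Segment envelopes and resample to the 101-point normalized grid
#'
#' Extracts the window from 0.2 s before movement start (muscles are active
#' before visible movement) to movement end and resamples each channel to
#' 101 time points (0-100% of the movement) by cubic spline interpolation on
#' the channel's own time base, so mixed acquisition rates need no prior
#' common-rate resampling.
#'
#' @param envelopes list of per-channel envelope series.
#' @param rates per-channel sampling rates in Hz.
#' @param events an `event_times` object.
#' @param t0 wall-clock time of the first sample of every channel (seconds).
#' @return A 101 x (number of channels) matrix.
#' @export
segment_and_normalize_time <- function(envelopes, rates, events, t0 = 0) {
  w0 <- events$movement_start - events$pre_window
  w1 <- events$movement_end
  grid <- seq(w0, w1, length.out = 101)
  out <- matrix(0, 101, length(envelopes))
  for (ch in seq_along(envelopes)) {
    x <- envelopes[[ch]]
    t <- t0 + (seq_along(x) - 1) / rates[ch]
    if (w0 < t[1] - 1e-9 || w1 > t[length(t)] + 1e-9)
      stop("segmentation window [", round(w0, 3), ", ", round(w1, 3),
           "] s exceeds the recording span of channel ", ch)
    out[, ch] <- spline(t, x, xout = grid)$y
  }
  pmax(out, 0)
}

#' Amplitude-normalize all trials of one participant
#'
#' Divides each muscle channel by that muscle's maximum activity across all
#' of the participant's trials, so the per-muscle maximum over the
#' participant's normalized trials is exactly 1. Muscles that are identically
#' zero are left unscaled and flagged.
#'
#' @param envelopes list of 101 x 30 envelope matrices (one participant).
#' @return List with `envelopes` (normalized matrices), `factors` (the 30
#'   per-muscle maxima) and `flagged` (logical, all-zero muscles).
#' @export
normalize_amplitude <- function(envelopes) {
  stopifnot(length(envelopes) >= 1)
  maxima <- Reduce(pmax, lapply(envelopes, function(m) apply(m, 2, max)))
  flagged <- maxima <= 0
  divisor <- ifelse(flagged, 1, maxima)
  out <- lapply(envelopes, function(m) sweep(m, 2, divisor, "/"))
  list(envelopes = out, factors = maxima, flagged = flagged)
}

#' Preprocess one raw trial to an event-segmented envelope matrix
#'
#' Runs the single-trial part of the chain: band-pass + notch filtering,
#' optional ECG template subtraction on trunk channels, rectification and
#' 10 Hz envelope smoothing, 10 Hz low-pass of the kinetic traces, event
#' detection, and segmentation to the 101-point grid. Amplitude
#' normalization is a cohort-level step (see [preprocess_cohort()]).
#'
#' @param raw a `raw_trial`.
#' @param ecg_templates optional named list (by channel code) of
#'   `build_ecg_template()` results for the trunk channels.
#' @param skip_ecg if `TRUE`, skip ECG removal.
#' @param seed seed for event-detection restarts.
#' @return List of class `processed_trial`: `envelope` (101 x 30, not yet
#'   amplitude-normalized), `events`, `meta`.
#' @export
preprocess_raw_trial <- function(raw, ecg_templates = NULL, skip_ecg = FALSE,
                                 seed = 1) {
  channels <- muscle_channel_table()
  envs <- vector("list", 30)
  for (ch in 1:30) {
    x <- bandpass_notch_filter(raw$emg[[ch]], raw$emg_rates[ch])
    code <- channels$code[ch]
    if (!skip_ecg && channels$group[ch] == "trunk" &&
        !is.null(ecg_templates[[code]])) {
      tpl <- ecg_templates[[code]]
      beats <- detect_beats_against_template(x, tpl, raw$emg_rates[ch])
      x <- remove_ecg_artifacts(x, tpl$template, beats, raw$emg_rates[ch])
    }
    envs[[ch]] <- rectify_and_smooth(x, raw$emg_rates[ch])
  }
  lp <- function(s) list(x = zerophase_butter(s$x, s$rate, 10, type = "low"),
                         rate = s$rate)
  events <- detect_events(lp(raw$grf), lp(raw$seat_force), lp(raw$com),
                          movement = raw$meta$movement, seed = seed)
  env_mat <- segment_and_normalize_time(envs, raw$emg_rates, events)
  colnames(env_mat) <- channels$code
  structure(list(envelope = env_mat, events = events, meta = raw$meta),
            class = "processed_trial")
}

# Locate beats in a single trial by matched filtering against the template.
detect_beats_against_template <- function(x, tpl, rate) {
  if (rate != tpl$rate) {
    # resample the template onto this channel's rate
    nt <- length(tpl$template)
    t_old <- (seq_len(nt) - 1) / tpl$rate
    t_new <- seq(0, t_old[nt], by = 1 / rate)
    template <- approx(t_old, tpl$template, xout = t_new)$y
  } else template <- tpl$template
  score <- as.numeric(stats::filter(x, rev(template) / sum(template^2),
                                    sides = 2))
  score[is.na(score)] <- 0
  thr <- median(score) + 3 * mad(score)
  refr <- round(0.4 * rate)
  cand <- which(score > thr)
  cand <- cand[order(score[cand], decreasing = TRUE)]
  beats <- integer(0)
  for (i in cand) if (all(abs(i - beats) > refr)) beats <- c(beats, i)
  (sort(beats) - 1) / rate
}

#' Preprocess a raw cohort
#'
#' Builds muscle- and participant-specific ECG templates for the trunk
#' channels from all of each participant's filtered trials, preprocesses
#' every trial ([preprocess_raw_trial()]), and amplitude-normalizes per
#' muscle and participant across all of that participant's trials.
#'
#' @param cohort a raw-level cohort from [generate_cohort()] (or any list
#'   with `trials` of class `raw_trial` and a `metadata` data frame).
#' @param skip_ecg if `TRUE`, skip ECG template building and removal.
#' @param seed integer seed.
#' @return List with `trials` (list of `processed_trial`, amplitude
#'   normalized), `metadata`, `normalization` (per-participant factors).
#' @export
preprocess_cohort <- function(cohort, skip_ecg = FALSE, seed = 1) {
  channels <- muscle_channel_table()
  trunk_idx <- which(channels$group == "trunk")
  meta <- cohort$metadata
  processed <- vector("list", length(cohort$trials))
  norm_info <- list()
  for (pid in unique(meta$participant)) {
    rows <- which(meta$participant == pid)
    templates <- NULL
    if (!skip_ecg) {
      templates <- list()
      for (ch in trunk_idx) {
        code <- channels$code[ch]
        sigs <- lapply(cohort$trials[rows], function(tr)
          bandpass_notch_filter(tr$emg[[ch]], tr$emg_rates[ch]))
        rate <- cohort$trials[[rows[1]]]$emg_rates[ch]
        templates[[code]] <- tryCatch(
          build_ecg_template(sigs, rate, min_duration = 0),
          error = function(e) NULL)  # too few beats: skip removal
      }
    }
    for (i in rows) {
      processed[[i]] <- preprocess_raw_trial(
        cohort$trials[[i]], ecg_templates = templates, skip_ecg = skip_ecg,
        seed = split_seed(seed, paste("events", i)))
    }
    nrm <- normalize_amplitude(lapply(processed[rows], `[[`, "envelope"))
    for (j in seq_along(rows)) {
      processed[[rows[j]]]$envelope <- nrm$envelopes[[j]]
      processed[[rows[j]]]$normalization_factors <- nrm$factors
    }
    norm_info[[pid]] <- nrm[c("factors", "flagged")]
  }
  list(trials = processed, metadata = meta, normalization = norm_info)
}
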