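#' Main-sequence peak velocity
#'
#' Linear amplitude/peak-velocity relationship used by the simulator:
#' `peak velocity = main_sequence_slope * amplitude`.
#'
#' @param amplitude Event amplitude in degrees (>= 0, vectorized).
#' @param slope Main-sequence slope in (deg/s) per degree.
#' @return Peak velocity in deg/s.
#' @export
#' @examples
#' main_sequence_peak_velocity(0.5, slope = 60) # 30 deg/s
main_sequence_peak_velocity <- function(amplitude, slope = 80) {
  if (any(!is.finite(amplitude)) || any(amplitude < 0)) {
    stopf("field 'amplitude' must be nonnegative",
          class = "microsacc_validation_error")
  }
  check_number(slope, "main_sequence_slope", lower = 0,
               allow_equal_lower = FALSE)
  slope * amplitude
}

#' Inject a microsaccade waveform into a position trace
#'
#' Adds a smooth unidirectional displacement whose velocity profile is a
#' raised-cosine pulse: over `duration_samples` samples the position moves
#' by `amplitude` along `direction`, with peak velocity
#' `2 * amplitude / duration`. Samples after the event keep the full
#' displacement.
#'
#' @param trace An n x 2 matrix of x, y positions in degrees.
#' @param onset_index 0-based sample index of event onset.
#' @param amplitude Displacement magnitude in degrees (>= 0).
#' @param direction Direction in radians (0 = +x, pi/2 = +y).
#' @param duration_samples Event duration in samples (>= 1).
#' @return The trace with the event added.
#' @export
inject_microsaccade <- function(trace, onset_index, amplitude, direction,
                                duration_samples) {
  if (!is.matrix(trace) || ncol(trace) != 2L) {
    stopf("'trace' must be an n x 2 matrix",
          class = "microsacc_validation_error")
  }
  check_number(onset_index, "onset_index", lower = 0, integer = TRUE)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(duration_samples, "duration_samples", lower = 1,
               integer = TRUE)
  n <- nrow(trace)
  if (onset_index + duration_samples > n - 1L) {
    stopf("event [%d, %d] exceeds trial bounds (n = %d)", onset_index,
          onset_index + duration_samples, n,
          class = "microsacc_validation_error")
  }
  if (amplitude == 0) return(trace)
  # position profile of a raised-cosine velocity pulse
  s <- pmin(pmax((seq_len(n) - 1L - onset_index) / duration_samples, 0), 1)
  disp <- amplitude * (s - sin(2 * pi * s) / (2 * pi))
  trace[, 1] <- trace[, 1] + disp * cos(direction)
  trace[, 2] <- trace[, 2] + disp * sin(direction)
  trace
}

# event duration in samples from the main sequence: duration = 2A/Vp = 2/slope
.event_duration_samples <- function(config) {
  max(3L, as.integer(round(2 * config$sampling_rate /
                             config$main_sequence_slope)))
}

#' Simulate one fixation trial
#'
#' Generates a binocular gaze trial: mean-reverting (discretized
#' Ornstein-Uhlenbeck) drift shared by the two eyes, injected microsaccade
#' waveforms (identical displacement in both eyes), per-eye independent
#' Gaussian sensor noise, and optionally one blink (a run of invalid
#' samples). Event onsets follow a refractory-modified Poisson process whose
#' exponential intensity `lambda = r / (1 - r * refractory)` is corrected
#' for the dead time so the realized rate equals the nominal rate `r`.
#'
#' Draw order within the trial's RNG stream is fixed (per-trial rate jitter;
#' event gaps; event amplitudes; event directions; blink indicator, length,
#' position; drift initial states and innovations for x then y; left-eye
#' then right-eye noise), so a given `(config, seed)` is bit-reproducible.
#'
#' @param rate Expected event rate for this trial's session, events/s
#'   (>= 0). A rate of exactly 0 produces no events regardless of jitter.
#' @param config A [sim_config()].
#' @param seed Optional seed for a private RNG stream; if `NULL`, the
#'   current RNG state is used (and advanced).
#' @param participant_id,session,trial_index Identifiers stored in the
#'   returned trial.
#' @return A list with `trial` (a [gaze_trial()]) and `events` (data frame
#'   of ground-truth events: `onset_time` s, `onset_sample`, `amplitude`
#'   deg, `direction` rad, `duration` s).
#' @export
simulate_trial <- function(rate, config, seed = NULL,
                           participant_id = "sim", session = "pre",
                           trial_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.finite(rate) || rate < 0) {
    stopf("field 'rate' must be nonnegative",
          class = "microsacc_validation_error")
  }
  if (!is.null(seed)) {
    return(with_seed(seed, simulate_trial(rate, config, NULL,
                                          participant_id, session,
                                          trial_index)))
  }
  fs <- config$sampling_rate
  n <- as.integer(round(config$trial_duration * fs))
  dur_samples <- .event_duration_samples(config)
  dur_s <- dur_samples / fs

  # per-trial rate jitter (silent processes stay silent)
  r <- rate
  if (r > 0 && config$within_trial_rate_jitter_sd > 0) {
    r <- max(0, r + stats::rnorm(1, 0, config$within_trial_rate_jitter_sd))
  }

  # event onsets: refractory renewal process at realized rate r
  onsets <- numeric(0)
  if (r > 0) {
    tau <- config$refractory_interval
    if (r * tau >= 0.95) {
      stopf("rate %.3g /s is infeasible with refractory interval %.3g s",
            r, tau, class = "microsacc_validation_error")
    }
    lambda <- r / (1 - r * tau)
    t_on <- stats::rexp(1, lambda)
    limit <- config$trial_duration - dur_s
    while (t_on <= limit) {
      onsets <- c(onsets, t_on)
      t_on <- t_on + tau + stats::rexp(1, lambda)
    }
  }
  n_ev <- length(onsets)
  amplitudes <- if (n_ev) {
    stats::rlnorm(n_ev, config$amplitude_log_mean, config$amplitude_log_sd)
  } else numeric(0)
  directions <- if (n_ev) stats::runif(n_ev, 0, 2 * pi) else numeric(0)

  # blink
  blink <- NULL
  if (config$blink_probability_per_trial > 0) {
    if (stats::runif(1) < config$blink_probability_per_trial) {
      len <- as.integer(round(stats::runif(1, 0.1, 0.3) * fs))
      len <- min(len, n - 1L)
      start <- sample.int(n - len + 1L, 1L)
      blink <- c(start = start, end = start + len - 1L)
    }
  }

  # shared drift
  common <- matrix(0, n, 2)
  if (config$drift_sd > 0) {
    a <- exp(-config$drift_mean_reversion / fs)
    innov_sd <- config$drift_sd * sqrt(max(0, 1 - a^2))
    for (ax in 1:2) {
      x0 <- stats::rnorm(1, 0, config$drift_sd)
      e <- stats::rnorm(n, 0, innov_sd)
      common[, ax] <- as.numeric(
        stats::filter(e, a, method = "recursive", init = x0))
    }
  }
  onset_samples <- as.integer(round(onsets * fs))
  keep <- onset_samples + dur_samples <= n - 1L
  onset_samples <- onset_samples[keep]
  onsets <- onsets[keep]
  amplitudes <- amplitudes[keep]
  directions <- directions[keep]
  for (k in seq_along(onsets)) {
    common <- inject_microsaccade(common, onset_samples[k], amplitudes[k],
                                  directions[k], dur_samples)
  }

  noise <- function() {
    if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else
      numeric(n)
  }
  xl <- common[, 1] + noise(); yl <- common[, 2] + noise()
  xr <- common[, 1] + noise(); yr <- common[, 2] + noise()
  valid_l <- valid_r <- rep(TRUE, n)
  if (!is.null(blink)) {
    rng <- blink["start"]:blink["end"]
    xl[rng] <- NA_real_; yl[rng] <- NA_real_
    xr[rng] <- NA_real_; yr[rng] <- NA_real_
    valid_l[rng] <- FALSE; valid_r[rng] <- FALSE
  }
  trial <- gaze_trial(participant_id, session, trial_index, fs,
                      xl = xl, yl = yl, xr = xr, yr = yr,
                      valid_l = valid_l, valid_r = valid_r)
  events <- data.frame(onset_time = onsets, onset_sample = onset_samples,
                       amplitude = amplitudes, direction = directions,
                       duration = rep(dur_s, length(onsets)))
  list(trial = trial, events = events)
}

#' Simulate a full pre/post study
#'
#' Generates `n_participants` x 2 sessions (pre, post) x
#' `n_trials_per_session` fixation trials with ground truth. Participant
#' `i`'s pre-session base rate is drawn from a Gaussian (clamped at zero)
#' around `base_rate_mean`, and the post-session expected rate is
#' `pre rate * post_rate_multiplier`. Every trial uses a child RNG stream
#' derived from the root seed by a fixed counter scheme
#' (`child_seed(seed, participant, session, trial)`), so any subset of the
#' dataset is reproducible independently of generation order.
#'
#' @param config A [sim_config()].
#' @return A list with `study` (a [gaze_study()]) and `truth` (class
#'   `"ground_truth"`: `$events` per-trial ground-truth event table,
#'   `$participant_rates` with per-participant `pre_rate`/`post_rate`).
#' @export
#' @examples
#' out <- simulate_study(sim_config(n_participants = 2,
#'                                  n_trials_per_session = 3,
#'                                  trial_duration = 2))
#' out$study
#' head(out$truth$events)
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  root <- config$seed
  sessions <- c("pre", "post")
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  pre_rates <- vapply(seq_len(config$n_participants), function(i) {
    with_seed(child_seed(root, i, 0L, 0L),
              max(0, stats::rnorm(1, config$base_rate_mean,
                                  config$base_rate_sd)))
  }, numeric(1))
  post_rates <- pre_rates * config$post_rate_multiplier
  trials <- list()
  ev_list <- list()
  for (i in seq_len(config$n_participants)) {
    for (s in 1:2) {
      rate_is <- if (s == 1L) pre_rates[i] else post_rates[i]
      for (t in seq_len(config$n_trials_per_session)) {
        out <- simulate_trial(rate_is, config,
                              seed = child_seed(root, i, s, t),
                              participant_id = ids[i],
                              session = sessions[s], trial_index = t)
        trials[[length(trials) + 1L]] <- out$trial
        if (nrow(out$events)) {
          ev_list[[length(ev_list) + 1L]] <- cbind(
            data.frame(participant_id = ids[i], session = sessions[s],
                       trial_index = t), out$events)
        }
      }
    }
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(participant_id = character(), session = character(),
               trial_index = integer(), onset_time = numeric(),
               onset_sample = integer(), amplitude = numeric(),
               direction = numeric(), duration = numeric())
  rownames(events) <- NULL
  truth <- structure(
    list(events = events,
         participant_rates = data.frame(participant_id = ids,
                                        pre_rate = pre_rates,
                                        post_rate = post_rates)),
    class = "ground_truth")
  list(study = gaze_study(trials), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d events, %d participants\n",
              nrow(x$events), nrow(x$participant_rates)))
  invisible(x)
}

#' Match detected events to ground truth
#'
#' Greedily matches detected binocular events to ground-truth injections by
#' onset-time proximity (closest pairs first, one-to-one, within
#' `tolerance` seconds), per trial, and reports precision, recall and F1.
#'
#' @param detection An `"ms_detection"` from [detect_study()].
#' @param truth A `"ground_truth"` from [simulate_study()].
#' @param sampling_rate Sampling rate in Hz (to convert detected onset
#'   indices to seconds).
#' @param tolerance Maximum onset-time separation for a match, seconds
#'   (default 0.02).
#' @return A list with `n_truth`, `n_detected`, `n_matched`, `precision`,
#'   `recall`, `f1`. Trials excluded by detection are dropped from both
#'   sides.
#' @export
event_recovery <- function(detection, truth, sampling_rate,
                           tolerance = 0.02) {
  stopifnot(inherits(detection, "ms_detection"),
            inherits(truth, "ground_truth"))
  bin <- detection$events[detection$events$eye == "BIN", , drop = FALSE]
  tl <- detection$trials
  used <- tl[!tl$excluded, , drop = FALSE]
  keyf <- function(d) paste(d$participant_id, d$session, d$trial_index)
  te <- truth$events[keyf(truth$events) %in% keyf(used), , drop = FALSE]
  bin <- bin[keyf(bin) %in% keyf(used), , drop = FALSE]
  n_matched <- 0L
  for (key in unique(c(keyf(te), keyf(bin)))) {
    g <- te$onset_time[keyf(te) == key]
    d <- bin$onset_idx[keyf(bin) == key] / sampling_rate
    if (!length(g) || !length(d)) next
    dist <- abs(outer(d, g, "-"))
    repeat {
      m <- which(dist == min(dist), arr.ind = TRUE)[1, ]
      if (dist[m[1], m[2]] > tolerance) break
      n_matched <- n_matched + 1L
      dist[m[1], ] <- Inf
      dist[, m[2]] <- Inf
      if (all(!is.finite(dist))) break
    }
  }
  precision <- if (nrow(bin)) n_matched / nrow(bin) else NA_real_
  recall <- if (nrow(te)) n_matched / nrow(te) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(n_truth = nrow(te), n_detected = nrow(bin), n_matched = n_matched,
       precision = precision, recall = recall, f1 = f1)
}
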