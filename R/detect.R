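#' Moving-difference gaze velocity
#'
#' Smoothed finite-difference velocity estimate. For the default 5-sample
#' window, interior samples use
#' `v[n] = (p[n+2] + p[n+1] - p[n-1] - p[n-2]) / (6 * dt)`; samples one step
#' from either edge fall back to the central difference
#' `(p[n+1] - p[n-1]) / (2 * dt)`, and the first and last samples are set to
#' zero. For a general odd window `2m + 1` the kernel is
#' `sum_k (p[n+k] - p[n-k]) / (m (m+1) dt)`, which is exact on affine
#' signals; edge samples use the largest centered window that fits.
#'
#' @param x,y Position series in degrees.
#' @param sampling_rate Sampling rate in Hz.
#' @param velocity_window Odd window length in samples (>= 3, default 5).
#' @return A list with components `vx` and `vy` in deg/s.
#' @export
compute_velocity <- function(x, y, sampling_rate, velocity_window = 5L) {
  n <- length(x)
  if (length(y) != n) {
    stopf("x and y must have equal length",
          class = "microsacc_validation_error")
  }
  check_number(velocity_window, "velocity_window", lower = 3, integer = TRUE)
  if (velocity_window %% 2 == 0) {
    stopf("field 'velocity_window' must be odd",
          class = "microsacc_validation_error")
  }
  if (n < velocity_window) {
    stopf("series of length %d is shorter than velocity_window %d", n,
          velocity_window, class = "microsacc_validation_error")
  }
  list(vx = .mdiff_velocity(x, sampling_rate, velocity_window),
       vy = .mdiff_velocity(y, sampling_rate, velocity_window))
}

.mdiff_velocity <- function(p, fs, w) {
  n <- length(p)
  m <- (w - 1L) %/% 2L
  v <- numeric(n)
  # interior: full kernel, vectorized over shells
  if (n >= w) {
    idx <- (m + 1L):(n - m)
    acc <- numeric(length(idx))
    for (k in seq_len(m)) acc <- acc + p[idx + k] - p[idx - k]
    v[idx] <- acc * fs / (m * (m + 1))
  }
  # edges: largest centered kernel that fits; extremes stay 0
  for (i in seq_len(min(m, n))[-1]) {
    mm <- i - 1L
    ks <- seq_len(mm)
    v[i] <- sum(p[i + ks] - p[i - ks]) * fs / (mm * (mm + 1))
    j <- n - i + 1L
    v[j] <- sum(p[j + ks] - p[j - ks]) * fs / (mm * (mm + 1))
  }
  v
}

#' Median-based velocity thresholds
#'
#' Per-axis elliptic detection thresholds: the robust velocity spread is
#' `sigma = sqrt(median(v^2) - median(v)^2)` and the threshold is
#' `eta = vfac * sigma`. Samples flagged invalid (and non-finite velocities)
#' are excluded from the medians. A spread below 1e-10 deg/s indicates a
#' degenerate trial (tracker dropout) and raises a classed error rather than
#' returning a zero threshold.
#'
#' @param vx,vy Velocity series in deg/s.
#' @param vfac Velocity threshold scaling factor (> 0).
#' @param valid Optional logical mask of samples to use.
#' @return Named numeric vector `c(eta_x, eta_y)` in deg/s.
#' @export
estimate_thresholds <- function(vx, vy, vfac = 5, valid = NULL) {
  check_number(vfac, "vfac", lower = 0, allow_equal_lower = FALSE)
  if (is.null(valid)) valid <- rep(TRUE, length(vx))
  eta <- vapply(list(vx, vy), function(v) {
    v <- v[valid & is.finite(v)]
    if (!length(v)) {
      stopf("no valid velocity samples in trial",
            class = c("microsacc_degenerate_trial"))
    }
    s2 <- .median_fast(v^2) - .median_fast(v)^2
    s <- sqrt(max(s2, 0))
    if (s < 1e-10) {
      stopf("degenerate trial: velocity spread %.3g deg/s below floor", s,
            class = c("microsacc_degenerate_trial"))
    }
    vfac * s
  }, numeric(1))
  c(eta_x = eta[1], eta_y = eta[2])
}

# exact median via partial sort (linear time)
.median_fast <- function(v) {
  n <- length(v)
  half <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    sort.int(v, partial = half)[half]
  } else {
    s <- sort.int(v, partial = c(half, half + 1L))
    (s[half] + s[half + 1L]) / 2
  }
}

#' Monocular event candidate detection
#'
#' A sample is suprathreshold iff `(vx/eta_x)^2 + (vy/eta_y)^2 > 1`. Maximal
#' runs of consecutive suprathreshold samples are merged across gaps of at
#' most `merge_gap` subthreshold samples, then runs shorter than `mindur`
#' samples are dropped, and events overlapping any invalid sample are
#' discarded.
#'
#' @param vx,vy Velocity series in deg/s.
#' @param eta_x,eta_y Positive thresholds in deg/s.
#' @param mindur Minimum run length in samples.
#' @param merge_gap Maximum subthreshold gap merged before the duration
#'   test (default 0).
#' @param invalid Optional logical mask of invalid samples.
#' @return A data frame with 0-based inclusive `onset` and `offset` columns,
#'   one row per event, ordered by onset.
#' @export
detect_monocular <- function(vx, vy, eta_x, eta_y, mindur = 6L,
                             merge_gap = 0L, invalid = NULL) {
  if (!is.finite(eta_x) || !is.finite(eta_y) || eta_x <= 0 || eta_y <= 0) {
    stopf("thresholds must be positive", class = "microsacc_validation_error")
  }
  check_number(mindur, "mindur", lower = 1, integer = TRUE)
  check_number(merge_gap, "merge_gap", lower = 0, integer = TRUE)
  ev <- .detect_mono_core(vx, vy, eta_x, eta_y, mindur, merge_gap, invalid)
  data.frame(onset = ev$onset, offset = ev$offset)
}

# core run-length detector; returns 0-based inclusive onset/offset vectors
.detect_mono_core <- function(vx, vy, eta_x, eta_y, mindur, merge_gap,
                              invalid) {
  test <- (vx / eta_x)^2 + (vy / eta_y)^2 > 1
  if (anyNA(test)) test[is.na(test)] <- FALSE
  r <- rle(test)
  ends <- cumsum(r$lengths)
  sel <- r$values
  start <- (ends - r$lengths + 1L)[sel]
  end <- ends[sel]
  if (length(start) > 1L && merge_gap > 0L) {
    keep <- logical(length(start))
    keep[1] <- TRUE
    cur <- 1L
    for (k in 2L:length(start)) {
      if (start[k] - end[cur] - 1L <= merge_gap) {
        end[cur] <- end[k]
      } else {
        cur <- k
        keep[k] <- TRUE
      }
    }
    start <- start[keep]
    end <- end[keep]
  }
  ok <- end - start + 1L >= mindur
  start <- start[ok]
  end <- end[ok]
  if (!is.null(invalid) && length(start) && any(invalid)) {
    cum <- c(0L, cumsum(invalid))
    bad <- (cum[end + 1L] - cum[start]) > 0L
    start <- start[!bad]
    end <- end[!bad]
  }
  list(onset = start - 1L, offset = end - 1L)
}

# vectorized event_properties over several intervals (0-based inclusive)
.props_many <- function(x, y, vx, vy, onsets, offsets, fs) {
  n <- length(onsets)
  pk <- amp <- dx <- dy <- numeric(n)
  sp <- sqrt(vx^2 + vy^2)
  for (k in seq_len(n)) {
    idx <- (onsets[k] + 1L):(offsets[k] + 1L)
    pk[k] <- max(sp[idx])
    xs <- x[idx]; ys <- y[idx]
    amp[k] <- sqrt((max(xs) - min(xs))^2 + (max(ys) - min(ys))^2)
    dx[k] <- x[offsets[k] + 1L] - x[onsets[k] + 1L]
    dy[k] <- y[offsets[k] + 1L] - y[onsets[k] + 1L]
  }
  data.frame(onset_idx = as.integer(onsets),
             offset_idx = as.integer(offsets),
             duration_ms = (offsets - onsets + 1) * 1000 / fs,
             peak_velocity_dps = pk, amplitude_deg = amp,
             dx_deg = dx, dy_deg = dy)
}

#' Greedy binocular event pairing
#'
#' Pairs left- and right-eye events whose (0-based inclusive) sample
#' intervals share at least `min_overlap` samples. Pairing is greedy in
#' onset order and one-to-one: each monocular event is used at most once.
#' The binocular event spans the union of the paired intervals.
#'
#' @param left_events,right_events Data frames with `onset` and `offset`
#'   columns, sorted by onset and non-overlapping within eye.
#' @param min_overlap Minimum shared samples (>= 1).
#' @return A data frame with columns `l` and `r` (row indices of the paired
#'   events), `onset`, `offset` (the union interval).
#' @export
pair_binocular <- function(left_events, right_events, min_overlap = 1L) {
  check_number(min_overlap, "min_overlap", lower = 1, integer = TRUE)
  for (ev in list(left_events, right_events)) {
    if (nrow(ev) > 1L) {
      if (is.unsorted(ev$onset, strictly = TRUE) ||
          any(ev$onset[-1] <= ev$offset[-nrow(ev)])) {
        stopf("monocular events must be sorted by onset and non-overlapping",
              class = "microsacc_validation_error")
      }
    }
  }
  p <- .pair_core(left_events$onset, left_events$offset,
                  right_events$onset, right_events$offset, min_overlap)
  data.frame(l = p$l, r = p$r, onset = p$onset, offset = p$offset)
}

# greedy one-to-one pairing core on 0-based inclusive intervals
.pair_core <- function(lon, loff, ron, roff, min_overlap) {
  nl <- length(lon); nr <- length(ron)
  cap <- min(nl, nr)
  l <- r <- on <- off <- integer(cap)
  np <- 0L
  i <- 1L; j <- 1L
  while (i <= nl && j <= nr) {
    ov <- min(loff[i], roff[j]) - max(lon[i], ron[j]) + 1L
    if (ov >= min_overlap) {
      np <- np + 1L
      l[np] <- i; r[np] <- j
      on[np] <- min(lon[i], ron[j]); off[np] <- max(loff[i], roff[j])
      i <- i + 1L; j <- j + 1L
    } else if (loff[i] < roff[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  list(l = l[seq_len(np)], r = r[seq_len(np)], onset = on[seq_len(np)],
       offset = off[seq_len(np)])
}

#' Event kinematic properties
#'
#' Computes the kinematics of an event over its 0-based inclusive interval:
#' peak velocity `max hypot(vx, vy)`, net displacement
#' `dx = x[offset] - x[onset]` (likewise `dy`), and amplitude as the
#' Euclidean norm of the per-axis extents
#' `hypot(max(x) - min(x), max(y) - min(y))` — the extent can exceed the net
#' displacement for overshooting trajectories.
#'
#' @param x,y Position series in degrees.
#' @param vx,vy Velocity series in deg/s.
#' @param onset,offset 0-based inclusive sample indices.
#' @param sampling_rate Sampling rate in Hz.
#' @return A one-row data frame with `onset_idx`, `offset_idx`,
#'   `duration_ms`, `peak_velocity_dps`, `amplitude_deg`, `dx_deg`, `dy_deg`.
#' @export
event_properties <- function(x, y, vx, vy, onset, offset, sampling_rate) {
  if (onset < 0 || offset < onset || offset >= length(x)) {
    stopf("invalid event interval [%d, %d]", onset, offset,
          class = "microsacc_validation_error")
  }
  idx <- (onset + 1L):(offset + 1L)
  data.frame(
    onset_idx = as.integer(onset), offset_idx = as.integer(offset),
    duration_ms = (offset - onset + 1) * 1000 / sampling_rate,
    peak_velocity_dps = max(sqrt(vx[idx]^2 + vy[idx]^2)),
    amplitude_deg = sqrt((max(x[idx]) - min(x[idx]))^2 +
                           (max(y[idx]) - min(y[idx]))^2),
    dx_deg = x[offset + 1L] - x[onset + 1L],
    dy_deg = y[offset + 1L] - y[onset + 1L])
}

#' Detect microsaccades in one trial
#'
#' Full per-trial detection: velocity estimation, per-eye median-based
#' thresholds (estimated on this trial only), monocular run detection, and
#' greedy binocular pairing. Binocular (`BIN`) events span the union of the
#' paired monocular intervals and take their kinematics from the eye with
#' the larger peak velocity. Invalid-sample runs are padded by
#' `invalid_pad` samples before detection, and events overlapping invalid
#' samples are discarded. A degenerate trial (velocity spread below floor)
#' raises an error of class `"microsacc_degenerate_trial"`; use
#' [detect_study()] to have such trials flagged as excluded instead.
#'
#' @param trial A [gaze_trial()].
#' @param params A [detection_params()].
#' @param invalid_pad Samples of padding around invalid runs (default 10).
#' @return A data frame of events (columns `eye`, `onset_idx`, `offset_idx`,
#'   `duration_ms`, `peak_velocity_dps`, `amplitude_deg`, `dx_deg`,
#'   `dy_deg`), `eye` one of `"L"`, `"R"`, `"BIN"`, ordered L, R, BIN.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 1, n_trials_per_session = 1)
#' tr <- simulate_trial(1.5, cfg, seed = 7)$trial
#' detect_trial(tr, detection_params())
detect_trial <- function(trial, params = detection_params(),
                         invalid_pad = 10L) {
  stopifnot(inherits(trial, "gaze_trial"),
            inherits(params, "detection_params"))
  tr <- mark_invalid_runs(trial, invalid_pad)
  fs <- tr$sampling_rate
  empty <- data.frame(eye = character(), onset_idx = integer(),
                      offset_idx = integer(), duration_ms = numeric(),
                      peak_velocity_dps = numeric(), amplitude_deg = numeric(),
                      dx_deg = numeric(), dy_deg = numeric())
  core <- .detect_trial_core(tr, params)
  mono <- core$mono
  props <- list()
  for (eye in c("L", "R")) {
    e <- core$per_eye[[eye]]
    v <- core$vel[[eye]]
    props[[eye]] <- .props_many(e$x, e$y, v$vx, v$vy, mono[[eye]]$onset,
                                mono[[eye]]$offset, fs)
  }
  pairs <- core$pairs
  if (length(pairs$l)) {
    stronger <- props$L$peak_velocity_dps[pairs$l] >=
      props$R$peak_velocity_dps[pairs$r]
    pick <- function(col) {
      ifelse(stronger, props$L[[col]][pairs$l], props$R[[col]][pairs$r])
    }
    props$BIN <- data.frame(
      onset_idx = as.integer(pairs$onset),
      offset_idx = as.integer(pairs$offset),
      duration_ms = (pairs$offset - pairs$onset + 1) * 1000 / fs,
      peak_velocity_dps = pick("peak_velocity_dps"),
      amplitude_deg = pick("amplitude_deg"),
      dx_deg = pick("dx_deg"), dy_deg = pick("dy_deg"))
  }
  keep <- names(props)[vapply(props, nrow, 1L) > 0]
  if (!length(keep)) return(empty)
  out <- do.call(rbind, lapply(keep, function(eye) {
    cbind(data.frame(eye = rep(eye, nrow(props[[eye]]))), props[[eye]])
  }))
  rownames(out) <- NULL
  out
}

# shared per-trial detection core: velocities, thresholds, monocular events
# and binocular pairs, without any per-event table assembly
.detect_trial_core <- function(tr, params) {
  fs <- tr$sampling_rate
  per_eye <- list(L = list(x = tr$xl, y = tr$yl, valid = tr$valid_l),
                  R = list(x = tr$xr, y = tr$yr, valid = tr$valid_r))
  vel <- mono <- list()
  for (eye in c("L", "R")) {
    e <- per_eye[[eye]]
    v <- compute_velocity(e$x, e$y, fs, params$velocity_window)
    eta <- estimate_thresholds(v$vx, v$vy, params$vfac, valid = e$valid)
    mono[[eye]] <- .detect_mono_core(v$vx, v$vy, eta[1], eta[2],
                                     params$mindur, params$merge_gap,
                                     invalid = !e$valid)
    vel[[eye]] <- v
  }
  pairs <- .pair_core(mono$L$onset, mono$L$offset, mono$R$onset,
                      mono$R$offset, params$min_overlap)
  list(per_eye = per_eye, vel = vel, mono = mono, pairs = pairs)
}

# counts-only fast path used by parameter sweeps: identical detection,
# no kinematic property tables
.detect_trial_counts <- function(trial, params, invalid_pad) {
  tr <- mark_invalid_runs(trial, invalid_pad)
  core <- .detect_trial_core(tr, params)
  c(n_left = length(core$mono$L$onset), n_right = length(core$mono$R$onset),
    n_bin = length(core$pairs$l))
}

#' Detect microsaccades across a study
#'
#' Runs [detect_trial()] on every trial of a study. Degenerate trials
#' (velocity spread below floor) are flagged excluded with a reason rather
#' than counted as zero.
#'
#' @param study A [gaze_study()].
#' @param params A [detection_params()].
#' @param invalid_pad Samples of padding around invalid runs.
#' @param collect_events Assemble the full per-event table (default). When
#'   only the per-trial counts are needed (e.g. inside a large parameter
#'   sweep) this can be turned off; detection itself is unchanged.
#' @return An object of class `"ms_detection"`: a list with `events` (all
#'   events with participant/session/trial columns prepended), `trials`
#'   (per-trial table with `n_left`, `n_right`, `n_bin`, `excluded`,
#'   `reason`), and the `params` used.
#' @export
detect_study <- function(study, params = detection_params(),
                         invalid_pad = 10L, collect_events = TRUE) {
  stopifnot(inherits(study, "gaze_study"))
  idx <- study_index(study)
  events <- vector("list", length(study$trials))
  n_left <- n_right <- n_bin <- integer(nrow(idx))
  excluded <- logical(nrow(idx))
  reason <- character(nrow(idx))
  for (k in seq_along(study$trials)) {
    tr <- study$trials[[k]]
    ev <- tryCatch(
      if (collect_events) detect_trial(tr, params, invalid_pad)
      else .detect_trial_counts(tr, params, invalid_pad),
      microsacc_degenerate_trial = function(e) e)
    if (inherits(ev, "condition")) {
      excluded[k] <- TRUE
      reason[k] <- conditionMessage(ev)
      next
    }
    if (collect_events) {
      n_left[k] <- sum(ev$eye == "L")
      n_right[k] <- sum(ev$eye == "R")
      n_bin[k] <- sum(ev$eye == "BIN")
      if (nrow(ev)) {
        events[[k]] <- cbind(idx[k, , drop = FALSE], ev, row.names = NULL)
      }
    } else {
      n_left[k] <- ev["n_left"]
      n_right[k] <- ev["n_right"]
      n_bin[k] <- ev["n_bin"]
    }
  }
  events <- if (any(!vapply(events, is.null, TRUE))) {
    do.call(rbind, events[!vapply(events, is.null, TRUE)])
  } else {
    cbind(idx[0, ], data.frame(eye = character(), onset_idx = integer(),
                               offset_idx = integer(), duration_ms = numeric(),
                               peak_velocity_dps = numeric(),
                               amplitude_deg = numeric(),
                               dx_deg = numeric(), dy_deg = numeric()))
  }
  rownames(events) <- NULL
  trials <- cbind(idx, data.frame(n_left = n_left, n_right = n_right,
                                  n_bin = n_bin, excluded = excluded,
                                  reason = reason))
  structure(list(events = events, trials = trials, params = params),
            class = "ms_detection")
}

#' @export
print.ms_detection <- function(x, ...) {
  cat(sprintf(
    "Microsaccade detection: %d trials (%d excluded), %d binocular events\n",
    nrow(x$trials), sum(x$trials$excluded), sum(x$trials$n_bin)))
  cat(sprintf("  vfac %g, mindur %d, window %d, count mode %s\n",
              x$params$vfac, x$params$mindur, x$params$velocity_window,
              x$params$count_mode))
  invisible(x)
}

#' Per-trial event rates from a detection result
#'
#' Converts per-trial counts into rates (events/s) using the configured
#' count mode (binocular count by default, or the mean of the two monocular
#' counts).
#'
#' @param detection An `"ms_detection"` from [detect_study()].
#' @param trial_duration Trial duration in seconds.
#' @param count_mode Overrides the count mode in the detection params.
#' @return A data frame `participant_id, session, trial_index, rate,
#'   excluded` suitable for [ms_study()].
#' @export
rates_from_detection <- function(detection, trial_duration,
                                 count_mode = NULL) {
  stopifnot(inherits(detection, "ms_detection"))
  check_number(trial_duration, "trial_duration", lower = 0,
               allow_equal_lower = FALSE)
  mode <- if (is.null(count_mode)) detection$params$count_mode else count_mode
  tl <- detection$trials
  counts <- switch(mode,
                   BIN = tl$n_bin,
                   mean_LR = (tl$n_left + tl$n_right) / 2,
                   stopf("unknown count_mode '%s'", mode,
                         class = "microsacc_validation_error"))
  data.frame(participant_id = tl$participant_id, session = tl$session,
             trial_index = tl$trial_index,
             rate = trial_rate(counts, trial_duration),
             excluded = tl$excluded)
}
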