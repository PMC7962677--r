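#' Construct a binocular gaze trial
#'
#' A `gaze_trial` holds one fixation trial's timestamped binocular position
#' samples in degrees of visual angle, with per-eye validity flags. Samples
#' are 0-based indexed throughout the package; event intervals are inclusive.
#'
#' @param participant_id Participant identifier (coerced to character).
#' @param session `"pre"` or `"post"`.
#' @param trial_index 1-based trial number within the session.
#' @param sampling_rate Sampling rate in Hz.
#' @param xl,yl,xr,yr Left/right eye x/y positions in degrees.
#' @param time Sample times in seconds; defaults to a uniform grid starting
#'   at 0. Must be uniformly spaced to within 1e-6 s and consistent with
#'   `sampling_rate`.
#' @param valid_l,valid_r Per-sample validity flags; default all valid.
#'   Non-finite positions are always marked invalid for the affected eye.
#' @return An object of class `"gaze_trial"`.
#' @export
#' @examples
#' n <- 100
#' tr <- gaze_trial("p1", "pre", 1, 500, xl = rnorm(n, sd = 0.01),
#'                  yl = rnorm(n, sd = 0.01), xr = rnorm(n, sd = 0.01),
#'                  yr = rnorm(n, sd = 0.01))
#' tr
gaze_trial <- function(participant_id, session, trial_index, sampling_rate,
                       xl, yl, xr, yr, time = NULL,
                       valid_l = NULL, valid_r = NULL) {
  session <- match.arg(as.character(session), c("pre", "post"))
  check_number(trial_index, "trial_index", lower = 1, integer = TRUE)
  check_number(sampling_rate, "sampling_rate", lower = 0,
               allow_equal_lower = FALSE)
  n <- length(xl)
  if (n < 5L) {
    stopf("trial must contain at least 5 samples (got %d)", n,
          class = "microsacc_validation_error")
  }
  lens <- c(length(yl), length(xr), length(yr))
  if (any(lens != n)) {
    stopf("position arrays must all have the same length",
          class = "microsacc_validation_error")
  }
  if (is.null(time)) time <- (seq_len(n) - 1L) / sampling_rate
  if (length(time) != n) {
    stopf("'time' must have the same length as the position arrays",
          class = "microsacc_validation_error")
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    stopf("sample times must be strictly increasing",
          class = "microsacc_format_error")
  }
  if (diff(range(dt)) > 1e-6) {
    stopf("trial %s/%s/%d: non-uniform sample spacing (range %.3g s)",
          participant_id, session, trial_index, diff(range(dt)),
          class = "microsacc_format_error")
  }
  if (abs(stats::median(dt) - 1 / sampling_rate) > 1e-6) {
    stopf("trial %s/%s/%d: time spacing inconsistent with sampling_rate %g",
          participant_id, session, trial_index, sampling_rate,
          class = "microsacc_format_error")
  }
  if (is.null(valid_l)) valid_l <- rep(TRUE, n)
  if (is.null(valid_r)) valid_r <- rep(TRUE, n)
  valid_l <- as.logical(valid_l) & is.finite(xl) & is.finite(yl)
  valid_r <- as.logical(valid_r) & is.finite(xr) & is.finite(yr)
  structure(
    list(participant_id = as.character(participant_id), session = session,
         trial_index = as.integer(trial_index),
         sampling_rate = as.numeric(sampling_rate),
         time = as.numeric(time),
         xl = as.numeric(xl), yl = as.numeric(yl),
         xr = as.numeric(xr), yr = as.numeric(yr),
         valid_l = valid_l, valid_r = valid_r),
    class = "gaze_trial"
  )
}

#' @export
print.gaze_trial <- function(x, ...) {
  cat(sprintf(
    "Gaze trial %s/%s/%d: %d samples at %g Hz (%.3g s), %d invalid L / %d invalid R\n",
    x$participant_id, x$session, x$trial_index, length(x$time),
    x$sampling_rate, length(x$time) / x$sampling_rate,
    sum(!x$valid_l), sum(!x$valid_r)))
  invisible(x)
}

#' Pad invalid-sample runs
#'
#' Extends every contiguous run of invalid samples by `pad` samples on both
#' sides (clamped to the trial bounds), independently per eye. Detection
#' discards events that overlap invalid samples, so padding suppresses the
#' spurious velocity spikes at blink edges.
#'
#' @param trial A [gaze_trial()].
#' @param pad Number of samples to add on each side of every invalid run
#'   (>= 0; default 10, i.e. 20 ms at 500 Hz).
#' @return The trial with updated `valid_l`/`valid_r`.
#' @export
mark_invalid_runs <- function(trial, pad = 10L) {
  stopifnot(inherits(trial, "gaze_trial"))
  check_number(pad, "pad", lower = 0, integer = TRUE)
  pad <- as.integer(pad)
  if (pad == 0L) return(trial)
  for (eye in c("valid_l", "valid_r")) {
    v <- trial[[eye]]
    if (all(v)) next
    r <- rle(!v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    inv <- rep(FALSE, length(v))
    for (k in which(r$values)) {
      inv[max(1L, starts[k] - pad):min(length(v), ends[k] + pad)] <- TRUE
    }
    trial[[eye]] <- v & !inv
  }
  trial
}

#' Construct a gaze study dataset
#'
#' A `gaze_study` is an ordered collection of [gaze_trial()] objects covering
#' participants x sessions x trials.
#'
#' @param trials A list of `gaze_trial` objects.
#' @return An object of class `"gaze_study"`.
#' @export
gaze_study <- function(trials) {
  if (!length(trials) || !all(vapply(trials, inherits, TRUE, "gaze_trial"))) {
    stopf("'trials' must be a non-empty list of gaze_trial objects",
          class = "microsacc_validation_error")
  }
  structure(list(trials = trials), class = "gaze_study")
}

#' @export
print.gaze_study <- function(x, ...) {
  idx <- study_index(x)
  cat(sprintf("Gaze study: %d trials, %d participants, sessions: %s\n",
              nrow(idx), length(unique(idx$participant_id)),
              paste(sort(unique(idx$session)), collapse = ", ")))
  invisible(x)
}

#' @export
length.gaze_study <- function(x) length(x$trials)

# participant/session/trial index table of a study, in storage order
study_index <- function(study) {
  data.frame(
    participant_id = vapply(study$trials, `[[`, "", "participant_id"),
    session = vapply(study$trials, `[[`, "", "session"),
    trial_index = vapply(study$trials, `[[`, 1L, "trial_index"),
    stringsAsFactors = FALSE
  )
}
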