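#' Detection parameters
#'
#' Parameters of the median-based velocity-threshold microsaccade detector.
#' The defaults (`vfac = 5`, `mindur = 6` samples) are the conventional
#' settings for 500 Hz binocular recordings.
#'
#' @param vfac Velocity threshold scaling factor (> 0). The per-axis
#'   detection threshold is `vfac` times the median-based velocity spread.
#' @param mindur Minimum event duration in samples (>= 1): the least number
#'   of consecutive suprathreshold samples that constitutes an event.
#' @param velocity_window Length in samples of the moving-difference velocity
#'   kernel; odd, >= 3. The default 5-sample kernel averages positions over
#'   two samples on each side.
#' @param min_overlap Minimum number of shared samples for a left and a
#'   right event to be paired into one binocular event (>= 1).
#' @param merge_gap Runs of suprathreshold samples separated by at most this
#'   many subthreshold samples are merged before the duration test
#'   (>= 0; default 0, no merging).
#' @param count_mode Per-trial count used downstream: `"BIN"` (number of
#'   binocular events, the default) or `"mean_LR"` (mean of the two
#'   monocular counts).
#' @return An object of class `"detection_params"`.
#' @export
#' @examples
#' detection_params()
#' detection_params(vfac = 6, mindur = 4)
detection_params <- function(vfac = 5, mindur = 6L, velocity_window = 5L,
                             min_overlap = 1L, merge_gap = 0L,
                             count_mode = c("BIN", "mean_LR")) {
  check_number(vfac, "vfac", lower = 0, allow_equal_lower = FALSE)
  check_number(mindur, "mindur", lower = 1, integer = TRUE)
  check_number(velocity_window, "velocity_window", lower = 3, integer = TRUE)
  if (velocity_window %% 2 == 0) {
    stopf("field 'velocity_window' must be odd",
          class = "microsacc_validation_error")
  }
  check_number(min_overlap, "min_overlap", lower = 1, integer = TRUE)
  check_number(merge_gap, "merge_gap", lower = 0, integer = TRUE)
  count_mode <- match.arg(count_mode)
  structure(
    list(vfac = as.numeric(vfac), mindur = as.integer(mindur),
         velocity_window = as.integer(velocity_window),
         min_overlap = as.integer(min_overlap),
         merge_gap = as.integer(merge_gap), count_mode = count_mode),
    class = "detection_params"
  )
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Microsaccade detection parameters\n")
  cat(sprintf("  vfac: %g   mindur: %d samples   velocity window: %d\n",
              x$vfac, x$mindur, x$velocity_window))
  cat(sprintf("  binocular min overlap: %d   merge gap: %d   count mode: %s\n",
              x$min_overlap, x$merge_gap, x$count_mode))
  invisible(x)
}

#' Simulation configuration
#'
#' Configuration of the synthetic binocular gaze generator. The defaults
#' emulate a two-session (pre/post intervention) fixation study: 22
#' participants, 60 trials of 5.5 s per session sampled at 500 Hz, stable
#' per-participant microsaccade rates around 1.4 events/s with a
#' between-participant SD of 0.45 events/s, and a post-session rate reduced
#' to 85% of the pre-session rate.
#'
#' Events are drawn from a refractory-modified Poisson process (gaps are a
#' hard refractory interval plus an exponential wait whose intensity is
#' corrected for the dead time, so the realized event rate equals the
#' nominal rate). Drift is a discretized mean-reverting Ornstein-Uhlenbeck
#' process shared by the two eyes; sensor noise is per-eye independent
#' Gaussian. Microsaccade waveforms are raised-cosine velocity pulses with
#' peak velocity on a linear main sequence.
#'
#' @param n_participants Number of participants (>= 1).
#' @param n_trials_per_session Trials per session (>= 1).
#' @param trial_duration Trial length in seconds.
#' @param sampling_rate Sampling rate in Hz; must be at least
#'   `2 / trial_duration`.
#' @param base_rate_mean Mean pre-session microsaccade rate, events/s.
#' @param base_rate_sd Between-participant SD of the base rate, events/s.
#' @param post_rate_multiplier Ratio of post to pre expected rate, in (0, 1].
#' @param within_trial_rate_jitter_sd SD of the per-trial additive rate
#'   jitter, events/s (clamped at zero; a participant whose base rate is
#'   exactly zero stays silent).
#' @param refractory_interval Hard minimum gap between event onsets, s.
#' @param amplitude_log_mean,amplitude_log_sd Parameters of the lognormal
#'   event amplitude distribution, in log-degrees.
#' @param main_sequence_slope Peak velocity per degree of amplitude,
#'   (deg/s)/deg.
#' @param drift_sd Stationary SD of the fixational drift, degrees.
#' @param drift_mean_reversion Mean-reversion rate of the drift, 1/s.
#' @param noise_sd Per-sample, per-eye independent sensor noise SD, degrees.
#' @param blink_probability_per_trial Probability that a trial contains one
#'   blink (a run of invalid samples), in \[0, 1\].
#' @param seed Root seed; per-participant/per-trial child streams are derived
#'   from it by a fixed counter scheme so any subset is reproducible.
#' @return An object of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 2, n_trials_per_session = 4)
#' cfg
sim_config <- function(n_participants = 22L,
                       n_trials_per_session = 60L,
                       trial_duration = 5.5,
                       sampling_rate = 500,
                       base_rate_mean = 1.4,
                       base_rate_sd = 0.45,
                       post_rate_multiplier = 0.85,
                       within_trial_rate_jitter_sd = 0.2,
                       refractory_interval = 0.15,
                       amplitude_log_mean = log(0.55),
                       amplitude_log_sd = 0.25,
                       main_sequence_slope = 80,
                       drift_sd = 0.05,
                       drift_mean_reversion = 2,
                       noise_sd = 0.01,
                       blink_probability_per_trial = 0.05,
                       seed = 1L) {
  check_number(n_participants, "n_participants", lower = 1, integer = TRUE)
  check_number(n_trials_per_session, "n_trials_per_session", lower = 1,
               integer = TRUE)
  check_number(trial_duration, "trial_duration", lower = 0,
               allow_equal_lower = FALSE)
  check_number(sampling_rate, "sampling_rate",
               lower = 2 / trial_duration)
  check_number(base_rate_mean, "base_rate_mean", lower = 0)
  check_number(base_rate_sd, "base_rate_sd", lower = 0)
  check_number(post_rate_multiplier, "post_rate_multiplier", lower = 0,
               upper = 1, allow_equal_lower = FALSE)
  check_number(within_trial_rate_jitter_sd, "within_trial_rate_jitter_sd",
               lower = 0)
  check_number(refractory_interval, "refractory_interval", lower = 0)
  check_number(amplitude_log_mean, "amplitude_log_mean")
  check_number(amplitude_log_sd, "amplitude_log_sd", lower = 0)
  check_number(main_sequence_slope, "main_sequence_slope", lower = 0,
               allow_equal_lower = FALSE)
  check_number(drift_sd, "drift_sd", lower = 0)
  check_number(drift_mean_reversion, "drift_mean_reversion", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(blink_probability_per_trial, "blink_probability_per_trial",
               lower = 0, upper = 1)
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(n_participants = as.integer(n_participants),
         n_trials_per_session = as.integer(n_trials_per_session),
         trial_duration = as.numeric(trial_duration),
         sampling_rate = as.numeric(sampling_rate),
         base_rate_mean = as.numeric(base_rate_mean),
         base_rate_sd = as.numeric(base_rate_sd),
         post_rate_multiplier = as.numeric(post_rate_multiplier),
         within_trial_rate_jitter_sd = as.numeric(within_trial_rate_jitter_sd),
         refractory_interval = as.numeric(refractory_interval),
         amplitude_log_mean = as.numeric(amplitude_log_mean),
         amplitude_log_sd = as.numeric(amplitude_log_sd),
         main_sequence_slope = as.numeric(main_sequence_slope),
         drift_sd = as.numeric(drift_sd),
         drift_mean_reversion = as.numeric(drift_mean_reversion),
         noise_sd = as.numeric(noise_sd),
         blink_probability_per_trial = as.numeric(blink_probability_per_trial),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Gaze simulation configuration\n")
  cat(sprintf("  %d participants x 2 sessions x %d trials of %g s at %g Hz\n",
              x$n_participants, x$n_trials_per_session, x$trial_duration,
              x$sampling_rate))
  cat(sprintf("  base rate %g /s (sd %g), post multiplier %g, jitter sd %g\n",
              x$base_rate_mean, x$base_rate_sd, x$post_rate_multiplier,
              x$within_trial_rate_jitter_sd))
  cat(sprintf("  amplitude lognormal(%.3f, %.3f) deg, main-sequence slope %g\n",
              x$amplitude_log_mean, x$amplitude_log_sd, x$main_sequence_slope))
  cat(sprintf("  drift sd %g deg (reversion %g /s), noise sd %g deg, blink p %g\n",
              x$drift_sd, x$drift_mean_reversion, x$noise_sd,
              x$blink_probability_per_trial))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys are exactly the [sim_config()] argument names; absent keys take the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"sim_config"` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    stopf("config file '%s' does not exist", path,
          class = "microsacc_io_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "),
          class = "microsacc_validation_error")
  }
  do.call(sim_config, vals)
}
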