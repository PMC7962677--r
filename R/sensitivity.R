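#' Effect-size surface over detection parameters
#'
#' Re-runs the full detection + analysis pipeline from the raw gaze samples
#' for every (mindur, vfac) combination (no caching of threshold crossings
#' — both parameters change which samples form events) and records the
#' effect size per cell, along with the number of excluded trials. The
#' default grid is mindur 2..11 samples by vfac 3..8.
#'
#' @param study A [gaze_study()] of raw gaze trials.
#' @param trial_duration Trial duration in seconds (for rates).
#' @param params Baseline [detection_params()]; mindur and vfac are
#'   overridden per cell.
#' @param mindur_values Integer vector of minimum durations (samples).
#' @param vfac_values Numeric vector of velocity threshold scaling factors.
#' @param d_variant Cohen's d variant for the surface.
#' @param invalid_pad Samples of padding around invalid runs.
#' @return An object of class `"effect_surface"`: `mindur_values`,
#'   `vfac_values`, `d` (matrix mindur x vfac; `NA` where fewer than 2
#'   participants retain trials), `n_excluded` (matrix of excluded-trial
#'   counts), `d_variant`.
#' @export
parameter_sweep <- function(study, trial_duration,
                            params = detection_params(),
                            mindur_values = 2:11, vfac_values = 3:8,
                            d_variant = c("pooled", "pre_sd", "dz"),
                            invalid_pad = 10L) {
  stopifnot(inherits(study, "gaze_study"))
  d_variant <- match.arg(d_variant)
  nm <- length(mindur_values)
  nv <- length(vfac_values)
  d <- matrix(NA_real_, nm, nv,
              dimnames = list(mindur = mindur_values, vfac = vfac_values))
  n_excluded <- matrix(NA_integer_, nm, nv,
                       dimnames = dimnames(d))
  for (a in seq_len(nm)) {
    for (b in seq_len(nv)) {
      p <- params
      p$mindur <- as.integer(mindur_values[a])
      p$vfac <- as.numeric(vfac_values[b])
      det <- detect_study(study, p, invalid_pad, collect_events = FALSE)
      n_excluded[a, b] <- sum(det$trials$excluded)
      rates <- rates_from_detection(det, trial_duration)
      d[a, b] <- tryCatch({
        s <- summarize_sessions(rates)
        pre <- s$mean_rate[s$session == "pre"]
        post <- s$mean_rate[s$session == "post"]
        if (length(pre) < 2L) NA_real_ else cohens_d(pre, post, d_variant)
      }, microsacc_error = function(e) NA_real_)
    }
  }
  structure(list(mindur_values = as.integer(mindur_values),
                 vfac_values = as.numeric(vfac_values),
                 d = d, n_excluded = n_excluded, d_variant = d_variant),
            class = "effect_surface")
}

#' @export
print.effect_surface <- function(x, digits = 3, ...) {
  cat(sprintf("Effect-size surface (%s d): mindur %s x vfac %s\n",
              x$d_variant,
              paste(range(x$mindur_values), collapse = "-"),
              paste(range(x$vfac_values), collapse = "-")))
  cat(sprintf("  d range %.3f .. %.3f (%d missing cells)\n",
              min(x$d, na.rm = TRUE), max(x$d, na.rm = TRUE),
              sum(is.na(x$d))))
  invisible(x)
}

#' @export
as.data.frame.effect_surface <- function(x, ...) {
  grid <- expand.grid(mindur = x$mindur_values, vfac = x$vfac_values)
  grid$d <- as.vector(x$d)
  grid$n_excluded <- as.vector(x$n_excluded)
  grid
}

#' Bootstrap trial-count sensitivity curves
#'
#' Asks how stable the effect size and the pre/post correlation would have
#' been with fewer trials: for each `k` in `k_range` and each of `n_boot`
#' replicates, draws `k` trials with replacement — independently for every
#' participant and session — recomputes each participant's mean rate, then
#' the effect size and Pearson correlation across participants, and reports
#' the per-k bootstrap mean and percentile 95% interval (2.5th/97.5th
#' percentiles). Participants are never resampled.
#'
#' The RNG stream is documented and fixed: after `set.seed(seed)`, for each
#' k in ascending order, for each participant in sorted order, pre session
#' then post, one call `sample.int(n_trials, n_boot * k, replace = TRUE)`
#' whose draws fill an `n_boot` x `k` matrix by row (row = replicate).
#' Degenerate replicates (zero variance in any required denominator) are
#' redrawn from the continuing stream, participant-major, and counted.
#'
#' @param rates Per-trial rates data frame as in [ms_study()].
#' @param k_range Integer vector of trial counts to resample (each >= 3).
#' @param n_boot Number of bootstrap replicates per k (default 1000).
#' @param seed RNG seed; same seed gives bit-identical curves.
#' @param d_variant Cohen's d variant.
#' @return An object of class `"bootstrap_curves"`: `curves` (data frame
#'   `statistic` (`"effect_size"`/`"correlation"`), `k`, `mean`, `lo95`,
#'   `hi95`), plus `n_boot`, `seed`, `d_variant`, `n_redraws`.
#' @export
bootstrap_trial_curves <- function(rates, k_range = 3:60, n_boot = 1000L,
                                   seed = 1L,
                                   d_variant = c("pooled", "pre_sd", "dz")) {
  d_variant <- match.arg(d_variant)
  check_number(n_boot, "n_boot", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (any(k_range < 3)) {
    stopf("field 'k_range' must be >= 3 trials",
          class = "microsacc_validation_error")
  }
  if (is.null(rates$excluded)) rates$excluded <- FALSE
  used <- rates[!rates$excluded, , drop = FALSE]
  ids <- sort(unique(used$participant_id))
  pools <- lapply(ids, function(p) {
    list(pre = used$rate[used$participant_id == p & used$session == "pre"],
         post = used$rate[used$participant_id == p & used$session == "post"])
  })
  for (i in seq_along(ids)) {
    if (!length(pools[[i]]$pre) || !length(pools[[i]]$post)) {
      stopf("participant '%s' has no usable trials in one session", ids[i],
            class = "microsacc_validation_error")
    }
  }
  P <- length(ids)
  n_redraws <- 0L
  rows <- vector("list", 2L * length(k_range))
  eff <- function(pre, post) cohens_d(pre, post, d_variant)
  old_seed <- NULL
  with_seed(seed, {
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      premat <- matrix(NA_real_, n_boot, P)
      postmat <- matrix(NA_real_, n_boot, P)
      for (i in seq_len(P)) {
        for (sess in c("pre", "post")) {
          pool <- pools[[i]][[sess]]
          draws <- matrix(sample.int(length(pool), n_boot * k,
                                     replace = TRUE),
                          nrow = n_boot, ncol = k, byrow = TRUE)
          m <- rowMeans(matrix(pool[draws], nrow = n_boot))
          if (sess == "pre") premat[, i] <- m else postmat[, i] <- m
        }
      }
      degen <- function(b) {
        sp <- stats::sd(premat[b, ]); so <- stats::sd(postmat[b, ])
        sdd <- stats::sd(premat[b, ] - postmat[b, ])
        sp == 0 || so == 0 || sdd == 0
      }
      for (b in seq_len(n_boot)) {
        attempts <- 0L
        while (degen(b)) {
          attempts <- attempts + 1L
          if (attempts > 100L) {
            stopf("replicate stuck degenerate at k = %d", k,
                  class = "microsacc_degenerate_stat")
          }
          n_redraws <- n_redraws + 1L
          for (i in seq_len(P)) {
            for (sess in c("pre", "post")) {
              pool <- pools[[i]][[sess]]
              m <- mean(pool[sample.int(length(pool), k, replace = TRUE)])
              if (sess == "pre") premat[b, i] <- m else postmat[b, i] <- m
            }
          }
        }
      }
      dvals <- vapply(seq_len(n_boot),
                      function(b) eff(premat[b, ], postmat[b, ]), numeric(1))
      rvals <- vapply(seq_len(n_boot),
                      function(b) stats::cor(premat[b, ], postmat[b, ]),
                      numeric(1))
      qd <- stats::quantile(dvals, c(0.025, 0.975), names = FALSE)
      qr <- stats::quantile(rvals, c(0.025, 0.975), names = FALSE)
      rows[[2L * ki - 1L]] <- data.frame(statistic = "effect_size", k = k,
                                         mean = mean(dvals), lo95 = qd[1],
                                         hi95 = qd[2])
      rows[[2L * ki]] <- data.frame(statistic = "correlation", k = k,
                                    mean = mean(rvals), lo95 = qr[1],
                                    hi95 = qr[2])
    }
  })
  curves <- do.call(rbind, rows)
  rownames(curves) <- NULL
  structure(list(curves = curves, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), d_variant = d_variant,
                 n_redraws = n_redraws),
            class = "bootstrap_curves")
}

#' @export
print.bootstrap_curves <- function(x, ...) {
  cat(sprintf(
    "Bootstrap trial-count curves: k %d..%d, %d replicates, seed %d\n",
    min(x$curves$k), max(x$curves$k), x$n_boot, x$seed))
  for (st in unique(x$curves$statistic)) {
    cc <- x$curves[x$curves$statistic == st, ]
    last <- cc[which.max(cc$k), ]
    cat(sprintf("  %s at k=%d: %.3f [%.3f, %.3f]\n", st, last$k, last$mean,
                last$lo95, last$hi95))
  }
  if (x$n_redraws > 0) {
    cat(sprintf("  degenerate replicates redrawn: %d\n", x$n_redraws))
  }
  invisible(x)
}

#' @export
plot.bootstrap_curves <- function(x, statistic = "effect_size", ...) {
  cc <- x$curves[x$curves$statistic == statistic, ]
  graphics::plot(cc$k, cc$mean, type = "l", ylim = range(cc$lo95, cc$hi95),
                 xlab = "trials resampled (k)", ylab = statistic, ...)
  graphics::lines(cc$k, cc$lo95, lty = 3)
  graphics::lines(cc$k, cc$hi95, lty = 3)
  invisible(x)
}
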