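#' Per-trial event rate
#'
#' @param n_events Event count(s).
#' @param trial_duration Trial duration in seconds (> 0).
#' @return Rate in events/s.
#' @export
#' @examples
#' trial_rate(7, 5.5)
trial_rate <- function(n_events, trial_duration) {
  check_number(trial_duration, "trial_duration", lower = 0,
               allow_equal_lower = FALSE)
  n_events / trial_duration
}

#' Per-participant session summaries
#'
#' Collapses per-trial rates to one mean rate per participant and session,
#' omitting excluded trials. Every participant must have both sessions.
#'
#' @param rates Data frame with columns `participant_id`, `session`
#'   (`"pre"`/`"post"`), `trial_index`, `rate`, and optionally a logical
#'   `excluded`.
#' @return A data frame `participant_id, session, n_trials_used, mean_rate`
#'   sorted by participant then session (pre before post).
#' @export
summarize_sessions <- function(rates) {
  req <- c("participant_id", "session", "trial_index", "rate")
  missing <- setdiff(req, names(rates))
  if (length(missing)) {
    stopf("rates table is missing column(s): %s",
          paste(missing, collapse = ", "), class = "microsacc_schema_error")
  }
  if (is.null(rates$excluded)) rates$excluded <- FALSE
  for (p in unique(rates$participant_id)) {
    have <- unique(rates$session[rates$participant_id == p])
    if (!all(c("pre", "post") %in% have)) {
      stopf("participant '%s' is missing session '%s'", p,
            setdiff(c("pre", "post"), have)[1],
            class = "microsacc_validation_error")
    }
  }
  used <- rates[!rates$excluded, , drop = FALSE]
  agg <- stats::aggregate(used$rate,
                          by = list(participant_id = used$participant_id,
                                    session = used$session),
                          FUN = function(v) c(n = length(v), m = mean(v)))
  out <- data.frame(participant_id = agg$participant_id,
                    session = agg$session,
                    n_trials_used = as.integer(agg$x[, "n"]),
                    mean_rate = agg$x[, "m"])
  out$session <- factor(out$session, levels = c("pre", "post"))
  out <- out[order(out$participant_id, out$session), , drop = FALSE]
  out$session <- as.character(out$session)
  rownames(out) <- NULL
  out
}

#' Paired t-test on participant means
#'
#' Two-sided paired t-test of pre vs post per-participant means (wraps
#' [stats::t.test()]): `t = mean(pre - post) / (sd(pre - post) / sqrt(n))`
#' with the n-1 SD, `dof = n - 1`.
#'
#' @param pre,post Per-participant mean rates, paired by position.
#' @return A list with `t`, `dof`, `p`.
#' @export
paired_t <- function(pre, post) {
  .check_paired(pre, post, min_n = 2L)
  d <- pre - post
  if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, mean(abs(d)))) {
    stopf("zero variance of paired differences",
          class = "microsacc_degenerate_stat")
  }
  ht <- stats::t.test(pre, post, paired = TRUE)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = ht$p.value)
}

#' Cohen's d for the pre/post design
#'
#' Standardized mean difference `mean(pre) - mean(post)` divided by, per
#' variant: `"pooled"` (default) the root mean of the two group variances
#' `sqrt((sd(pre)^2 + sd(post)^2) / 2)`; `"pre_sd"` the pre-session SD; or
#' `"dz"` the SD of the paired differences (so that
#' `d_z * sqrt(n) = t`). All SDs use the n-1 denominator.
#'
#' @param pre,post Per-participant mean rates, paired by position.
#' @param variant `"pooled"`, `"pre_sd"` or `"dz"`.
#' @return The effect size (a number).
#' @export
cohens_d <- function(pre, post, variant = c("pooled", "pre_sd", "dz")) {
  .check_paired(pre, post, min_n = 2L)
  variant <- match.arg(variant)
  num <- mean(pre) - mean(post)
  if (num == 0) return(0)
  den <- switch(variant,
                pooled = sqrt((stats::sd(pre)^2 + stats::sd(post)^2) / 2),
                pre_sd = stats::sd(pre),
                dz = stats::sd(pre - post))
  if (!is.finite(den) || den < .Machine$double.eps) {
    stopf("zero denominator in Cohen's d (variant '%s')", variant,
          class = "microsacc_degenerate_stat")
  }
  num / den
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation (wraps [stats::cor.test()]); the p-value uses
#' the t transform `r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return A list with `r` and `p`.
#' @export
pearson_r <- function(a, b) {
  .check_paired(a, b, min_n = 3L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stopf("zero variance input to correlation",
          class = "microsacc_degenerate_stat")
  }
  ht <- stats::cor.test(a, b)
  list(r = unname(ht$estimate), p = ht$p.value)
}

.check_paired <- function(a, b, min_n) {
  if (length(a) != length(b)) {
    stopf("inputs must have equal length",
          class = "microsacc_validation_error")
  }
  if (length(a) < min_n) {
    stopf("need at least %d pairs (got %d)", min_n, length(a),
          class = "microsacc_validation_error")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stopf("inputs must be finite", class = "microsacc_validation_error")
  }
  invisible(TRUE)
}

#' Per-trial-index timecourse
#'
#' Mean rate across participants for each trial index and session
#' (excluded trials skipped), for plotting rate against trial number.
#'
#' @param rates Data frame as in [summarize_sessions()].
#' @return A data frame `trial_index, session, mean_rate, n_participants`,
#'   sorted by session (pre first) then trial index.
#' @export
trial_timecourse <- function(rates) {
  if (is.null(rates$excluded)) rates$excluded <- FALSE
  used <- rates[!rates$excluded, , drop = FALSE]
  agg <- stats::aggregate(used$rate,
                          by = list(trial_index = used$trial_index,
                                    session = used$session),
                          FUN = function(v) c(n = length(v), m = mean(v)))
  out <- data.frame(trial_index = agg$trial_index, session = agg$session,
                    mean_rate = agg$x[, "m"],
                    n_participants = as.integer(agg$x[, "n"]))
  out$session <- factor(out$session, levels = c("pre", "post"))
  out <- out[order(out$session, out$trial_index), , drop = FALSE]
  out$session <- as.character(out$session)
  rownames(out) <- NULL
  out
}

#' Fit the pre/post study analysis
#'
#' The study-level estimator: collapses per-trial event rates to
#' per-participant session means and computes the pre/post contrast —
#' session means and between-participant SDs, the two-sided paired t-test,
#' Cohen's d (all three variants, one chosen as the headline value), and
#' the pre/post stability correlation — plus the per-trial-index
#' timecourse.
#'
#' @param rates Data frame with columns `participant_id`, `session`
#'   (`"pre"`/`"post"`), `trial_index`, `rate` (events/s), optional logical
#'   `excluded` (e.g. from [rates_from_detection()]).
#' @param d_variant Headline Cohen's d variant: `"pooled"` (default),
#'   `"pre_sd"` or `"dz"`.
#' @return An object of class `"ms_study"` with components `summaries`,
#'   `result` (the study statistics), `timecourse`, `rates`, `d_variant`.
#'   Methods: `print`, `summary`, `coef`, `plot`.
#' @export
#' @examples
#' set.seed(1)
#' base <- rnorm(8, 1.4, 0.4)
#' rates <- do.call(rbind, lapply(seq_along(base), function(i) {
#'   data.frame(participant_id = sprintf("P%02d", i),
#'              session = rep(c("pre", "post"), each = 10), trial_index = 1:10,
#'              rate = c(rnorm(10, base[i], 0.2), rnorm(10, base[i] * 0.85, 0.2)))
#' }))
#' fit <- ms_study(rates)
#' fit
#' coef(fit)
ms_study <- function(rates, d_variant = c("pooled", "pre_sd", "dz")) {
  d_variant <- match.arg(d_variant)
  summaries <- summarize_sessions(rates)
  wide <- merge(summaries[summaries$session == "pre",
                          c("participant_id", "mean_rate")],
                summaries[summaries$session == "post",
                          c("participant_id", "mean_rate")],
                by = "participant_id", suffixes = c("_pre", "_post"))
  wide <- wide[order(wide$participant_id), , drop = FALSE]
  pre <- wide$mean_rate_pre
  post <- wide$mean_rate_post
  tt <- paired_t(pre, post)
  rr <- pearson_r(pre, post)
  d_all <- c(pooled = cohens_d(pre, post, "pooled"),
             pre_sd = cohens_d(pre, post, "pre_sd"),
             dz = cohens_d(pre, post, "dz"))
  result <- list(
    n_participants = length(pre),
    pre_mean = mean(pre), post_mean = mean(post),
    pre_sd = stats::sd(pre), post_sd = stats::sd(post),
    t_statistic = tt$t, dof = tt$dof, p_value = tt$p,
    cohens_d = unname(d_all[d_variant]), cohens_d_all = d_all,
    pearson_r = rr$r, r_p_value = rr$p)
  structure(list(summaries = summaries, result = result,
                 timecourse = trial_timecourse(rates),
                 participant_means = wide, rates = rates,
                 d_variant = d_variant),
            class = "ms_study")
}

#' @export
print.ms_study <- function(x, digits = 3, ...) {
  r <- x$result
  cat(sprintf("Pre/post microsaccade rate analysis (%d participants)\n",
              r$n_participants))
  cat(sprintf("  pre  %.*f events/s (sd %.*f)\n", digits, r$pre_mean,
              digits, r$pre_sd))
  cat(sprintf("  post %.*f events/s (sd %.*f)\n", digits, r$post_mean,
              digits, r$post_sd))
  cat(sprintf("  paired t(%d) = %.*f, p = %.3g\n", r$dof, digits,
              r$t_statistic, r$p_value))
  cat(sprintf("  Cohen's d (%s) = %.*f\n", x$d_variant, digits, r$cohens_d))
  cat(sprintf("  pre/post r = %.*f, p = %.3g\n", digits, r$pearson_r,
              r$r_p_value))
  invisible(x)
}

#' @export
summary.ms_study <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  d <- object$result$cohens_d_all
  cat(sprintf("  d variants: pooled %.*f, pre_sd %.*f, dz %.*f\n",
              digits, d["pooled"], digits, d["pre_sd"], digits, d["dz"]))
  n <- object$summaries$n_trials_used
  cat(sprintf("  trials used per session: %d-%d\n", min(n), max(n)))
  invisible(object)
}

#' @export
coef.ms_study <- function(object, ...) {
  r <- object$result
  c(pre_mean = r$pre_mean, post_mean = r$post_mean,
    pre_sd = r$pre_sd, post_sd = r$post_sd,
    t = r$t_statistic, p = r$p_value,
    cohens_d = r$cohens_d, pearson_r = r$pearson_r)
}

#' @export
plot.ms_study <- function(x, ...) {
  w <- x$participant_means
  lim <- range(w$mean_rate_pre, w$mean_rate_post)
  graphics::plot(w$mean_rate_pre, w$mean_rate_post, xlim = lim, ylim = lim,
                 xlab = "pre mean rate (events/s)",
                 ylab = "post mean rate (events/s)",
                 main = "Per-participant stability", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
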