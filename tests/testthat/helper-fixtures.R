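# Shared fixtures, built in code.

# small, fast simulation regime for unit tests
toy_config <- function(...) {
  args <- list(...)
  defaults <- list(n_participants = 3L, n_trials_per_session = 6L,
                   trial_duration = 2.5, blink_probability_per_trial = 0,
                   seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# a clean fixation trial: tiny noise, no drift, no events
quiet_trial <- function(n = 600, fs = 500, noise_sd = 0.002, seed = 5) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    gaze_trial("p1", "pre", 1, fs,
               xl = rnorm(n, sd = noise_sd), yl = rnorm(n, sd = noise_sd),
               xr = rnorm(n, sd = noise_sd), yr = rnorm(n, sd = noise_sd))
  })
}

# deterministic per-trial rates table for the statistics layer
toy_rates <- function(n_participants = 6, n_trials = 10, base = NULL,
                      multiplier = 0.85, noise = 0.15, seed = 3) {
  set.seed(seed)
  if (is.null(base)) base <- rnorm(n_participants, 1.4, 0.45)
  do.call(rbind, lapply(seq_len(n_participants), function(i) {
    data.frame(
      participant_id = sprintf("P%02d", i),
      session = rep(c("pre", "post"), each = n_trials),
      trial_index = rep(seq_len(n_trials), 2),
      rate = pmax(0, c(rnorm(n_trials, base[i], noise),
                       rnorm(n_trials, base[i] * multiplier, noise))))
  }))
}

# independent brute-force oracles -----------------------------------------

# velocity kernel evaluated sample by sample from the formula
oracle_velocity <- function(p, fs) {
  n <- length(p)
  v <- numeric(n)
  for (i in seq_len(n)) {
    if (i >= 3 && i <= n - 2) {
      v[i] <- (p[i + 2] + p[i + 1] - p[i - 1] - p[i - 2]) * fs / 6
    } else if (i >= 2 && i <= n - 1) {
      v[i] <- (p[i + 1] - p[i - 1]) * fs / 2
    }
  }
  v
}

oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_sigma <- function(v) sqrt(oracle_median(v^2) - oracle_median(v)^2)

# brute-force run scanner over a boolean mask
oracle_runs <- function(mask, mindur) {
  out <- NULL
  i <- 1
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1]) j <- j + 1
      if (j - i + 1 >= mindur) out <- rbind(out, c(i - 1, j - 1))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

oracle_paired_t <- function(pre, post) {
  d <- pre - post
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, dof = n - 1, p = 2 * pt(-abs(t), n - 1))
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# thinned-Poisson-with-dead-time event stream, built independently of the
# package's renewal construction
oracle_event_stream <- function(rate, tau, duration) {
  lambda <- rate / (1 - rate * tau)
  # dense homogeneous Poisson stream, thinned non-paralyzably
  t_all <- cumsum(rexp(ceiling(4 * lambda * duration) + 20, lambda))
  t_all <- t_all[t_all < duration]
  kept <- numeric(0)
  last <- -Inf
  for (t in t_all) {
    if (t - last >= tau) {
      kept <- c(kept, t)
      last <- t
    }
  }
  kept
}
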