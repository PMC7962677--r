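test_that("trial rates are counts per second", {
  expect_equal(trial_rate(0, 5.5), 0)
  expect_equal(trial_rate(11, 5.5), 2)
  expect_equal(trial_rate(7, 5.5), 7 / 5.5)
  expect_equal(trial_rate(c(3, 6), 3), c(1, 2))
  expect_error(trial_rate(3, 0), "trial_duration")
})

test_that("session summaries average the retained trials", {
  r <- toy_rates(n_participants = 2, n_trials = 3)
  r$rate <- rep(c(1, 2, 3, 2, 2, 2), 2)
  s <- summarize_sessions(r)
  expect_equal(s$mean_rate, rep(c(2, 2), 2))
  expect_equal(s$n_trials_used, rep(3L, 4))
  expect_equal(s$session, rep(c("pre", "post"), 2))

  # exclusions reduce n and the mean only over retained trials
  r60 <- data.frame(participant_id = "P01",
                    session = rep(c("pre", "post"), each = 60),
                    trial_index = rep(1:60, 2),
                    rate = c(rep(2, 60), rep(1, 60)),
                    excluded = FALSE)
  r60$rate[1:5] <- 99
  r60$excluded[1:5] <- TRUE
  s2 <- summarize_sessions(r60)
  expect_equal(s2$n_trials_used, c(55L, 60L))
  expect_equal(s2$mean_rate, c(2, 1))

  r_bad <- r[r$session == "pre" | r$participant_id != "P02", ]
  expect_error(summarize_sessions(r_bad), "P02")
})

test_that("paired t handles symmetric, degenerate and textbook cases", {
  pre <- c(1, 2, 3, 4)
  post <- c(1.5, 1.5, 3.5, 3.5)  # differences {-0.5, +0.5, -0.5, +0.5}
  res <- paired_t(pre, post)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$dof, 3)

  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)),
               class = "microsacc_degenerate_stat")

  got <- paired_t(c(1.5, 1.0, 2.0, 1.2), c(1.2, 0.9, 1.6, 1.1))
  want <- oracle_paired_t(c(1.5, 1.0, 2.0, 1.2), c(1.2, 0.9, 1.6, 1.1))
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
})

test_that("paired t and Pearson r match brute-force formulas on random input", {
  set.seed(404)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    a <- rnorm(n, 1.4, 0.5)
    b <- a * runif(1, 0.7, 1) + rnorm(n, 0, 0.2)
    tt <- paired_t(a, b)
    to <- oracle_paired_t(a, b)
    expect_equal(tt$t, to$t, tolerance = 1e-10)
    expect_equal(tt$p, to$p, tolerance = 1e-10)
    rr <- pearson_r(a, b)
    ro <- oracle_pearson(a, b)
    expect_equal(rr$r, ro$r, tolerance = 1e-10)
    expect_equal(rr$p, ro$p, tolerance = 1e-10)
  }
})

test_that("Cohen's d variants agree with their definitions", {
  pre <- c(1, 2, 3, 4)
  expect_equal(cohens_d(pre, pre, "pooled"), 0)
  expect_equal(cohens_d(pre, pre, "pre_sd"), 0)
  expect_equal(cohens_d(pre, pre, "dz"), 0)

  # from the printed summary statistics of a pre/post contrast:
  # means 1.40 / 1.18, sds 0.52 / 0.43 (two-point constructions)
  pre2 <- 1.40 + c(1, -1) * 0.52 / sqrt(2)
  post2 <- 1.18 + c(1, -1) * 0.43 / sqrt(2)
  expect_equal(sd(pre2), 0.52)
  expect_equal(cohens_d(pre2, post2, "pooled"),
               0.22 / sqrt((0.52^2 + 0.43^2) / 2), tolerance = 1e-12)
  expect_equal(cohens_d(pre2, post2, "pre_sd"), 0.22 / 0.52,
               tolerance = 1e-12)

  # scale invariance
  set.seed(7)
  a <- rnorm(10, 1.4, 0.5); b <- rnorm(10, 1.2, 0.4)
  for (v in c("pooled", "pre_sd", "dz")) {
    expect_equal(cohens_d(3 * a, 3 * b, v), cohens_d(a, b, v))
  }
  expect_error(cohens_d(c(1, 1, 1), c(0, 0, 0), "pooled"),
               class = "microsacc_degenerate_stat")
})

test_that("dz times sqrt(n) reproduces the paired t statistic exactly", {
  set.seed(505)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    a <- rnorm(n, 1.4, 0.5)
    b <- a + rnorm(n, -0.2, 0.15)
    expect_equal(cohens_d(a, b, "dz") * sqrt(n), paired_t(a, b)$t,
                 tolerance = 1e-12)
  }
})

test_that("Pearson r recovers exact linear relations", {
  a <- c(0.3, 1.1, 2.2, 2.9, 4.4)
  expect_equal(pearson_r(a, 2 * a + 1)$r, 1)
  expect_equal(pearson_r(a, -a)$r, -1)
  expect_error(pearson_r(a, rep(1, 5)),
               class = "microsacc_degenerate_stat")
  expect_error(pearson_r(a[1:2], a[1:2]), "at least 3")
})

test_that("timecourse averages participants per trial index", {
  r <- toy_rates(n_participants = 4, n_trials = 8)
  r$rate <- 1.3
  tc <- trial_timecourse(r)
  expect_equal(nrow(tc), 16)
  expect_true(all(tc$mean_rate == 1.3))
  expect_true(all(tc$n_participants == 4))

  # a within-session trend in the rates shows up as a positive slope
  r2 <- toy_rates(n_participants = 6, n_trials = 20, noise = 0.05)
  r2$rate <- r2$rate + 0.02 * r2$trial_index
  tc2 <- trial_timecourse(r2)
  pre_tc <- tc2[tc2$session == "pre", ]
  expect_gt(coef(lm(mean_rate ~ trial_index, pre_tc))[2], 0)
})

test_that("a true rate reduction separates the session timecourses", {
  cfg <- toy_config(n_participants = 22, n_trials_per_session = 12,
                    trial_duration = 5.5, post_rate_multiplier = 0.85,
                    base_rate_sd = 0.1, within_trial_rate_jitter_sd = 0.05,
                    seed = 31)
  out <- simulate_study(cfg)
  ev <- out$truth$events
  key <- function(p, s, t) paste(p, s, t)
  grid <- expand.grid(participant_id = sprintf("P%02d", 1:22),
                      trial_index = 1:12, stringsAsFactors = FALSE)
  rates <- do.call(rbind, lapply(c("pre", "post"), function(s) {
    counts <- vapply(seq_len(nrow(grid)), function(i) {
      sum(key(ev$participant_id, ev$session, ev$trial_index) ==
            key(grid$participant_id[i], s, grid$trial_index[i]))
    }, numeric(1))
    data.frame(participant_id = grid$participant_id, session = s,
               trial_index = grid$trial_index,
               rate = counts / cfg$trial_duration)
  }))
  tc <- trial_timecourse(rates)
  pre <- tc$mean_rate[tc$session == "pre"]
  post <- tc$mean_rate[tc$session == "post"]
  expect_gte(mean(post < pre), 0.8)
})

test_that("study fit reports the full contrast and is order invariant", {
  r <- toy_rates(n_participants = 8, n_trials = 15, seed = 12)
  fit <- ms_study(r)
  res <- fit$result
  expect_equal(res$n_participants, 8)
  expect_equal(res$dof, 7)
  expect_gt(res$pre_mean, res$post_mean)
  expect_equal(res$cohens_d, unname(res$cohens_d_all["pooled"]))
  expect_true(res$p_value >= 0 && res$p_value <= 1)

  # shuffling rows changes nothing
  r_shuf <- r[sample.int(nrow(r)), ]
  fit2 <- ms_study(r_shuf)
  expect_equal(fit2$result, res)

  # methods
  expect_output(print(fit), "paired t")
  expect_output(summary(fit), "d variants")
  cf <- coef(fit)
  expect_named(cf, c("pre_mean", "post_mean", "pre_sd", "post_sd", "t", "p",
                     "cohens_d", "pearson_r"))
  pdf(NULL)
  plot(fit)
  dev.off()

  # d variant selection is honored
  fit3 <- ms_study(r, d_variant = "pre_sd")
  expect_equal(fit3$result$cohens_d, unname(res$cohens_d_all["pre_sd"]))
})
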