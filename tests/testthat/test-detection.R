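test_that("velocity kernel is exact on constant and affine signals", {
  n <- 50
  v <- compute_velocity(rep(2.5, n), rep(-1, n), 500)
  expect_equal(v$vx, rep(0, n))
  expect_equal(v$vy, rep(0, n))

  # linear ramp p[n] = n * c at 500 Hz: interior velocity exactly c * 500
  c0 <- 0.003
  ramp <- (0:(n - 1)) * c0
  v <- compute_velocity(ramp, ramp, 500)$vx
  expect_equal(v[2:(n - 1)], rep(c0 * 500, n - 2))
  expect_equal(v[c(1, n)], c(0, 0))
})

test_that("velocity kernel matches its per-sample formula on random input", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    p <- rnorm(n)
    q <- rnorm(n)
    got <- compute_velocity(p, q, 500)
    expect_equal(got$vx, oracle_velocity(p, 500), tolerance = 1e-12)
    expect_equal(got$vy, oracle_velocity(q, 500), tolerance = 1e-12)
  }
  expect_error(compute_velocity(rnorm(4), rnorm(4), 500), "shorter")
  expect_error(compute_velocity(rnorm(10), rnorm(10), 500,
                                velocity_window = 4), "odd")
})

test_that("median-based threshold estimator handles symmetric and degenerate input", {
  v <- rep(c(1, -1), 10)
  eta <- estimate_thresholds(v, v, vfac = 5)
  expect_equal(unname(eta), c(5, 5))

  expect_error(estimate_thresholds(rep(2, 11), rnorm(11), 5),
               class = "microsacc_degenerate_trial")
  expect_error(estimate_thresholds(numeric(0), numeric(0), 5),
               class = "microsacc_degenerate_trial")
})

test_that("threshold estimator equals brute-force sorted medians", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(c(11, 20, 37, 101), 1)
    vx <- rnorm(n) * 10
    vy <- rt(n, df = 3)
    vfac <- runif(1, 3, 8)
    if (oracle_sigma(vx) < 1e-10 || oracle_sigma(vy) < 1e-10) {
      expect_error(estimate_thresholds(vx, vy, vfac),
                   class = "microsacc_degenerate_trial")
    } else {
      eta <- estimate_thresholds(vx, vy, vfac)
      expect_equal(unname(eta[1]), vfac * oracle_sigma(vx),
                   tolerance = 1e-12)
      expect_equal(unname(eta[2]), vfac * oracle_sigma(vy),
                   tolerance = 1e-12)
    }
  }
})

test_that("run-length detection honors the minimum duration boundary", {
  mk <- function(mask) ifelse(mask, 5, 0)  # suprathreshold where TRUE
  mindur <- 6
  mask <- rep(FALSE, 40)
  mask[10:(10 + mindur - 2)] <- TRUE  # length mindur - 1
  ev <- detect_monocular(mk(mask), mk(mask), 1, 1, mindur)
  expect_equal(nrow(ev), 0)

  mask[10 + mindur - 1] <- TRUE  # now exactly mindur
  ev <- detect_monocular(mk(mask), mk(mask), 1, 1, mindur)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 9)
  expect_equal(ev$offset, 9 + mindur - 1)

  expect_equal(nrow(detect_monocular(rep(0, 20), rep(0, 20), 1, 1, 3)), 0)
})

test_that("run-length detection matches a brute-force scanner on random masks", {
  set.seed(303)
  for (rep in 1:100) {
    n <- sample(30:120, 1)
    mask <- runif(n) < 0.35
    mindur <- sample(2:7, 1)
    ev <- detect_monocular(ifelse(mask, 3, 0), rep(0, n), 1, 1, mindur)
    want <- oracle_runs(mask, mindur)
    expect_equal(nrow(ev), nrow(want))
    if (nrow(want)) {
      expect_equal(as.numeric(ev$onset), as.numeric(want[, 1]))
      expect_equal(as.numeric(ev$offset), as.numeric(want[, 2]))
    }
  }
})

test_that("merge_gap joins nearby runs before the duration test", {
  mask <- rep(FALSE, 40)
  mask[c(10:12, 15:17)] <- TRUE  # two 3-runs, gap 2
  vx <- ifelse(mask, 3, 0)
  expect_equal(nrow(detect_monocular(vx, rep(0, 40), 1, 1, mindur = 6)), 0)
  ev <- detect_monocular(vx, rep(0, 40), 1, 1, mindur = 6, merge_gap = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$onset, ev$offset), c(9, 16))
})

test_that("events overlapping invalid samples are discarded", {
  mask <- rep(FALSE, 40)
  mask[10:18] <- TRUE
  invalid <- rep(FALSE, 40)
  invalid[15] <- TRUE
  ev <- detect_monocular(ifelse(mask, 3, 0), rep(0, 40), 1, 1, 6,
                         invalid = invalid)
  expect_equal(nrow(ev), 0)
})

test_that("binocular pairing is greedy, one-to-one and union-spanning", {
  l <- data.frame(onset = c(10L, 40L), offset = c(20L, 50L))
  # identical lists pair completely
  p <- pair_binocular(l, l)
  expect_equal(nrow(p), 2)
  expect_equal(p$onset, l$onset)
  expect_equal(p$offset, l$offset)

  # disjoint lists pair nothing
  r <- data.frame(onset = c(100L), offset = c(110L))
  expect_equal(nrow(pair_binocular(l, r)), 0)

  # L1 overlaps R1 and R2: greedy keeps (L1, R1), R2 stays unpaired
  lc <- data.frame(onset = 10L, offset = 30L)
  rc <- data.frame(onset = c(8L, 25L), offset = c(15L, 35L))
  p <- pair_binocular(lc, rc)
  expect_equal(nrow(p), 1)
  expect_equal(p$l, 1)
  expect_equal(p$r, 1)
  expect_equal(c(p$onset, p$offset), c(8, 30))  # union interval

  # min_overlap gate
  l2 <- data.frame(onset = 10L, offset = 20L)
  r2 <- data.frame(onset = 19L, offset = 30L)  # overlap of 2 samples
  expect_equal(nrow(pair_binocular(l2, r2, min_overlap = 2)), 1)
  expect_equal(nrow(pair_binocular(l2, r2, min_overlap = 3)), 0)

  expect_error(pair_binocular(data.frame(onset = c(5L, 1L),
                                         offset = c(8L, 3L)), l),
               "sorted")
})

test_that("event properties capture displacement, extent and overshoot", {
  n <- 60
  x <- rep(0, n)
  x[21:n] <- 0.5  # step displacement
  x[15:20] <- seq(0, 0.5, length.out = 6)
  y <- rep(0, n)
  v <- compute_velocity(x, y, 500)
  ev <- event_properties(x, y, v$vx, v$vy, 14, 20, 500)
  expect_equal(ev$dx_deg, 0.5)
  expect_equal(ev$dy_deg, 0)
  expect_equal(ev$amplitude_deg, 0.5)
  expect_equal(ev$duration_ms, 7 * 1000 / 500)

  # overshoot: extent exceeds net displacement
  x2 <- c(rep(0, 10), seq(0, 0.6, length.out = 6),
          seq(0.6, 0.5, length.out = 4), rep(0.5, 10))
  v2 <- compute_velocity(x2, rep(0, 30), 500)
  ev2 <- event_properties(x2, rep(0, 30), v2$vx, v2$vy, 9, 19, 500)
  expect_equal(ev2$dx_deg, 0.5)
  expect_equal(ev2$amplitude_deg, 0.6)
  expect_gt(ev2$amplitude_deg, abs(ev2$dx_deg))
})

test_that("one injected event in a quiet trial yields exactly one BIN event", {
  cfg <- toy_config(noise_sd = 0.002, drift_sd = 0, base_rate_mean = 0,
                    base_rate_sd = 0)
  set.seed(9)
  n <- 1250
  ms <- inject_microsaccade(matrix(0, n, 2), 600, 0.4, pi / 4, 12)
  tr <- gaze_trial("p1", "pre", 1, 500,
                   xl = ms[, 1] + rnorm(n, 0, 0.002),
                   yl = ms[, 2] + rnorm(n, 0, 0.002),
                   xr = ms[, 1] + rnorm(n, 0, 0.002),
                   yr = ms[, 2] + rnorm(n, 0, 0.002))
  ev <- detect_trial(tr, detection_params())
  bin <- ev[ev$eye == "BIN", ]
  expect_equal(nrow(bin), 1)
  expect_lt(abs(bin$onset_idx - 600), 10)
  expect_equal(bin$amplitude_deg, 0.4, tolerance = 0.1)
  expect_equal(bin$peak_velocity_dps,
               main_sequence_peak_velocity(0.4, 2 * 500 / 12),
               tolerance = 0.15)

  # same trial, same params: identical output
  expect_identical(ev, detect_trial(tr, detection_params()))

  # pure low-noise trace with no events
  expect_equal(sum(detect_trial(quiet_trial(), detection_params())$eye ==
                     "BIN"), 0)
})

test_that("detection is translation invariant and mirror symmetric", {
  sim <- simulate_trial(2, toy_config(), seed = 33)
  tr <- sim$trial
  base <- detect_trial(tr, detection_params())

  shifted <- tr
  shifted$xl <- tr$xl + 3.7; shifted$xr <- tr$xr + 3.7
  shifted$yl <- tr$yl - 1.2; shifted$yr <- tr$yr - 1.2
  got <- detect_trial(shifted, detection_params())
  expect_identical(got$onset_idx, base$onset_idx)
  expect_identical(got$offset_idx, base$offset_idx)
  expect_identical(got$eye, base$eye)
  expect_equal(got$peak_velocity_dps, base$peak_velocity_dps)
  expect_equal(got$dx_deg, base$dx_deg)
  expect_equal(got$amplitude_deg, base$amplitude_deg)

  mirrored <- tr
  mirrored$xl <- -tr$xl; mirrored$xr <- -tr$xr
  got2 <- detect_trial(mirrored, detection_params())
  expect_equal(got2$onset_idx, base$onset_idx)
  expect_equal(got2$dx_deg, -base$dx_deg)
  expect_equal(got2$dy_deg, base$dy_deg)
  expect_equal(got2$peak_velocity_dps, base$peak_velocity_dps)
})

test_that("raising vfac or mindur never increases the per-trial count", {
  cfg <- toy_config(n_participants = 2, n_trials_per_session = 3)
  out <- simulate_study(cfg)
  for (tr in out$study$trials) {
    counts_v <- vapply(c(3, 4, 5, 6, 8), function(vf) {
      ev <- detect_trial(tr, detection_params(vfac = vf))
      sum(ev$eye == "BIN")
    }, numeric(1))
    expect_true(all(diff(counts_v) <= 0))
    counts_m <- vapply(c(2L, 4L, 6L, 9L, 11L), function(md) {
      ev <- detect_trial(tr, detection_params(mindur = md))
      sum(ev$eye == "BIN")
    }, numeric(1))
    expect_true(all(diff(counts_m) <= 0))
  }
})

test_that("degenerate trials are excluded and logged, not counted as zero", {
  flat <- gaze_trial("p9", "pre", 1, 500, xl = rep(1, 100), yl = rep(0, 100),
                     xr = rep(1, 100), yr = rep(0, 100))
  expect_error(detect_trial(flat, detection_params()),
               class = "microsacc_degenerate_trial")

  ok <- simulate_trial(1.5, toy_config(), seed = 2)$trial
  study <- gaze_study(list(flat, ok))
  det <- detect_study(study, detection_params())
  expect_identical(det$trials$excluded, c(TRUE, FALSE))
  expect_match(det$trials$reason[1], "degenerate")
  rates <- rates_from_detection(det, 2.5)
  expect_identical(rates$excluded, c(TRUE, FALSE))
})

test_that("detected counts track ground-truth counts across trials", {
  cfg <- toy_config(n_participants = 5, n_trials_per_session = 10,
                    base_rate_sd = 0.6, seed = 77)
  out <- simulate_study(cfg)
  det <- detect_study(out$study)
  key <- function(d) paste(d$participant_id, d$session, d$trial_index)
  truth_counts <- table(factor(key(out$truth$events),
                               levels = key(det$trials)))
  expect_gte(cor(as.numeric(truth_counts), det$trials$n_bin), 0.9)
})

test_that("count mode mean_LR averages the monocular counts", {
  out <- simulate_study(toy_config(n_participants = 2,
                                   n_trials_per_session = 2))
  det <- detect_study(out$study)
  r1 <- rates_from_detection(det, 2.5, count_mode = "mean_LR")
  expect_equal(r1$rate,
               (det$trials$n_left + det$trials$n_right) / 2 / 2.5)
})
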