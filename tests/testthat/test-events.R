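test_that("body weight over a quiet 1 s window recovers mean and SD", {
  tr <- flat_trial(800)
  bw <- estimate_body_weight(tr)
  expect_equal(bw$bw, 800)
  expect_equal(bw$sd, 0)
  expect_equal(diff(bw$window) + 1L, 1500L)
  expect_true(bw$stationary)

  set.seed(11)
  noise <- rnorm(4500, 0, 2)
  tr2 <- raw_trial("n", "A", "T0", 1500, 400 + noise / 2, 400 + noise / 2,
                   "left")
  bw2 <- estimate_body_weight(tr2)
  expect_equal(bw2$bw, 800, tolerance = 0.2 / 800)
  expect_true(abs(bw2$sd - 2) < 0.3)
})

test_that("recordings shorter than 1 s cannot yield a body weight", {
  tr <- raw_trial("s", "A", "T0", 1500, rep(400, 750), rep(400, 750), "left")
  expect_error(estimate_body_weight(tr), class = "cmj_data_error")
})

test_that("threshold onset fires at the first BW - 5SD crossing", {
  f <- rep(400, 4000)
  f[3200:4000] <- 390 # total 780 < 790 = 800 - 5*2
  tr <- raw_trial("o", "A", "T0", 1500, f, f, "left")
  expect_identical(detect_onset_threshold(tr, bw_obj(800, 2)), 3200L)

  # degenerate SD: any dip triggers
  f2 <- rep(400, 4000); f2[2500:4000] <- 400 - 1e-9
  tr2 <- raw_trial("o2", "A", "T0", 1500, f2, f2, "left")
  expect_identical(detect_onset_threshold(tr2, bw_obj(800, 0)), 2500L)

  expect_error(detect_onset_threshold(flat_trial(800), bw_obj(800, 2)),
               class = "cmj_no_movement")
})

test_that("backtracking onset captures a preload excursion", {
  # band is [790, 810]; bump above 810 at j..j+60 (40 ms before onset_m1)
  f <- rep(400, 6000)
  j <- 3000L
  f[j:(j + 60)] <- 408 # total 816 > 810
  onset_m1 <- j + 60 + 60L # 40 ms after bump end
  f[onset_m1:6000] <- 380
  tr <- raw_trial("p", "A", "T0", 1500, f, f, "left")
  got <- detect_onset_backtrack(tr, bw_obj(800, 2), onset_m1)
  expect_identical(got, j - 1L) # last in-band sample before first departure

  # no exceedance in the lookback: identity
  f2 <- rep(400, 6000); f2[onset_m1:6000] <- 380
  tr2 <- raw_trial("p2", "A", "T0", 1500, f2, f2, "left")
  expect_identical(detect_onset_backtrack(tr2, bw_obj(800, 2), onset_m1),
                   onset_m1)

  # bump 150 ms before onset_m1 is outside the 100 ms lookback
  f3 <- rep(400, 6000)
  k <- onset_m1 - 225L # 150 ms
  f3[(k - 20):k] <- 408
  f3[onset_m1:6000] <- 380
  tr3 <- raw_trial("p3", "A", "T0", 1500, f3, f3, "left")
  expect_identical(detect_onset_backtrack(tr3, bw_obj(800, 2), onset_m1),
                   onset_m1)
})

test_that("take-off is the first sub-20 N sample after the peak", {
  f <- rep(400, 6000)
  f[3000:4000] <- seq(400, 800, length.out = 1001) # ramp to 1600 N total
  f[4001:4200] <- seq(800, 5, length.out = 200)    # falls through 20 N
  f[4201:6000] <- 5
  tr <- raw_trial("t", "A", "T0", 1500, f, f, "left")
  k <- detect_takeoff(tr, 3000L)
  expect_true(2 * f[k] < 20 && 2 * f[k - 1] >= 20)

  expect_error(detect_takeoff(flat_trial(800), 100L),
               class = "cmj_no_takeoff")
})

test_that("a total-unweighting dip is flagged but take-off still found after the peak", {
  f <- rep(400, 8000)
  f[3000:3500] <- seq(400, 5, length.out = 501)  # dip to 10 N total
  f[3501:4500] <- seq(5, 900, length.out = 1000) # recover to 1800 N peak
  f[4501:4700] <- seq(900, 2, length.out = 200)
  f[4701:8000] <- 2
  tr <- raw_trial("u", "A", "T0", 1500, f, f, "left")
  bw <- estimate_body_weight(tr)
  onset <- detect_onset_threshold(tr, bw)
  k <- detect_takeoff(tr, onset)
  expect_true(k > 4500) # after the propulsion peak, not the dip
  ev <- events_obj(bw, onset, onset, k)
  expect_true("total_unweighting" %in% qc_trial(tr, bw, ev))
})

test_that("a drifting baseline raises no_stationary_baseline", {
  cfg <- quiet_config(n_athletes = 1, trials_per_session = 1,
                      qc_violation = list(athlete = 1, session = "T0",
                                          trial = 1,
                                          type = "no_stationary_baseline"),
                      seed = 21)
  coh <- simulate_cohort(cfg)
  ev <- detect_events(coh$trials[[1]])
  expect_true("no_stationary_baseline" %in% ev$qc)

  clean <- simulate_cohort(quiet_config(n_athletes = 1,
                                        trials_per_session = 1, seed = 21))
  expect_length(detect_events(clean$trials[[1]])$qc, 0)
})

test_that("onset indices are invariant to adding a constant to both limbs", {
  cfg <- sim_config(n_athletes = 1, trials_per_session = 1, seed = 8)
  tr <- simulate_cohort(cfg)$trials[[1]]
  ev <- detect_events(tr)
  for (const in c(-50, 120)) {
    tr2 <- tr
    tr2$f_left <- tr$f_left + const / 2
    tr2$f_right <- tr$f_right + const / 2
    ev2 <- detect_events(tr2)
    expect_identical(ev2$onset_m1, ev$onset_m1)
    expect_identical(ev2$onset_m2, ev$onset_m2)
  }
})

test_that("noise-free trials recover onset and take-off within one sample", {
  cfg <- quiet_config(n_athletes = 3, trials_per_session = 1, seed = 5)
  coh <- simulate_cohort(cfg)
  for (id in names(coh$trials)) {
    ev <- detect_events(coh$trials[[id]])
    tru <- coh$truth[[id]]
    expect_lte(abs(ev$onset_m1 - tru$idx_onset), 1)
    expect_lte(abs(ev$onset_m2 - tru$idx_onset), 1)
    expect_lte(abs(ev$takeoff - tru$idx_takeoff), 1)
    expect_identical(ev$onset_m2, ev$onset_m1) # no preload: equality
  }
})

test_that("preload trials give onset_m2 strictly before onset_m1", {
  cfg <- quiet_config(n_athletes = 3, trials_per_session = 1,
                      preload_prob = 1, seed = 6)
  coh <- simulate_cohort(cfg)
  for (id in names(coh$trials)) {
    ev <- detect_events(coh$trials[[id]])
    tru <- coh$truth[[id]]
    expect_lt(ev$onset_m2, ev$onset_m1)
    expect_lte(abs(ev$onset_m2 - tru$idx_pre), 1)
  }
})
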