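test_that("equilibrium force integrates to zero velocity and displacement", {
  tr <- flat_trial(800)
  kin <- integrate_kinematics(tr, bw_obj(800, 0), 1600L)
  expect_equal(max(abs(kin$v)), 0)
  expect_equal(max(abs(kin$s)), 0)
  expect_equal(kin$m, 800 / 9.81)
})

test_that("constant acceleration gives the closed-form v and s", {
  fs <- 1500
  m <- 800 / 9.81
  n <- 2 * fs + 1L # onset at 1, 1500 samples of a = +1 afterwards... use onset mid-trial
  f_half <- rep(400, 3 * fs)
  onset <- fs + 1L
  f_half[onset:(3 * fs)] <- 400 + m * 1 / 2 # total = bw + m*1
  tr <- raw_trial("ca", "A", "T0", fs, f_half, f_half, "left")
  kin <- integrate_kinematics(tr, bw_obj(800, 0), onset)
  end <- onset + fs # exactly 1.0 s later
  expect_equal(kin$v[end], 1.000, tolerance = 1e-12)
  expect_equal(kin$s[end], 0.500, tolerance = 1e-12)
})

test_that("a piecewise-linear force prescription is recovered exactly", {
  # v quadratic (a linear) -> trapezoidal integration is exact
  fs <- 1500
  m <- 75
  tt <- (0:(3 * fs)) / fs
  onset <- fs + 1L
  a <- pmax(0, tt - 1) * 2 # linear ramp after onset at t = 1 s
  v_true <- pmax(0, tt - 1)^2
  f_total <- m * (a + 9.81)
  tr <- raw_trial("pl", "A", "T0", fs, f_total / 2, f_total / 2, "left")
  kin <- integrate_kinematics(tr, bw_obj(m * 9.81, 0), onset)
  expect_lt(max(abs(kin$v - v_true)), 1e-6)
})

test_that("phase segmentation finds the prescribed landmarks", {
  fs <- 1500
  v <- numeric(6000)
  onset <- 2000L
  v[2001:3000] <- -sin(pi * (1:1000) / 1000) # dips to -1 at 2500... min at 2501
  v[3001:4000] <- (1:1000) / 500             # rises through 0 immediately
  kin <- kin_obj(v, onset, fs = fs)
  ev <- events_obj(bw_obj(75 * 9.81, 0), onset, onset, 4000L)
  ph <- segment_phases(kin, ev)
  expect_identical(ph$idx_vmin, 2500L) # -sin peaks at sample 500 of the dip
  expect_identical(ph$idx_v0, 3001L)
  b <- ph$bounds
  expect_identical(b$unweighting[2], b$braking[1])
  expect_identical(b$braking[2], b$propulsion[1])
  expect_identical(b$unweighting[1], onset)
  expect_identical(b$propulsion[2], 4000L)
})

test_that("phase segmentation tie-breaks to the earliest minimum and errors cleanly", {
  v <- numeric(5000)
  v[2001:2500] <- -1 # flat minimum: earliest index taken
  v[2501:3000] <- seq(-1, 1, length.out = 500)
  kin <- kin_obj(v, 1500L)
  ev <- events_obj(bw_obj(700, 0), 1500L, 1500L, 3500L)
  expect_identical(segment_phases(kin, ev)$idx_vmin, 2001L)

  kin2 <- kin_obj(abs(v), 1500L)
  expect_error(segment_phases(kin2, ev), class = "cmj_no_countermovement")

  v3 <- numeric(5000); v3[2001:3500] <- -1
  kin3 <- kin_obj(v3, 1500L)
  expect_error(segment_phases(kin3, ev), class = "cmj_no_propulsion")
})

test_that("phase impulse matches rectangle areas and null net force", {
  fs <- 1500
  m <- 800 / 9.81
  f_half <- rep(400, 6000)
  ph <- structure(list(bounds = list(
    unweighting = c(2000L, 2300L), braking = c(2300L, 2600L),
    propulsion = c(2600L, 2900L)
  )), class = "cmj_phases")
  tr <- raw_trial("pi", "A", "T0", fs, f_half, f_half, "left")
  expect_equal(phase_impulse(tr, bw_obj(800, 0), ph, "left", "braking"), 0)

  # constant net m*0.5 N over 0.2 s (300 samples) -> 0.100 N.s/kg
  f2 <- f_half
  f2[2600:2900] <- 400 + m * 0.5
  tr2 <- raw_trial("pi2", "A", "T0", fs, f2, f_half, "left")
  expect_equal(phase_impulse(tr2, bw_obj(800, 0), ph, "left", "propulsion"),
               0.100, tolerance = 1e-12)
})

test_that("limb-phase impulses sum to take-off velocity (conservation)", {
  cfg <- sim_config(n_athletes = 2, trials_per_session = 1, seed = 13)
  coh <- simulate_cohort(cfg)
  for (id in names(coh$trials)) {
    tr <- coh$trials[[id]]
    ev <- detect_events(tr)
    kin <- integrate_kinematics(tr, ev$bw, ev$onset_m2)
    ph <- segment_phases(kin, ev)
    tot <- 0
    for (limb in c("left", "right")) {
      for (phase in c("unweighting", "braking", "propulsion")) {
        tot <- tot + phase_impulse(tr, ev$bw, ph, limb, phase)
      }
    }
    expect_equal(tot, kin$v[ev$takeoff], tolerance = 1e-9)
  }
})

test_that("jump height follows v^2 / 2g", {
  kin <- kin_obj(c(rep(0, 99), 2.0), 1L)
  ev <- events_obj(bw_obj(700, 0), 1L, 1L, 100L)
  expect_equal(jump_height(kin, ev), 0.2038736, tolerance = 1e-6)
  kin$v[100] <- 2.8
  expect_equal(jump_height(kin, ev), 0.3995922, tolerance = 1e-6)
  kin$v[100] <- 0
  expect_error(jump_height(kin, ev), class = "cmj_data_error")
})

test_that("contraction time is the method-2 onset to take-off interval", {
  ev <- events_obj(bw_obj(700, 0), 1600L, 1500L, 2850L)
  expect_equal(contraction_time(ev, 1500), 0.900)
  ev2 <- events_obj(bw_obj(700, 0), 840L, 1L, 841L)
  expect_equal(contraction_time(ev2, 1000), 0.840)
})

test_that("RSImod reproduces the session-mean worked examples", {
  expect_equal(round(rsi_mod(0.37, 0.84), 2), 0.44)
  expect_equal(round(rsi_mod(0.35, 0.89), 2), 0.39)
  expect_equal(rsi_mod(0, 1), 0)
  expect_error(rsi_mod(0.3, 0), class = "cmj_data_error")
})

test_that("F_TOTAL sums independent per-limb peaks", {
  expect_equal(f_total(7.7, 7.5), 15.2)
  expect_equal(f_total(0, 0), 0)
  p <- 6.3
  expect_equal(f_total(p, p), 2 * p)
})

test_that("asymmetry index is antisymmetric and zero at symmetry", {
  expect_equal(asymmetry_index(1, 1), 0)
  expect_equal(asymmetry_index(2, 1), 100 / 3, tolerance = 1e-9)
  expect_equal(asymmetry_index(1, 2), -100 / 3, tolerance = 1e-9)
  set.seed(3)
  for (i in 1:20) {
    u <- runif(1, 0.2, 3); v <- runif(1, 0.2, 3)
    expect_equal(asymmetry_index(u, v), -asymmetry_index(v, u))
  }
  expect_error(asymmetry_index(1, -1), class = "cmj_data_error")
})

test_that("best-trial selection maximizes jump height with first-wins ties", {
  mk <- function(jh, qc = character(0)) {
    list(qc = qc, metrics = data.frame(jump_height = jh))
  }
  trials <- list(mk(0.31), mk(0.35), mk(0.33))
  expect_equal(select_best_trial(trials)$metrics$jump_height, 0.35)
  tied <- list(mk(0.35), mk(0.35))
  expect_identical(select_best_trial(tied), tied[[1]])
  excluded <- list(mk(0.4, "total_unweighting"), mk(0.5, "no_takeoff"))
  expect_error(select_best_trial(excluded), class = "cmj_data_error")
})

test_that("impulse-momentum jump height matches the analytic flight time", {
  cfg <- quiet_config(n_athletes = 3, trials_per_session = 1, seed = 17)
  coh <- simulate_cohort(cfg)
  for (id in names(coh$trials)) {
    tr <- coh$trials[[id]]
    tru <- coh$truth[[id]]
    ev <- detect_events(tr)
    kin <- integrate_kinematics(tr, ev$bw, ev$onset_m2)
    jh <- jump_height(kin, ev)
    expect_equal(jh, 9.81 * tru$t_flight^2 / 8, tolerance = 1e-3)
  }
})
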