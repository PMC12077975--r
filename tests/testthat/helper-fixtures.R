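# In-code fixtures used across the test files.

# A flat dual-plate trial: total force `total_n`, split evenly.
flat_trial <- function(total_n = 800, fs = 1500, secs = 3,
                       involved = "left") {
  n <- round(secs * fs)
  raw_trial("flat", "A01", "T0", fs,
            rep(total_n / 2, n), rep(total_n / 2, n), involved)
}

# A hand-built body-weight object (bypasses estimation).
bw_obj <- function(bw, sd, window = c(1L, 1500L), stationary = TRUE) {
  structure(list(bw = bw, sd = sd, window = window, stationary = stationary),
            class = "cmj_bodyweight")
}

# Events object wrapper for low-level kinetics calls.
events_obj <- function(bw, onset_m1, onset_m2 = onset_m1, takeoff) {
  structure(list(bw = bw, onset_m1 = as.integer(onset_m1),
                 onset_m2 = as.integer(onset_m2),
                 takeoff = as.integer(takeoff), qc = character(0)),
            class = "cmj_events")
}

# Minimal kinetics object with a prescribed velocity vector.
kin_obj <- function(v, onset, m = 75, fs = 1500) {
  structure(list(a = c(0, diff(v)) * fs, v = v, s = cumsum(v) / fs,
                 m = m, g = 9.81, onset = as.integer(onset), fs = fs),
            class = "cmj_kinetics")
}

# Noise-free simulation config (exact ground truth).
quiet_config <- function(...) {
  sim_config(noise_amp = 0, white_noise_sd = 0, trial_cv = 0,
             share_wiggle_sd = 0, ...)
}

# The deficit-recovery study conditions: involved-limb share reduced by
# 20% over the last tenth of the movement at T1, which delivers a mean
# nodewise Cohen's d of about 1.5 over the window at the default noise
# level (see the methods vignette for the calibration).
recovery_config <- function(delta = 0.20, seed = 1, ...) {
  sim_config(n_athletes = 10, trials_per_session = 3,
             deficit = list(window = c(90, 100), delta = delta,
                            session = "T1"),
             seed = seed, ...)
}
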