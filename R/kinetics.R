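# Impulse-momentum kinetics and discrete metrics ----------------------------
#
# The total force-time curve is integrated from the method-2 onset
# (stationary start, v = 0) to give centre-of-mass acceleration,
# velocity and displacement; phases are segmented at the velocity
# minimum and the zero-velocity upcrossing; discrete per-limb metrics
# and interlimb asymmetry indices follow.

#' Integrate total force to centre-of-mass kinematics
#'
#' Computes `a = F_total / m - g` pointwise and integrates (cumulative
#' trapezoid) from `onset` with `v = 0`, `s = 0` there; body mass is
#' derived as `bw / g`.  Values before `onset` are held at zero
#' (stationary standing).
#'
#' @param trial a `cmj_trial`.
#' @param bw a `cmj_bodyweight`.
#' @param onset integration start (normally the method-2 onset, where
#'   the zero-initial-velocity assumption holds).
#' @param g gravitational acceleration, m/s^2.
#' @return a `cmj_kinetics` list with full-length vectors `a`, `v`, `s`,
#'   plus `m` (kg), `g`, `onset`, `fs`.
#' @export
integrate_kinematics <- function(trial, bw, onset, g = GRAVITY) {
  m <- bw$bw / g
  if (!is.finite(m) || m <= 0) cmj_stop("non-positive body mass", "cmj_data_error")
  onset <- as.integer(onset)
  f <- total_force(trial)
  n <- length(f)
  a <- (f - bw$bw) / m
  v <- numeric(n)
  s <- numeric(n)
  dt <- 1 / trial$fs
  seg <- onset:n
  v[seg] <- pracma::cumtrapz(a[seg])[, 1] * dt
  s[seg] <- pracma::cumtrapz(v[seg])[, 1] * dt
  structure(
    list(a = a, v = v, s = s, m = m, g = g, onset = onset, fs = trial$fs),
    class = "cmj_kinetics"
  )
}

#' Segment the countermovement into phases
#'
#' Unweighting runs from onset to the velocity minimum, braking from the
#' velocity minimum to the zero-velocity upcrossing, propulsion from
#' there to take-off.  Ties at the velocity minimum break to the
#' earliest index.
#'
#' @param kin a `cmj_kinetics`.
#' @param events a `cmj_events` (uses `takeoff`).
#' @return a `cmj_phases` list: `idx_vmin`, `idx_v0`, and a `bounds`
#'   list of inclusive index pairs for `unweighting`, `braking`,
#'   `propulsion`.
#' @export
segment_phases <- function(kin, events) {
  onset <- as.integer(kin$onset)
  takeoff <- as.integer(events$takeoff)
  if (is.na(takeoff) || takeoff <= onset + 2L) {
    cmj_stop("invalid onset/take-off for phase segmentation", "cmj_data_error")
  }
  inner <- (onset + 1L):(takeoff - 1L)
  v <- kin$v
  if (min(v[inner]) >= 0) {
    cmj_stop("velocity never negative after onset (no countermovement)",
             "cmj_no_countermovement")
  }
  idx_vmin <- inner[which.min(v[inner])]
  after <- (idx_vmin + 1L):(takeoff - 1L)
  up <- after[v[after] >= 0]
  if (!length(up)) {
    cmj_stop("velocity never returns to zero before take-off",
             "cmj_no_propulsion")
  }
  idx_v0 <- up[1]
  structure(
    list(
      idx_vmin = idx_vmin, idx_v0 = idx_v0,
      bounds = list(
        unweighting = c(onset, idx_vmin),
        braking = c(idx_vmin, idx_v0),
        propulsion = c(idx_v0, takeoff)
      )
    ),
    class = "cmj_phases"
  )
}

#' Resolve a limb label against a trial
#' @noRd
limb_channel <- function(trial, limb) {
  limb <- match.arg(limb, c("left", "right", "involved", "uninvolved"))
  side <- switch(limb,
    left = "left", right = "right",
    involved = trial$involved_side,
    uninvolved = setdiff(c("left", "right"), trial$involved_side)
  )
  if (side == "left") trial$f_left else trial$f_right
}

#' Net impulse of one limb over one phase
#'
#' Trapezoidal integral over the phase of `F_limb - bw/2` (the limb's
#' even static share of body weight removed), divided by body mass;
#' units N.s/kg.  Unweighting impulses are negative for valid jumps,
#' propulsion impulses positive.
#'
#' @param trial a `cmj_trial`.
#' @param bw a `cmj_bodyweight`.
#' @param phases a `cmj_phases`.
#' @param limb `"left"`, `"right"`, `"involved"` or `"uninvolved"`.
#' @param phase `"unweighting"`, `"braking"` or `"propulsion"`.
#' @param g gravitational acceleration.
#' @return net impulse in N.s/kg.
#' @export
phase_impulse <- function(trial, bw, phases, limb, phase, g = GRAVITY) {
  phase <- match.arg(phase, c("unweighting", "braking", "propulsion"))
  b <- phases$bounds[[phase]]
  if (b[2] <= b[1]) cmj_stop("empty phase interval", "cmj_data_error")
  f <- limb_channel(trial, limb)
  m <- bw$bw / g
  idx <- b[1]:b[2]
  pracma::trapz(f[idx] - bw$bw / 2) / trial$fs / m
}

#' Net peak force of one limb
#'
#' Maximum of `(F_limb - bw/2) / m` over the whole movement
#' `[onset, takeoff)`, in N/kg.  Per-limb peaks are maximized
#' independently (they may occur at different instants).
#'
#' @inheritParams phase_impulse
#' @param events a `cmj_events`.
#' @param onset movement start index; defaults to the method-1 onset.
#' @return net peak force in N/kg.
#' @export
peak_force <- function(trial, bw, events, limb, onset = events$onset_m1,
                       g = GRAVITY) {
  f <- limb_channel(trial, limb)
  m <- bw$bw / g
  idx <- onset:(events$takeoff - 1L)
  max(f[idx] - bw$bw / 2) / m
}

#' Jump height by the impulse-momentum method
#'
#' `JH = v(takeoff)^2 / (2 g)`, with take-off velocity from the
#' integrated centre-of-mass velocity.
#'
#' @param kin a `cmj_kinetics`.
#' @param events a `cmj_events`.
#' @return jump height in m.
#' @export
jump_height <- function(kin, events) {
  v_to <- kin$v[events$takeoff]
  if (!is.finite(v_to) || v_to <= 0) {
    cmj_stop("non-positive take-off velocity", "cmj_data_error")
  }
  v_to^2 / (2 * kin$g)
}

#' Contraction time
#'
#' Time from movement initiation (method-2 onset) to take-off, seconds.
#'
#' @param events a `cmj_events`.
#' @param fs sampling rate in Hz.
#' @return contraction time in s.
#' @export
contraction_time <- function(events, fs) {
  (events$takeoff - events$onset_m2) / fs
}

#' Modified reactive strength index
#'
#' Ratio of jump height to contraction time (dimensionless, "AU").
#'
#' @param jh jump height, m.
#' @param ct contraction time, s.
#' @return RSImod.
#' @export
rsi_mod <- function(jh, ct) {
  if (any(ct <= 0)) cmj_stop("contraction time must be positive", "cmj_data_error")
  jh / ct
}

#' Total peak force
#'
#' Sum of the left and right net peak vertical forces (N/kg), each
#' maximized independently over the movement.
#'
#' @param peak_left,peak_right per-limb net peak forces, N/kg.
#' @return F_TOTAL in N/kg.
#' @export
f_total <- function(peak_left, peak_right) peak_left + peak_right

#' Interlimb asymmetry index
#'
#' `(uninvolved - involved) / (uninvolved + involved) * 100`; positive
#' values mean the uninvolved limb's metric is larger.  The formula is
#' applied to signed metrics as-is (so negative-valued unweighting
#' impulses keep their natural sign convention).
#'
#' @param uninvolved,involved metric values for the two limbs.
#' @return asymmetry index in percent.
#' @export
asymmetry_index <- function(uninvolved, involved) {
  den <- uninvolved + involved
  if (any(den == 0)) cmj_stop("zero denominator in asymmetry index", "cmj_data_error")
  (uninvolved - involved) / den * 100
}

#' Select the best trial of a session
#'
#' Among QC-passing analyzed trials, returns the one with the greatest
#' jump height; ties break to the earliest trial.
#'
#' @param results list of `cmj_trial_result` objects (see
#'   [analyze_trial()]).
#' @return the selected element of `results`.
#' @export
select_best_trial <- function(results) {
  ok <- vapply(results, function(r) length(r$qc) == 0 && is.finite(r$metrics$jump_height),
               logical(1))
  if (!any(ok)) cmj_stop("no QC-passing trials to select from", "cmj_data_error")
  cand <- which(ok)
  jh <- vapply(results[cand], function(r) r$metrics$jump_height, numeric(1))
  results[[cand[which.max(jh)]]]
}
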