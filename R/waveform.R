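# Waveform time normalization ----------------------------------------------

#' Time-normalize a per-limb force curve onto 101 nodes
#'
#' Linearly interpolates the mass-normalized limb force `F_limb / m`
#' onto `n_nodes` equally spaced time points spanning movement
#' initiation (method-1 onset) to take-off, so that node 0 is onset and
#' node 100 is take-off.  Endpoints equal the raw endpoint values
#' exactly.
#'
#' @param trial a `cmj_trial`.
#' @param events a `cmj_events` (uses `onset_m1`, `takeoff` and the
#'   embedded body weight for mass).
#' @param limb `"left"`, `"right"`, `"involved"` or `"uninvolved"`.
#' @param n_nodes number of nodes (default 101, i.e. 0..100% of the
#'   movement).
#' @param net if `TRUE`, subtract the limb's static share `bw / (2 m)`
#'   so the waveform is gravity-netted; default keeps absolute force
#'   per unit mass (N/kg).
#' @param g gravitational acceleration.
#' @return numeric vector of length `n_nodes`.
#' @export
time_normalize <- function(trial, events, limb, n_nodes = 101L,
                           net = FALSE, g = GRAVITY) {
  i0 <- events$onset_m1
  i1 <- events$takeoff
  if (is.na(i0) || is.na(i1) || i1 - i0 < 1L) {
    cmj_stop("movement segment too short to normalize", "cmj_data_error")
  }
  f <- limb_channel(trial, limb)
  m <- events$bw$bw / g
  y <- f / m
  if (net) y <- y - events$bw$bw / (2 * m)
  xout <- seq(i0, i1, length.out = n_nodes)
  out <- approx(seq_along(y), y, xout = xout)$y
  # guard against floating drift at the exact endpoints
  out[1] <- y[i0]
  out[n_nodes] <- y[i1]
  out
}
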