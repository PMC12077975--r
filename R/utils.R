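#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition so callers can distinguish error kinds
#' @noRd
cmj_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "cmj_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Smooth unit-variance Gaussian noise
#'
#' White Gaussian noise convolved with a Gaussian kernel whose full width
#' at half maximum is `fwhm` (in sample/node units), rescaled so the
#' marginal standard deviation is 1.  Used both by the synthetic trial
#' generator (within-trial smooth noise) and by the SPM calibration
#' simulations (smooth Gaussian null fields).
#'
#' @param n number of series to generate (rows).
#' @param len series length (columns).
#' @param fwhm kernel full width at half maximum in sample units;
#'   `fwhm = 0` returns white noise.
#' @return an `n x len` matrix with (approximately) unit marginal variance.
#' @export
smooth_gaussian_fields <- function(n, len, fwhm) {
  stopifnot(n >= 1, len >= 1, fwhm >= 0)
  if (fwhm == 0) {
    return(matrix(rnorm(n * len), nrow = n))
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- kern / sqrt(sum(kern^2)) # unit output variance
  out <- matrix(0, nrow = n, ncol = len)
  for (i in seq_len(n)) {
    out[i, ] <- conv_center(rnorm(len + 2 * length(kern)), kern, len)
  }
  out
}

#' Centered FFT convolution: smooth padded white noise, return `len`
#' central samples
#' @noRd
conv_center <- function(x, kern, len) {
  pad <- length(kern)
  half <- (length(kern) - 1) %/% 2
  z <- stats::convolve(x, rev(kern), type = "open")
  z[(pad + half + 1):(pad + half + len)]
}

#' Smooth unit-variance Gaussian noise along a sampled time axis
#'
#' For wide kernels the process is generated on a grid decimated to
#' ~sigma/5 and linearly interpolated back: the Gaussian-smoothed
#' process has negligible power above that scale (autocorrelation 0.99
#' at one coarse step), so the interpolation error is well under 1% of
#' the variance while the convolution cost drops by the decimation
#' factor.
#' @noRd
smooth_gaussian_vec <- function(len, sigma_samples) {
  step <- max(1L, floor(sigma_samples / 5))
  m <- as.integer(ceiling(len / step)) + 3L
  sig_c <- sigma_samples / step
  half <- max(1L, ceiling(4 * sig_c))
  kern <- exp(-((-half:half)^2) / (2 * sig_c^2))
  kern <- kern / sqrt(sum(kern^2))
  pad <- length(kern)
  x <- rnorm(m + 2 * pad)
  y <- stats::filter(x, kern, method = "convolution", sides = 2)
  coarse <- as.numeric(y[(pad + 1):(pad + m)])
  if (step == 1L) return(coarse[seq_len(len)])
  approx(x = (seq_len(m) - 1) * step, y = coarse,
         xout = seq_len(len) - 1)$y
}

#' Format numbers for exact-round-trip CSV output
#' @noRd
fmt_full <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%.0f", x), sprintf("%.17g", x))
}
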