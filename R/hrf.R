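#' Canonical double-gamma haemodynamic response function
#'
#' The canonical BOLD impulse response used throughout the package: a gamma
#' density peaking at `peak` seconds minus a second gamma density modelling the
#' post-stimulus undershoot at `undershoot` seconds, scaled by `1/ratio`. The
#' returned kernel is normalised to a peak height of 1 so that simulated and
#' fitted amplitudes stay on the scale of the neural boxcar.
#'
#' @param t Numeric vector of times (seconds) at which to evaluate the kernel.
#' @param peak Time-to-peak parameter (shape of the positive gamma), seconds.
#' @param undershoot Undershoot delay parameter, seconds.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return Numeric vector, `length(t)`, peak-normalised HRF values.
#' @examples
#' h <- hrf_double_gamma(seq(0, 30, by = 2))
#' which.max(h) # peak near 6 s
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  stopifnot(peak > 0, undershoot > 0, ratio > 0)
  h <- dgamma(t, shape = peak, rate = 1) - dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  # normalise on a fine grid so the peak height is 1 regardless of sampling
  tg <- seq(0, max(32, max(t)), by = 0.1)
  hg <- dgamma(tg, shape = peak, rate = 1) - dgamma(tg, shape = undershoot, rate = 1) / ratio
  h / max(hg)
}

# Convolve a TR-sampled neural time course with the canonical HRF (per run).
# x: numeric vector (one run); returns vector of the same length.
convolve_hrf <- function(x, tr, peak = 6, undershoot = 16, ratio = 6) {
  n <- length(x)
  kern <- hrf_double_gamma(seq(0, 32, by = tr), peak = peak, undershoot = undershoot, ratio = ratio)
  out <- stats::convolve(x, rev(kern), type = "open")[seq_len(n)]
  out
}

# Per-block HRF-convolved boxcar regressors for one run.
# Returns an n_tr x n_block matrix; block b's column is the convolved boxcar of
# that block alone. Condition regressors are sums of these columns.
block_regressor_matrix <- function(onset_tr, duration_tr, n_tr, tr, ...) {
  stopifnot(length(onset_tr) == length(duration_tr))
  X <- matrix(0, n_tr, length(onset_tr))
  for (b in seq_along(onset_tr)) {
    box <- numeric(n_tr)
    idx <- seq.int(onset_tr[b] + 1L, min(n_tr, onset_tr[b] + duration_tr[b]))
    box[idx] <- 1
    X[, b] <- convolve_hrf(box, tr, ...)
  }
  X
}
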