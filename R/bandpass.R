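#' Hard DFT bandpass of a set of time series
#'
#' Zeroes every discrete-Fourier frequency bin outside `[low_hz, high_hz]`,
#' including the DC bin, and inverse-transforms. The mean is therefore
#' removed (DC lies outside any positive passband).
#'
#' @param x Numeric matrix, time in rows (T x V), or a vector.
#' @param low_hz,high_hz Passband edges in Hz, `0 < low < high < 1/(2 tr)`.
#' @param tr Repetition time in seconds.
#' @return Filtered object of the same shape.
#' @export
bandpass_series <- function(x, low_hz, high_hz, tr) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  fail_if(!(low_hz > 0 && high_hz > low_hz), "passband must satisfy 0 < low < high")
  fail_if(high_hz > 1 / (2 * tr) + 1e-12,
          "passband upper edge %.4f Hz exceeds Nyquist %.4f Hz", high_hz, 1 / (2 * tr))
  freqs <- dft_frequencies(n, tr)
  keep <- freqs >= low_hz - 1e-12 & freqs <= high_hz + 1e-12
  fail_if(!any(keep), "no DFT bin falls inside [%g, %g] Hz at T=%d, TR=%g",
          low_hz, high_hz, n, tr)
  fx <- stats::mvfft(x)
  fx[!keep, ] <- 0
  out <- Re(stats::mvfft(fx, inverse = TRUE)) / n
  if (vec) out[, 1] else out
}

# |frequency| in Hz of each DFT bin for a length-n series.
dft_frequencies <- function(n, tr) {
  k <- 0:(n - 1)
  k <- pmin(k, n - k)
  k / (n * tr)
}

#' Bandpass-filter a 4D volume
#'
#' Applies [bandpass_series()] to every voxel time series.
#'
#' @param volume A [volume4d()].
#' @param low_hz,high_hz Passband edges in Hz.
#' @return A `volume4d` of the same geometry.
#' @export
bandpass_volume <- function(volume, low_hz, high_hz) {
  stopifnot(inherits(volume, "volume4d"))
  d <- dim(volume$data)
  y <- t(matrix(volume$data, prod(d[1:3]), d[4]))
  y <- bandpass_series(y, low_hz, high_hz, volume$tr)
  volume$data <- array(t(y), dim = d)
  volume
}
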