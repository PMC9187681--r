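#' Simulate a Gaussian random field on a grid
#'
#' Draws a zero-mean, unit-variance stationary Gaussian random field with
#' squared-exponential covariance `C(d) = exp(-(d / length_scale)^2)` by
#' circulant embedding on a doubled torus: the covariance of torus
#' distances is diagonalised by the 2-D FFT, the field is synthesised as
#' `IFFT(sqrt(eigenvalues) * FFT(white noise))`, and the top-left quarter
#' is returned. Exact for the embedded covariance (tiny negative
#' eigenvalues from truncation are clipped to zero); the doubling keeps
#' torus wrap-around negligible for length scales well below the domain
#' size.
#'
#' @param nrow,ncol Output field dimensions (cells).
#' @param length_scale Correlation length in cell units.
#' @return `nrow x ncol` matrix, marginally standard normal.
#' @examples
#' set.seed(1)
#' f <- sim_grf(50, 50, length_scale = 8)
#' @export
sim_grf <- function(nrow, ncol, length_scale) {
  stopifnot(nrow >= 1, ncol >= 1, length_scale > 0)
  m <- 2L * nrow; n <- 2L * ncol
  dy <- pmin(0:(m - 1), m - (0:(m - 1)))
  dx <- pmin(0:(n - 1), n - (0:(n - 1)))
  d2 <- outer(dy^2, dx^2, "+")
  C <- exp(-d2 / length_scale^2)
  ev <- Re(stats::fft(C))
  ev[ev < 0] <- 0
  eps <- matrix(stats::rnorm(m * n), m, n)
  Y <- stats::fft(sqrt(ev) * stats::fft(eps), inverse = TRUE) / (m * n)
  Re(Y)[seq_len(nrow), seq_len(ncol)]
}
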