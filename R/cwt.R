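## Complex-Morlet continuous wavelet transform and phase-lag estimation.

#' Complex Morlet wavelet transform at a single frequency
#'
#' Convolves a real signal with a complex Morlet wavelet
#' `psi(t) = pi^(-1/4) exp(i w0 t) exp(-t^2/2)` scaled so its peak
#' response is at `f0`.  Returns the complex coefficient series (same
#' length as the input; edges within one wavelet support are still
#' returned but should be excluded from phase averaging, see
#' [cwt_phase_lag()]).
#'
#' @param x numeric signal.
#' @param f0 analysis frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param omega0 Morlet centre-frequency parameter (default 6).
#' @return complex vector, `length(x)`.
#' @export
morlet_cwt <- function(x, f0, fs, omega0 = 6) {
  if (f0 <= 0 || fs <= 0 || f0 >= fs / 2)
    stop("need 0 < f0 < fs/2", call. = FALSE)
  a <- omega0 * fs / (2 * pi * f0)      # scale in samples
  half <- ceiling(4 * a)
  tk <- (-half):half
  psi <- pi^(-1 / 4) * exp(1i * omega0 * tk / a) * exp(-(tk / a)^2 / 2) /
    sqrt(a)
  nx <- length(x)
  L <- nx + length(psi) - 1L
  nfft <- 2^ceiling(log2(L))
  X <- stats::fft(c(x, rep(0, nfft - nx)))
  P <- stats::fft(c(Conj(rev(psi)), rep(0, nfft - length(psi))))
  w <- stats::fft(X * P, inverse = TRUE) / nfft
  ## full convolution with reversed conjugate kernel = correlation with psi;
  ## centre-aligned segment:
  w[(half + 1L):(half + nx)]
}

## wavelet half-support in samples at frequency f0
morlet_support <- function(f0, fs, omega0 = 6) {
  ceiling(4 * omega0 * fs / (2 * pi * f0))
}

#' Phase lag between two oscillatory signals at a task frequency
#'
#' Estimates the time shift of `signal` relative to `reference` from the
#' angular difference of their complex Morlet wavelet coefficients at
#' `f0`: per-sample phase differences are averaged circularly
#' (resultant-vector mean) over a window excluding one wavelet half-support
#' at each edge (cone of influence), and converted to seconds.  Positive
#' lag means `signal` lags (is behind) `reference`.  The estimate is
#' reported wrapped into `(-T/2, T/2]` for period `T = 1/f0`.
#'
#' @param signal,reference numeric series of equal length (at least
#'   `4 / f0` seconds).
#' @param f0 oscillation frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param omega0 Morlet centre-frequency parameter.
#' @return lag in seconds.
#' @examples
#' fs <- 60; t <- seq(0, 32 - 1 / fs, by = 1 / fs)
#' x <- sin(2 * pi * 0.5 * t)
#' y <- sin(2 * pi * 0.5 * (t - 0.5))          # y lags x by 500 ms
#' cwt_phase_lag(y, x, f0 = 0.5, fs = fs)
#' @export
cwt_phase_lag <- function(signal, reference, f0, fs, omega0 = 6) {
  if (length(signal) != length(reference))
    stop("'signal' and 'reference' must have equal length", call. = FALSE)
  if (length(signal) < 4 * fs / f0)
    stop("series too short: need at least 4/f0 seconds", call. = FALSE)
  ## remove the mean first: the Morlet wavelet is only approximately
  ## admissible, so a DC offset would otherwise leak into the phase
  ws <- morlet_cwt(signal - mean(signal), f0, fs, omega0)
  wr <- morlet_cwt(reference - mean(reference), f0, fs, omega0)
  half <- morlet_support(f0, fs, omega0)
  keep <- (half + 1L):(length(signal) - half)
  if (length(keep) < 2L)
    stop("series too short after edge exclusion", call. = FALSE)
  amp <- abs(ws[keep]) * abs(wr[keep])
  if (stats::median(abs(ws[keep])) < 1e-12 ||
      stats::median(abs(wr[keep])) < 1e-12)
    stop("undefined phase: wavelet amplitude is (near) zero", call. = FALSE)
  ## cross-coefficients: Arg gives phase(signal) - phase(reference);
  ## resultant-vector (circular) mean over the window
  cross <- ws[keep] * Conj(wr[keep])
  dphi <- Arg(sum(cross / Mod(cross)))
  lag <- -dphi / (2 * pi * f0)
  period <- 1 / f0
  lag <- lag - period * round(lag / period)
  if (lag <= -period / 2) lag <- lag + period
  lag
}
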