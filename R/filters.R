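# Zero-phase FFT-domain band-pass with raised-cosine transition bands.
# Transition width defaults to min(2 Hz, low/2) so that 1-Hz-wide sweep bands
# at low frequencies remain realizable; exactly zero-phase by construction.
fft_bandpass <- function(x, fs, low, high, transition = NULL) {
  n <- length(x)
  if (is.null(transition)) transition <- min(2, low / 2)
  f <- (seq_len(n) - 1) / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]
  mask <- raised_cosine_mask(f, low, high, transition)
  Re(fft(fft(x) * mask, inverse = TRUE)) / n
}

raised_cosine_mask <- function(f, low, high, transition) {
  mask <- numeric(length(f))
  inside <- f >= low & f <= high
  mask[inside] <- 1
  lo_t <- f >= low - transition & f < low
  mask[lo_t] <- 0.5 * (1 + cos(pi * (low - f[lo_t]) / transition))
  hi_t <- f > high & f <= high + transition
  mask[hi_t] <- 0.5 * (1 + cos(pi * (f[hi_t] - high) / transition))
  mask
}

#' Band specification
#'
#' @param low Lower band edge, Hz.
#' @param high Upper band edge, Hz.
#' @param label Optional label; defaults to `"low-high Hz"`.
#' @return A `band_spec` list.
#' @export
band_spec <- function(low, high, label = sprintf("%g-%g Hz", low, high)) {
  if (!(low > 0 && high > low)) rlang::abort("need 0 < low < high.")
  structure(list(low = low, high = high, label = label), class = "band_spec")
}

#' Extended alpha band (6-13 Hz)
#'
#' The default analysis band: alpha widened downward to 6 Hz because
#' oscillatory slowing in Alzheimer's disease can move the dominant rhythm
#' below the canonical 8 Hz edge.
#' @return A [band_spec()].
#' @export
alpha_band <- function() band_spec(6, 13, "alpha (6-13 Hz)")

#' Zero-phase band-pass filter
#'
#' FFT-domain masking with raised-cosine transition bands of width
#' `min(2 Hz, low/2)`: unity gain in the passband, zero phase at all
#' frequencies, > 60 dB attenuation beyond the transition. The first and last
#' second of the output contain filter edge transients; callers that window
#' the signal (DFA, fE/I) should drop them (see [alpha_envelope()]).
#'
#' @param x Numeric vector (single-channel signal).
#' @param band A [band_spec()].
#' @param fs Sampling rate, Hz.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, band, fs) {
  stopifnot(inherits(band, "band_spec"))
  if (band$high >= fs / 2) {
    rlang::abort("band upper edge must be below the Nyquist frequency.")
  }
  if (!all(is.finite(x))) rlang::abort("`x` must be finite.")
  fft_bandpass(x, fs, band$low, band$high)
}

#' Amplitude envelope via the analytic signal
#'
#' Magnitude of the Hilbert analytic signal, computed in the frequency domain.
#'
#' @param x Band-pass-filtered numeric vector.
#' @return Nonnegative envelope, same length as `x`.
#' @export
envelope <- function(x) {
  if (!all(is.finite(x))) rlang::abort("`x` must be finite.")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Band-pass, envelope, and edge trimming in one step
#'
#' Convenience wrapper used throughout the pipeline: filters `x` into `band`,
#' takes the analytic-signal envelope, and drops `trim_s` seconds at each end
#' to discard filter edge transients.
#'
#' @inheritParams bandpass
#' @param trim_s Seconds trimmed from each end (default 1).
#' @return Nonnegative envelope vector.
#' @export
band_envelope <- function(x, band, fs, trim_s = 1) {
  e <- envelope(bandpass(x, band, fs))
  k <- round(trim_s * fs)
  if (2 * k >= length(e)) rlang::abort("signal too short for edge trimming.")
  if (k > 0) e <- e[(k + 1):(length(e) - k)]
  e
}
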