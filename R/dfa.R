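# Vectorized per-window RMS of a linearly detrended profile. `y` is the
# cumulative signal profile; windows of `w` samples start every `step`
# samples. Returns one RMS per window.
window_rms_detrended <- function(y, w, step) {
  n <- length(y)
  starts <- seq.int(1L, n - w + 1L, by = step)
  idx <- outer(seq_len(w) - 1L, starts, `+`)
  M <- y[idx]
  dim(M) <- dim(idx)
  tc <- seq_len(w) - (w + 1) / 2
  mu <- .colMeans(M, w, ncol(M))
  slope <- as.vector(crossprod(tc, M)) / sum(tc^2)
  resid <- M - rep(mu, each = w) - outer(tc, slope)
  sqrt(.colMeans(resid^2, w, ncol(M)))
}

#' Detrended fluctuation analysis (DFA)
#'
#' Estimates the long-range temporal correlation (LRTC) exponent of a signal
#' (typically an oscillation amplitude envelope): the signal is demeaned and
#' cumulatively summed into a profile; for each of `n_windows` log-spaced
#' window sizes, the profile is cut into 50%-overlapping windows, linearly
#' detrended per window, and the mean per-window RMS gives the fluctuation
#' function F(t); the DFA exponent is the least-squares slope of
#' log10 F(t) vs log10 t over the window range. An exponent of 0.5 indicates
#' an uncorrelated signal; values above 0.5 indicate persistent correlations.
#'
#' @param x Numeric signal (an envelope from [band_envelope()], or any
#'   series).
#' @param fs Sampling rate, Hz.
#' @param window_range_s Smallest and largest window size in seconds
#'   (default `c(1, 20)`).
#' @param n_windows Number of log-spaced window sizes (default 15).
#' @param overlap_frac Fractional overlap between consecutive windows
#'   (default 0.5).
#' @param band Optional [band_spec()] recorded in the result for bookkeeping.
#' @param roi Optional ROI label recorded in the result.
#' @return A `dfa_result`: `exponent` (alpha), `window_sizes_s`,
#'   `fluctuations`, `fit_range_s`, `fit_r2`, `band`, `roi`.
#' @export
dfa <- function(x, fs, window_range_s = c(1, 20), n_windows = 15,
                overlap_frac = 0.5, band = NULL, roi = NA_character_) {
  check_positive_scalar(fs, "fs")
  n <- length(x)
  w_max <- round(window_range_s[2] * fs)
  if (n < 2 * w_max) {
    rlang::abort(sprintf(
      "signal too short for DFA: need >= %d samples (2 x the largest window), have %d.",
      2 * w_max, n))
  }
  sizes <- unique(round(10^seq(log10(window_range_s[1] * fs),
                               log10(window_range_s[2] * fs),
                               length.out = n_windows)))
  sizes <- sizes[sizes >= 8]
  y <- cumsum(x - mean(x))
  F_t <- vapply(sizes, function(w) {
    step <- max(1L, floor(w * (1 - overlap_frac)))
    mean(window_rms_detrended(y, w, step))
  }, numeric(1))
  t_s <- sizes / fs
  if (any(F_t <= .Machine$double.eps * n)) {
    rlang::warn("degenerate input: fluctuation function vanishes (constant signal?); DFA exponent undefined.",
                class = "eibalance_degenerate_dfa")
    expo <- NA_real_
    r2 <- NA_real_
  } else {
    fit <- lm(log10(F_t) ~ log10(t_s))
    expo <- unname(coef(fit)[2])
    r2 <- summary(fit)$r.squared
  }
  structure(
    list(exponent = expo, window_sizes_s = t_s, fluctuations = F_t,
         fit_range_s = window_range_s, fit_r2 = r2, band = band, roi = roi,
         n_samples = n, fs = fs),
    class = "dfa_result"
  )
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> alpha = %.3f (fit %g-%g s, R2 = %.4f)\n",
              x$exponent, x$fit_range_s[1], x$fit_range_s[2], x$fit_r2))
  invisible(x)
}

#' @describeIn dfa One row per window size (window_s, fluctuation).
#' @exportS3Method generics::tidy
tidy.dfa_result <- function(x, ...) {
  tibble::tibble(window_s = x$window_sizes_s, fluctuation = x$fluctuations)
}

#' @describeIn dfa One-row summary (exponent, fit_r2, n_samples).
#' @exportS3Method generics::glance
glance.dfa_result <- function(x, ...) {
  tibble::tibble(exponent = x$exponent, fit_r2 = x$fit_r2,
                 fit_min_s = x$fit_range_s[1], fit_max_s = x$fit_range_s[2],
                 n_samples = x$n_samples, roi = x$roi)
}

#' @describeIn dfa Log-log fluctuation plot with the fitted slope.
#' @param object A `dfa_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.dfa_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$window_s, y = .data$fluctuation)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Window size (s)", y = "Fluctuation F(t)",
                  title = sprintf("DFA exponent = %.3f", object$exponent))
}

#' Alpha-band envelope DFA of one channel
#'
#' Convenience wrapper: band-pass into `band` (default extended alpha,
#' 6-13 Hz), extract the amplitude envelope, trim 1 s edge transients, run
#' [dfa()].
#'
#' @inheritParams dfa
#' @param band A [band_spec()]; default [alpha_band()].
#' @return A `dfa_result`.
#' @export
band_dfa <- function(x, fs, band = alpha_band(), window_range_s = c(1, 20),
                     n_windows = 15, overlap_frac = 0.5, roi = NA_character_) {
  env <- band_envelope(x, band, fs)
  dfa(env, fs, window_range_s = window_range_s, n_windows = n_windows,
      overlap_frac = overlap_frac, band = band, roi = roi)
}

#' Broadband DFA sweep
#'
#' Repeats band-pass + envelope + DFA across contiguous `f_step`-wide bands
#' from `f_start` to `f_stop` (default 1-Hz bands over 1-44 Hz).
#'
#' @inheritParams dfa
#' @param f_start,f_stop,f_step Sweep grid in Hz.
#' @return A tibble with one row per band: `f_low`, `f_high`, `exponent`,
#'   `fit_r2`.
#' @export
dfa_sweep <- function(x, fs, f_start = 1, f_stop = 44, f_step = 1,
                      window_range_s = c(1, 20), n_windows = 15,
                      overlap_frac = 0.5) {
  lows <- seq(f_start, f_stop, by = f_step)
  purrr::map_dfr(lows, function(lo) {
    b <- band_spec(lo, lo + f_step)
    r <- band_dfa(x, fs, band = b, window_range_s = window_range_s,
                  n_windows = n_windows, overlap_frac = overlap_frac)
    tibble::tibble(f_low = lo, f_high = lo + f_step,
                   exponent = r$exponent, fit_r2 = r$fit_r2)
  })
}
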