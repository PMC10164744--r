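#' Functional excitation/inhibition ratio (fE/I)
#'
#' Computes the fE/I of an oscillation amplitude envelope. The envelope is cut
#' into non-overlapping windows of `window_s` seconds (trailing partial window
#' discarded). Per window w: the mean amplitude `A_w`; the window's demeaned
#' envelope divided by `A_w`, cumulatively summed into a profile, linearly
#' detrended, and its RMS taken as the amplitude-normalized fluctuation
#' `nF_w`. Then `fE/I = 1 - cor(A_w, nF_w)` (Pearson by default). Values ~1
#' indicate a balanced network, < 1 an inhibition-dominated and > 1 an
#' excitation-dominated regime.
#'
#' fE/I is only interpretable when the envelope carries long-range temporal
#' correlations: the result is gated on the channel's DFA exponent reaching
#' `threshold` (default 0.55; 0.6 is the conservative choice), below which
#' `valid = FALSE` and no fE/I value is emitted.
#'
#' @param env Amplitude envelope (from [band_envelope()]).
#' @param fs Sampling rate, Hz.
#' @param dfa_exponent The channel's DFA exponent used for validity gating.
#' @param window_s Window length in seconds (default 5).
#' @param threshold DFA validity threshold (default 0.55).
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`
#'   (for sensitivity analysis).
#' @param roi Optional ROI label carried through to outputs.
#' @return A `fei_result`: `fei` (NA when invalid), `window_amplitudes`,
#'   `normalized_fluctuations`, `correlation_r`, `dfa_exponent`, `valid`,
#'   `threshold_used`, `roi`.
#' @export
fei <- function(env, fs, dfa_exponent, window_s = 5, threshold = 0.55,
                method = c("pearson", "spearman"), roi = NA_character_) {
  method <- match.arg(method)
  check_positive_scalar(fs, "fs")
  w <- round(window_s * fs)
  n_win <- floor(length(env) / w)
  if (n_win < 2) {
    rlang::abort(sprintf(
      "envelope too short for fE/I: need >= 2 windows of %g s, have %.2f s.",
      window_s, length(env) / fs))
  }
  A <- numeric(n_win)
  nF <- numeric(n_win)
  drop <- logical(n_win)
  for (i in seq_len(n_win)) {
    seg <- env[((i - 1) * w + 1):(i * w)]
    A[i] <- mean(seg)
    if (A[i] <= 0) {
      drop[i] <- TRUE
      next
    }
    prof <- cumsum((seg - A[i]) / A[i])
    tc <- seq_len(w) - (w + 1) / 2
    prof <- prof - mean(prof) - tc * sum(tc * (prof - mean(prof))) / sum(tc^2)
    nF[i] <- sqrt(mean(prof^2))
  }
  if (any(drop)) {
    rlang::warn(sprintf("%d zero-amplitude window(s) dropped.", sum(drop)))
    A <- A[!drop]
    nF <- nF[!drop]
  }
  if (length(A) < 2) rlang::abort("fewer than 2 usable windows.")
  r <- cor(A, nF, method = method)
  valid <- is.finite(dfa_exponent) && dfa_exponent >= threshold
  structure(
    list(fei = if (valid) 1 - r else NA_real_,
         window_amplitudes = A, normalized_fluctuations = nF,
         correlation_r = r, dfa_exponent = dfa_exponent, valid = valid,
         threshold_used = threshold, window_s = window_s, roi = roi),
    class = "fei_result"
  )
}

#' @export
print.fei_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<fei_result> fE/I = %.3f (r = %.3f, %d windows, DFA %.3f >= %.2f)\n",
                x$fei, x$correlation_r, length(x$window_amplitudes),
                x$dfa_exponent, x$threshold_used))
  } else {
    cat(sprintf("<fei_result> invalid (DFA %.3f < threshold %.2f)\n",
                x$dfa_exponent, x$threshold_used))
  }
  invisible(x)
}

#' @describeIn fei One row per window (amplitude, normalized fluctuation).
#' @exportS3Method generics::tidy
tidy.fei_result <- function(x, ...) {
  tibble::tibble(window = seq_along(x$window_amplitudes),
                 amplitude = x$window_amplitudes,
                 normalized_fluctuation = x$normalized_fluctuations)
}

#' @describeIn fei One-row summary.
#' @exportS3Method generics::glance
glance.fei_result <- function(x, ...) {
  tibble::tibble(fei = x$fei, correlation_r = x$correlation_r,
                 dfa_exponent = x$dfa_exponent, valid = x$valid,
                 threshold = x$threshold_used,
                 n_windows = length(x$window_amplitudes), roi = x$roi)
}

#' @describeIn fei Amplitude vs normalized-fluctuation scatter.
#' @param object A `fei_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.fei_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$amplitude,
                                 y = .data$normalized_fluctuation)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = expression(A[w]), y = expression(nF[w]),
                  title = if (object$valid)
                    sprintf("fE/I = %.3f", object$fei) else "fE/I not valid")
}

#' Region-level fE/I with exclusion accounting
#'
#' Averages fE/I over a region's member ROIs, using only ROIs whose DFA
#' exponent reached the validity threshold. A region with zero valid ROIs
#' yields `NA` — a legal outcome recorded, not an error.
#'
#' @param results Named list of per-ROI `fei_result`s (names are ROI labels).
#' @param region A [region_set()].
#' @param subject_id Carried into the exclusion report.
#' @return A list with `fei` (region mean over valid ROIs, or `NA`) and
#'   `exclusions` — a one-row tibble (`region`, `subject_id`, `n_rois_total`,
#'   `n_rois_excluded`).
#' @export
fei_region <- function(results, region, subject_id = NA_character_) {
  stopifnot(inherits(region, "region_set"))
  missing <- setdiff(region$members, names(results))
  if (length(missing) > 0) {
    rlang::abort(paste("fE/I not attempted for region ROIs:",
                       paste(missing, collapse = ", ")))
  }
  vals <- vapply(results[region$members], function(r) r$fei, numeric(1))
  valid <- vapply(results[region$members], function(r) r$valid, logical(1))
  n_total <- length(region$members)
  list(
    fei = if (any(valid)) mean(vals[valid]) else NA_real_,
    exclusions = tibble::tibble(
      region = region$name, subject_id = subject_id,
      n_rois_total = n_total,
      n_rois_excluded = sum(!valid)
    )
  )
}

#' fE/I threshold sensitivity analysis
#'
#' Recomputes region fE/I at two DFA validity thresholds (default 0.55 and
#' the conservative 0.60) from the same per-ROI inputs, verifying that the
#' exclusion count is non-decreasing in the threshold.
#'
#' @param envelopes Named list of per-ROI amplitude envelopes.
#' @param dfa_exponents Named numeric vector of per-ROI DFA exponents.
#' @param fs Sampling rate, Hz.
#' @param region A [region_set()].
#' @param thresholds Two thresholds (default `c(0.55, 0.60)`).
#' @param subject_id Carried into reports.
#' @param window_s fE/I window length, seconds.
#' @return A tibble with one row per threshold: `threshold`, `fei`,
#'   `n_rois_excluded`, `n_rois_total`.
#' @export
fei_threshold_sensitivity <- function(envelopes, dfa_exponents, fs, region,
                                      thresholds = c(0.55, 0.60),
                                      subject_id = NA_character_,
                                      window_s = 5) {
  out <- purrr::map_dfr(sort(thresholds), function(th) {
    res <- lapply(region$members, function(lbl) {
      fei(envelopes[[lbl]], fs, dfa_exponent = dfa_exponents[[lbl]],
          window_s = window_s, threshold = th, roi = lbl)
    })
    names(res) <- region$members
    rr <- fei_region(res, region, subject_id = subject_id)
    tibble::tibble(threshold = th, fei = rr$fei,
                   n_rois_excluded = rr$exclusions$n_rois_excluded,
                   n_rois_total = rr$exclusions$n_rois_total)
  })
  stopifnot(!is.unsorted(out$n_rois_excluded))
  out
}
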