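#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Fits, in log10-power vs log10-frequency coordinates over `f_range`
#' (default the gamma range, 30-48 Hz): (1) a robust initial line excluding
#' high-residual (peak) bins; (2) up to `max_peaks` Gaussian peaks extracted
#' from the residual, largest first, stopping below `min_peak_height`; (3) a
#' refit of the line on the peak-subtracted spectrum. The aperiodic exponent
#' chi is the negative slope of the final line (fixed mode — no knee, which
#' is unidentifiable over so narrow a range). R-squared is computed between
#' the full model (line + peaks) and the observed log10 power; fits with
#' R-squared below `r2_min` are flagged `accepted = FALSE` and excluded
#' downstream.
#'
#' @param spec A `power_spectrum` (single column, e.g. from
#'   [region_average()]; for multi-ROI spectra the first column is used with a
#'   warning).
#' @param f_range Fit range in Hz (default `c(30, 48)`).
#' @param max_peaks Maximum number of Gaussian peaks (default 2).
#' @param min_peak_height Minimum peak height in log10-power units
#'   (default 0.05).
#' @param peak_width_limits Gaussian SD limits in Hz (default `c(0.5, 3.4)`,
#'   i.e. ~1-8 Hz full width).
#' @param r2_min Acceptance threshold on R-squared (default 0.8).
#' @return An `aperiodic_fit`: `offset`, `exponent` (chi), `peaks` (tibble:
#'   center_hz, height, sd_hz), `r2`, `fit_range`, `accepted`.
#' @export
fit_aperiodic <- function(spec, f_range = c(30, 48), max_peaks = 2,
                          min_peak_height = 0.05,
                          peak_width_limits = c(0.5, 3.4), r2_min = 0.8) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (ncol(spec$power) > 1) {
    rlang::warn("multi-ROI spectrum passed to fit_aperiodic(); using the first column.")
  }
  keep <- spec$freqs >= f_range[1] & spec$freqs <= f_range[2]
  f <- spec$freqs[keep]
  p <- spec$power[keep, 1]
  if (length(f) < 8) rlang::abort("spectrum does not cover the fit range.")
  if (any(p <= 0)) rlang::abort("non-positive power in the fit range.")
  lf <- log10(f)
  lp <- log10(p)

  # (1) robust initial line: OLS, then refit excluding bins whose positive
  # residual exceeds 2.5 x the MAD (peak bins), twice.
  # peaks only ever push residuals upward, so mask bins above the upper
  # Tukey fence of the residuals; a peakless spectrum is left untouched
  cf <- coef(lm(lp ~ lf))
  for (i in 1:2) {
    res <- lp - (cf[1] + cf[2] * lf)
    qs <- quantile(res, c(0.25, 0.75), names = FALSE)
    mask <- res <= qs[2] + 1.5 * (qs[2] - qs[1])
    if (sum(mask) >= 4) cf <- coef(lm(lp[mask] ~ lf[mask]))
  }
  aper <- unname(cf[1] + cf[2] * lf)

  # (2) iterative Gaussian peak extraction from the residual.
  resid <- lp - aper
  peaks <- list()
  for (k in seq_len(max_peaks)) {
    i0 <- which.max(resid)
    h0 <- resid[i0]
    # absolute floor plus a relative floor of 2 x the SD of the flattened
    # spectrum, so smooth correlated noise is not chased as a peak
    if (h0 < max(min_peak_height, 2 * sd(resid))) break
    par0 <- c(c = f[i0], h = h0, s = mean(peak_width_limits))
    obj <- function(par) {
      g <- par[2] * exp(-(f - par[1])^2 / (2 * par[3]^2))
      sum((resid - g)^2)
    }
    opt <- optim(par0, obj, method = "L-BFGS-B",
                 lower = c(f_range[1], min_peak_height / 2, peak_width_limits[1]),
                 upper = c(f_range[2], 2 * max(h0, min_peak_height), peak_width_limits[2]))
    g <- opt$par[2] * exp(-(f - opt$par[1])^2 / (2 * opt$par[3]^2))
    resid <- resid - g
    peaks[[k]] <- tibble::tibble(center_hz = opt$par[1], height = opt$par[2],
                                 sd_hz = opt$par[3])
  }
  peak_tbl <- if (length(peaks)) dplyr::bind_rows(peaks) else
    tibble::tibble(center_hz = numeric(0), height = numeric(0), sd_hz = numeric(0))

  # (3) refit the line on the peak-subtracted spectrum.
  peak_model <- lp - resid - aper     # summed Gaussians on the grid
  fit2 <- lm(I(lp - peak_model) ~ lf)
  offset <- unname(coef(fit2)[1])
  slope <- unname(coef(fit2)[2])

  # (4) joint refinement: line and all Gaussians optimized together, which
  # corrects the greedy pass's tendency to fold wide or edge peaks into the
  # line. Bounded; skipped when no peaks were found (the line fit is exact).
  K <- nrow(peak_tbl)
  if (K > 0) {
    par0 <- c(offset, slope,
              as.vector(t(as.matrix(peak_tbl))))
    model_fun <- function(par) {
      m <- par[1] + par[2] * lf
      for (k in seq_len(K)) {
        ctr <- par[3 * k]; h <- par[3 * k + 1]; sdv <- par[3 * k + 2]
        m <- m + h * exp(-(f - ctr)^2 / (2 * sdv^2))
      }
      m
    }
    lower <- c(-Inf, -10, rep(c(f_range[1], 0, peak_width_limits[1]), K))
    upper <- c(Inf, 10, rep(c(f_range[2], Inf, peak_width_limits[2]), K))
    opt <- optim(par0, function(par) sum((lp - model_fun(par))^2),
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 200))
    offset <- opt$par[1]
    slope <- opt$par[2]
    peak_tbl <- tibble::tibble(
      center_hz = opt$par[3 * seq_len(K)],
      height = opt$par[3 * seq_len(K) + 1],
      sd_hz = opt$par[3 * seq_len(K) + 2]
    )
    # drop vanishing peaks and peaks hugging a range edge (a half-Gaussian
    # over so short a range is degenerate with the aperiodic line)
    peak_tbl <- peak_tbl[peak_tbl$height >= min_peak_height / 2 &
                           peak_tbl$center_hz - peak_tbl$sd_hz > f_range[1] &
                           peak_tbl$center_hz + peak_tbl$sd_hz < f_range[2],
                         , drop = FALSE]
    peak_model <- rep(0, length(f))
    for (k in seq_len(nrow(peak_tbl))) {
      peak_model <- peak_model + peak_tbl$height[k] *
        exp(-(f - peak_tbl$center_hz[k])^2 / (2 * peak_tbl$sd_hz[k]^2))
    }
    fit3 <- lm(I(lp - peak_model) ~ lf)
    offset <- unname(coef(fit3)[1])
    slope <- unname(coef(fit3)[2])
  }
  model <- offset + slope * lf + peak_model
  r2 <- 1 - sum((lp - model)^2) / sum((lp - mean(lp))^2)

  structure(
    list(offset = offset, exponent = -slope, peaks = peak_tbl, r2 = r2,
         fit_range = f_range, accepted = is.finite(r2) && r2 >= r2_min,
         freqs = f, log_power = lp, model = model),
    class = "aperiodic_fit"
  )
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> chi = %.3f, offset = %.3f, %d peak(s), R2 = %.4f%s\n",
              x$exponent, x$offset, nrow(x$peaks), x$r2,
              if (x$accepted) "" else " [rejected]"))
  invisible(x)
}

#' @describeIn fit_aperiodic One row per fitted peak.
#' @param x An `aperiodic_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.aperiodic_fit <- function(x, ...) x$peaks

#' @describeIn fit_aperiodic One-row fit summary.
#' @exportS3Method generics::glance
glance.aperiodic_fit <- function(x, ...) {
  tibble::tibble(offset = x$offset, exponent = x$exponent,
                 n_peaks = nrow(x$peaks), r2 = x$r2, accepted = x$accepted,
                 f_low = x$fit_range[1], f_high = x$fit_range[2])
}

#' @describeIn fit_aperiodic Observed vs modelled log-power.
#' @param object An `aperiodic_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.aperiodic_fit <- function(object, ...) {
  d <- tibble::tibble(freq_hz = object$freqs, observed = object$log_power,
                      model = object$model)
  tidyr::pivot_longer(d, -"freq_hz") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$freq_hz, y = .data$value,
                                 colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "log10 power", colour = NULL,
                  title = sprintf("Aperiodic exponent = %.3f (R2 = %.3f)",
                                  object$exponent, object$r2))
}

#' Region-level aperiodic exponent
#'
#' Fits the region-average spectrum (not a mean of per-ROI exponents). A
#' rejected fit (R-squared below threshold) yields `NA` with the rejection
#' recorded — a legal outcome, not an error.
#'
#' @param spec A per-ROI `power_spectrum`.
#' @param region A [region_set()].
#' @param ... Passed to [fit_aperiodic()].
#' @return A one-row tibble: `region`, `offset`, `exponent` (NA if rejected),
#'   `r2`, `accepted`, `n_peaks`.
#' @export
aperiodic_region <- function(spec, region, ...) {
  fit <- fit_aperiodic(region_average(spec, region), ...)
  tibble::tibble(
    region = region$name, offset = fit$offset,
    exponent = if (fit$accepted) fit$exponent else NA_real_,
    r2 = fit$r2, accepted = fit$accepted, n_peaks = nrow(fit$peaks)
  )
}
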