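# Independent oracles used to cross-check the package's estimators. These
# deliberately share no code with the implementations they test.

# Plain loop-and-lm DFA (50% window overlap, like the implementation, but
# sharing none of its vectorized code path).
naive_dfa <- function(x, fs, window_range_s = c(1, 20), n_windows = 15) {
  y <- cumsum(x - mean(x))
  n <- length(y)
  sizes <- unique(round(10^seq(log10(window_range_s[1] * fs),
                               log10(window_range_s[2] * fs),
                               length.out = n_windows)))
  sizes <- sizes[sizes >= 8]
  Fv <- vapply(sizes, function(w) {
    starts <- seq(1, n - w + 1, by = max(1, floor(w / 2)))
    mean(vapply(starts, function(i) {
      seg <- y[i:(i + w - 1)]
      tt <- seq_len(w)
      sqrt(mean(stats::residuals(stats::lm(seg ~ tt))^2))
    }, numeric(1)))
  }, numeric(1))
  unname(stats::coef(stats::lm(log10(Fv) ~ log10(sizes / fs)))[2])
}

# Robust aperiodic-exponent fit, independent of the package's algorithm:
# drop the bins with the largest positive OLS residuals (oscillatory peaks
# only ever push power upward), then take the Theil-Sen median of pairwise
# slopes over the remaining bins.
oracle_aperiodic <- function(freqs, power) {
  lf <- log10(freqs)
  lp <- log10(power)
  theil_sen <- function(x, y) {
    ij <- utils::combn(length(x), 2)
    stats::median((y[ij[2, ]] - y[ij[1, ]]) / (x[ij[2, ]] - x[ij[1, ]]))
  }
  # iterate: fit on kept bins, re-rank all bins by residual, keep the lower
  # half; peak bins (always positive residuals) drop out within a few rounds
  keep <- seq_along(lf)
  slope <- NA_real_
  for (i in 1:5) {
    slope <- theil_sen(lf[keep], lp[keep])
    icpt <- stats::median(lp[keep] - slope * lf[keep])
    res <- lp - icpt - slope * lf
    keep <- which(res <= stats::quantile(res, 0.45))
  }
  -slope
}

# Two-stage step-up FDR, hand-coded from the published definition:
# stage 1 = linear step-up at q/(1+q); stage 2 = linear step-up at
# (q/(1+q)) * m / m0 with m0 = m - r1.
bky_reference <- function(p, q) {
  m <- length(p)
  step_up <- function(p, level) {
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= (seq_len(m) / m) * level)
    rej <- rep(FALSE, m)
    if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  r1 <- sum(step_up(p, q1))
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  step_up(p, q1 * m / (m - r1))
}

# Exact (no-ties) Kruskal-Wallis H from the rank-sum definition.
oracle_kw_h <- function(groups) {
  values <- unlist(groups)
  r <- rank(values)
  n <- length(values)
  idx <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  rbar <- tapply(r, idx, mean)
  ni <- tabulate(idx)
  12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
}

# Synthetic power_spectrum object on a regular grid (for fit tests).
make_spectrum <- function(freqs, power) {
  structure(list(freqs = freqs, power = matrix(power, ncol = 1),
                 fs = NA_real_, n_fft = NA_integer_, smoothed = FALSE,
                 roi_labels = "syn"),
            class = "power_spectrum")
}

# Random peaked/noisy spectrum on the 30-48 Hz grid with known exponent.
random_gamma_spectrum <- function(seed) {
  withr::with_seed(seed, {
    freqs <- seq(30, 48, by = 0.0762939453125)
    chi <- runif(1, 0.5, 2.5)
    offset <- runif(1, -1, 1)
    lp <- offset - chi * log10(freqs)
    n_peaks <- sample(0:2, 1)
    if (n_peaks > 0) {
      for (i in seq_len(n_peaks)) {
        ctr <- runif(1, 33, 45)
        h <- runif(1, 0.1, 0.3)
        sdv <- runif(1, 0.5, 1.2)
        lp <- lp + h * exp(-(freqs - ctr)^2 / (2 * sdv^2))
      }
    }
    lp <- lp + rnorm(length(freqs), sd = 0.02)
    list(spec = make_spectrum(freqs, 10^lp), chi = chi, n_peaks = n_peaks)
  })
}
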