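test_that("band-pass preserves the passband, rejects the stopband, and is near-idempotent", {
  fs <- 312.5
  t <- (seq_len(100 * fs) - 1) / fs
  band <- alpha_band()
  in_band <- sin(2 * pi * 10 * t)
  out_band <- sin(2 * pi * 2 * t)
  mid <- seq(round(5 * fs), round(95 * fs))

  y_in <- bandpass(in_band, band, fs)
  expect_lt(abs(max(y_in[mid]) - 1), 0.01)

  y_out <- bandpass(out_band, band, fs)
  expect_lt(20 * log10(sd(y_out[mid]) / sd(out_band)), -30)

  y_twice <- bandpass(y_in, band, fs)
  expect_lt(sqrt(mean((y_twice[mid] - y_in[mid])^2)) / sd(y_in[mid]), 0.01)

  expect_error(bandpass(in_band, band_spec(150, 200), fs), "Nyquist")
})

test_that("the analytic-signal envelope recovers amplitude modulation", {
  fs <- 312.5
  t <- (seq_len(60 * fs) - 1) / fs
  mid <- seq(round(2 * fs), round(58 * fs))

  x <- 2.5 * sin(2 * pi * 10 * t)
  env <- envelope(x)
  expect_lt(max(abs(env[mid] - 2.5) / 2.5), 0.01)
  expect_equal(envelope(-x), envelope(x), tolerance = 1e-12)

  m <- 1 + 0.5 * sin(2 * pi * 0.3 * t)
  env_am <- envelope(m * sin(2 * pi * 10 * t))
  expect_lt(sqrt(mean((env_am[mid] - m[mid])^2)) / mean(m), 0.02)
})

test_that("DFA recovers the exponent of uncorrelated and long-memory signals", {
  # i.i.d. Gaussian noise: alpha = 0.5 +/- 0.03 over 20 realizations
  est <- mean(sapply(1:20, function(s) {
    dfa(withr::with_seed(s, rnorm(1e5)), fs = 250)$exponent
  }))
  expect_lt(abs(est - 0.5), 0.03)

  # fGn-derived envelope with Hurst 0.85
  est85 <- mean(sapply(1:5, function(s) {
    dfa(gen_fgn_envelope(1e5, 0.85, seed = s), fs = 250)$exponent
  }))
  expect_lt(abs(est85 - 0.85), 0.05)
})

test_that("DFA is invariant to positive scaling and offsets, and flags degenerate input", {
  env <- gen_fgn_envelope(3e4, 0.7, seed = 9)
  a <- dfa(env, 250, window_range_s = c(0.5, 10))$exponent
  b <- dfa(37.1 * env + 5, 250, window_range_s = c(0.5, 10))$exponent
  expect_equal(a, b, tolerance = 1e-10)

  expect_warning(d <- dfa(rep(2, 3e4), 250, window_range_s = c(0.5, 10)),
                 class = "eibalance_degenerate_dfa")
  expect_true(is.na(d$exponent))

  expect_error(dfa(rnorm(100), 250), "too short")
})

test_that("DFA agrees with an independent naive implementation", {
  diffs <- sapply(1:10, function(s) {
    x <- gen_fgn_envelope(3e4, runif(1, 0.55, 0.9), seed = s)
    dfa(x, 250, window_range_s = c(1, 10))$exponent -
      naive_dfa(x, 250, window_range_s = c(1, 10))
  })
  expect_lt(max(abs(diffs)), 0.02)
})

test_that("estimated exponents increase monotonically with the generated Hurst", {
  hs <- seq(0.55, 0.95, by = 0.1)
  grid <- expand.grid(h = hs, s = 1:3)
  est <- mapply(function(h, s) dfa(gen_fgn_envelope(5e4, h, seed = s), 250)$exponent,
                grid$h, grid$s)
  means <- tapply(est, grid$h, mean)
  expect_gt(cor(means, hs, method = "spearman"), 0.95)
})

test_that("the broadband sweep localizes LRTC to the bands containing the oscillation", {
  # a near-pure 10.5 Hz tone amplitude-modulated by a slow (< 1 Hz) LRTC
  # envelope: its long-range structure lives only in bands containing the tone
  fs <- 312.5
  n <- 120 * fs
  t <- (seq_len(n) - 1) / fs
  env <- gen_fgn_envelope(n, 0.85, seed = 2)
  slow <- eibalance:::fft_bandpass(env - mean(env), fs, low = 0, high = 1,
                                   transition = 0.5) + mean(env)
  x <- pmax(slow, 0.05) * sin(2 * pi * 10.5 * t) +
    withr::with_seed(3, rnorm(n, sd = 0.1))
  sw <- dfa_sweep(x, fs, f_start = 2, f_stop = 18, f_step = 2,
                  window_range_s = c(1, 10))
  expect_equal(nrow(sw), 9)
  # the modulated tone occupies ~9.5-11.5 Hz, i.e. the [8,10) and [10,12) bands
  expect_true(sw$f_low[which.max(sw$exponent)] %in% c(8, 10))
  expect_gt(max(sw$exponent), sw$exponent[sw$f_low == 4] + 0.1)
})
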