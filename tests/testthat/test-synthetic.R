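test_that("aperiodic background recovers its spectral slope and the white-noise limit", {
  fs <- 312.5
  n <- 2^15
  # chi = 0 is spectrally flat
  x0 <- gen_aperiodic_background(n, fs, exponent = 0, power = 1, seed = 1)
  per <- function(x) Mod(fft(x))^2 / length(x)
  f <- (seq_len(n) - 1) / n * fs
  sel <- f >= 5 & f <= 40
  slope_of <- function(chi) {
    pm <- rowMeans(sapply(1:10, function(s) {
      per(gen_aperiodic_background(n, fs, exponent = chi, power = 1, seed = s))[sel]
    }))
    unname(coef(lm(log10(pm) ~ log10(f[sel])))[2])
  }
  expect_lt(abs(slope_of(0)), 0.1)
  for (chi in c(0.5, 1, 1.5, 2)) {
    expect_lt(abs(slope_of(chi) + chi), 0.15)
  }
})

test_that("aperiodic background is deterministic in its seed and validates inputs", {
  a <- gen_aperiodic_background(4096, 250, 1.5, 1, seed = 7)
  b <- gen_aperiodic_background(4096, 250, 1.5, 1, seed = 7)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, gen_aperiodic_background(4096, 250, 1.5, 1, seed = 8))))
  expect_lt(abs(mean(a)), 1e-10)
  expect_equal(sd(a), 1, tolerance = 1e-12)
  expect_error(gen_aperiodic_background(1, 250), "n_samples")
  expect_error(gen_aperiodic_background(100, -5), "fs")
  expect_error(gen_aperiodic_background(100, 250, exponent = -1), "exponent")
})

test_that("fGn envelope is positive, deterministic, and tracks its Hurst exponent", {
  e <- gen_fgn_envelope(5e4, 0.7, seed = 3)
  expect_gt(min(e), 0)
  expect_identical(e, gen_fgn_envelope(5e4, 0.7, seed = 3))
  expect_error(gen_fgn_envelope(1000, 1.2), "hurst")
  expect_error(gen_fgn_envelope(1000, 0), "hurst")
  for (h in c(0.6, 0.85)) {
    est <- mean(sapply(1:5, function(s) {
      dfa(gen_fgn_envelope(1e5, h, seed = s), fs = 250)$exponent
    }))
    expect_lt(abs(est - h), 0.05)
  }
})

test_that("single-ROI generation realizes the requested regimes", {
  # no oscillation: signal is background + noise, alpha envelope has no LRTC
  sp0 <- signal_spec(duration_s = 120, fs = 312.5, osc_power = 0, seed = 5)
  ts0 <- gen_roi_signal(sp0)
  d0 <- band_dfa(ts0$data[, 1], 312.5)
  expect_gt(d0$exponent, 0.45)
  expect_lt(d0$exponent, 0.62)

  # oscillation present: LRTC clearly recovered above the no-LRTC level
  sp1 <- signal_spec(duration_s = 120, fs = 312.5, envelope_hurst = 0.85, seed = 5)
  d1 <- band_dfa(gen_roi_signal(sp1)$data[, 1], 312.5)
  expect_gt(d1$exponent, d0$exponent + 0.05)

  # determinism and ground-truth metadata
  expect_identical(gen_roi_signal(sp1)$data, gen_roi_signal(sp1)$data)
  expect_equal(gen_roi_signal(sp1)$params$envelope_hurst, 0.85)

  expect_error(signal_spec(osc_center = 700, fs = 1250), "Nyquist")
})

test_that("healthy preset recovers DFA and aperiodic exponent in the expected bands", {
  p <- cohort_presets(duration_s = 140)
  vals <- sapply(1:4, function(s) {
    sp <- p$HE
    sp$seed <- s
    ts <- gen_roi_signal(sp)
    d <- band_dfa(ts$data[, 1], ts$fs)
    ps <- smooth_spectrum(power_spectrum(epoch(decimate_by_4(ts))), 20)
    c(dfa = d$exponent, chi = fit_aperiodic(ps)$exponent)
  })
  expect_gt(mean(vals["dfa", ]), 0.62)
  expect_lt(mean(vals["dfa", ]), 0.85)
  expect_gt(mean(vals["chi", ]), 1.2)
  expect_lt(mean(vals["chi", ]), 2.0)
})

test_that("cohort generation is deterministic with reproducible per-subject streams", {
  spec <- demo_cohort_spec(n_per_group = 2, master_seed = 11, duration_s = 8)
  a <- gen_cohort(spec)
  b <- gen_cohort(spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$signals[[1]]$data, b$signals[[1]]$data)
  expect_equal(nrow(a$subjects), 4)

  spec2 <- demo_cohort_spec(n_per_group = 2, master_seed = 12, duration_s = 8)
  c2 <- gen_cohort(spec2)
  expect_false(identical(a$signals[[1]]$data, c2$signals[[1]]$data))

  expect_error(cohort_spec(groups = list()), "non-empty")
})

test_that("zero jitter and zero score noise give identical within-group scores", {
  tmpl <- signal_spec(duration_s = 8, fs = 250, seed = 1)
  spec <- cohort_spec(
    groups = list(list(label = "G", n_subjects = 3, template = tmpl)),
    rois = "r1",
    score_model = list(baseline = 5, slope_hurst = 10, slope_exponent = 2,
                       noise_sd = 0),
    master_seed = 3
  )
  co <- gen_cohort(spec)
  expect_equal(length(unique(co$subjects$cognitive_score)), 1L)
  # but different subjects still get different signals
  expect_false(identical(co$signals[[1]]$data, co$signals[[2]]$data))
})
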