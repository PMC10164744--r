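#' Specification of a single synthetic ROI signal
#'
#' Bundles the generative parameters for one region's signal: a band-limited
#' oscillation whose amplitude envelope carries long-range temporal
#' correlations (LRTC) of known strength, an aperiodic 1/f^chi background, and
#' additive white sensor noise. The three `*_power` fields are variances in
#' arbitrary source-amplitude units squared.
#'
#' `fei_coupling` sets the relationship between the local oscillation
#' amplitude and the relative size of envelope fluctuations within it, which
#' is what the functional E/I ratio (fE/I) measures: positive values compress
#' the carrier's fluctuations in high-amplitude epochs (relatively quieter
#' when loud), pushing fE/I upward toward and beyond 1 (excitation-
#' dominated); negative values expand them, pulling fE/I down
#' (inhibition-dominated); 0 leaves the carrier untouched.
#'
#' @param duration_s Signal duration in seconds.
#' @param fs Sampling rate in Hz (default 1250, a common MEG rate).
#' @param osc_center Oscillation center frequency, Hz.
#' @param osc_bandwidth Full bandwidth of the oscillation, Hz.
#' @param envelope_hurst Hurst exponent of the envelope's fractional Gaussian
#'   noise source, in (0, 1); the DFA exponent of the envelope approximates it.
#' @param osc_power Variance of the oscillatory component.
#' @param aperiodic_exponent Spectral exponent chi >= 0 of the 1/f^chi
#'   background.
#' @param aperiodic_power Variance of the aperiodic background.
#' @param white_noise_power Variance of the additive white sensor noise.
#' @param fei_coupling Amplitude-fluctuation coupling (dimensionless, see
#'   Details); default 0.
#' @param env_contrast Contrast exponent applied to the normalized envelope in
#'   [gen_roi_signal()] (a smooth monotone power map; default 3). Raises the
#'   envelope's coefficient of variation so the LRTC modulation dominates the
#'   carrier's own Rayleigh fluctuations, as real alpha envelopes do.
#' @param seed Integer seed; the same spec generates bit-identical signals.
#'
#' @return A `signal_spec` object (a validated named list).
#' @export
signal_spec <- function(duration_s = 300, fs = 1250, osc_center = 10,
                        osc_bandwidth = 4, envelope_hurst = 0.75,
                        osc_power = 1, aperiodic_exponent = 1.5,
                        aperiodic_power = 0.3, white_noise_power = 0.001,
                        fei_coupling = 0, env_contrast = 3, seed = 1L) {
  check_positive_scalar(duration_s, "duration_s")
  check_positive_scalar(fs, "fs")
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-8) {
    rlang::abort("`duration_s * fs` must be a positive integer number of samples.")
  }
  if (envelope_hurst <= 0 || envelope_hurst >= 1) {
    rlang::abort("`envelope_hurst` must lie strictly in (0, 1).")
  }
  if (osc_power < 0 || aperiodic_power < 0 || white_noise_power < 0) {
    rlang::abort("power terms must be >= 0.")
  }
  if (aperiodic_exponent < 0) rlang::abort("`aperiodic_exponent` must be >= 0.")
  if (osc_center + osc_bandwidth / 2 >= fs / 2) {
    rlang::abort("oscillation band exceeds the Nyquist frequency.")
  }
  structure(
    list(duration_s = duration_s, fs = fs, osc_center = osc_center,
         osc_bandwidth = osc_bandwidth, envelope_hurst = envelope_hurst,
         osc_power = osc_power, aperiodic_exponent = aperiodic_exponent,
         aperiodic_power = aperiodic_power,
         white_noise_power = white_noise_power,
         fei_coupling = fei_coupling, env_contrast = env_contrast,
         seed = as.integer(seed)),
    class = "signal_spec"
  )
}

#' Generate an aperiodic 1/f^chi background signal
#'
#' Shapes white Gaussian noise in the frequency domain by an f^(-exponent/2)
#' amplitude profile (DC bin zeroed), inverse-transforms, and rescales to the
#' requested variance. The expected power spectral density is proportional to
#' 1/f^exponent across (0, fs/2).
#'
#' @param n_samples Number of samples (>= 2).
#' @param fs Sampling rate, Hz.
#' @param exponent Spectral exponent chi >= 0; 0 gives white noise.
#' @param power Target variance of the output.
#' @param seed Integer seed.
#' @return Zero-mean numeric vector of length `n_samples`.
#' @export
gen_aperiodic_background <- function(n_samples, fs, exponent = 1.5, power = 1,
                                     seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 2) {
    rlang::abort("`n_samples` must be >= 2.")
  }
  check_positive_scalar(fs, "fs")
  if (exponent < 0) rlang::abort("`exponent` must be >= 0.")
  if (power < 0) rlang::abort("`power` must be >= 0.")
  n <- as.integer(n_samples)
  if (power == 0) return(numeric(n))
  x <- withr::with_seed(seed, rnorm(n))
  f <- (seq_len(n) - 1) / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]  # two-sided frequency magnitude
  scale <- c(0, f[-1]^(-exponent / 2)) # zero the DC bin
  y <- Re(fft(fft(x) * scale, inverse = TRUE)) / n
  y <- y - mean(y)
  y * sqrt(power) / sd(y)
}

# Exact fractional Gaussian noise by circulant embedding (Davies-Harte).
# Returns a zero-mean, unit-variance series with Hurst exponent `hurst`.
gen_fgn <- function(n_samples, hurst, seed = 1L) {
  n <- as.integer(n_samples)
  H <- hurst
  m <- stats::nextn(2L * (n - 1L), c(2, 3, 5))
  if (m %% 2L != 0L) m <- stats::nextn(m + 1L, c(2, 3, 5))
  k <- 0:(m / 2)
  # fGn autocovariance gamma(k) = (|k+1|^2H - 2|k|^2H + |k-1|^2H) / 2
  g <- (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H)) / 2
  row <- c(g, g[(m / 2):2])
  lambda <- Re(fft(row))
  lambda[lambda < 0] <- 0  # clip tiny negative eigenvalues from roundoff
  z <- withr::with_seed(seed, complex(real = rnorm(m), imaginary = rnorm(m)))
  w <- fft(sqrt(lambda / (2 * m)) * z)
  x <- Re(w)[seq_len(n)]
  (x - mean(x)) / sd(x)
}

#' Generate a positive envelope with a known DFA exponent
#'
#' Synthesizes exact fractional Gaussian noise by circulant embedding and maps
#' it to a strictly positive envelope by shifting up 3 standard deviations and
#' clipping at a small positive floor. The clipping affects well under 1% of
#' samples, so the DFA exponent of the result tracks `hurst` closely (the
#' residual distortion is quantified in the test suite).
#'
#' @param n_samples Number of samples.
#' @param hurst Target Hurst exponent in (0, 1).
#' @param seed Integer seed.
#' @return Strictly positive numeric vector of length `n_samples`.
#' @export
gen_fgn_envelope <- function(n_samples, hurst, seed = 1L) {
  if (!is.numeric(hurst) || hurst <= 0 || hurst >= 1) {
    rlang::abort("`hurst` must lie strictly in (0, 1).")
  }
  if (n_samples < 2) rlang::abort("`n_samples` must be >= 2.")
  z <- gen_fgn(n_samples, hurst, seed)
  pmax(z + 3, 0.01)
}

#' Generate a single-ROI synthetic signal
#'
#' Realizes a `signal_spec`: a band-pass-filtered white-noise carrier in
#' `osc_center +/- osc_bandwidth/2`, multiplied by an LRTC envelope from
#' [gen_fgn_envelope()] (optionally recoupled via `fei_coupling`), scaled to
#' `osc_power`, plus an aperiodic 1/f^chi background and white noise. Healthy,
#' excitation-dominated and inhibition-dominated regimes are obtained by the
#' presets in [cohort_presets()].
#'
#' @param spec A [signal_spec()].
#' @param roi_label Column label for the generated ROI.
#' @return A single-ROI [roi_ts()] whose `params` field records the full
#'   ground-truth spec.
#' @export
gen_roi_signal <- function(spec, roi_label = "roi_1") {
  stopifnot(inherits(spec, "signal_spec"))
  n <- as.integer(round(spec$duration_s * spec$fs))
  seeds <- vapply(1:3, function(i) derive_seed(spec$seed, i), integer(1))

  osc <- numeric(n)
  if (spec$osc_power > 0) {
    white <- withr::with_seed(seeds[1], rnorm(n))
    f <- (seq_len(n) - 1) / n * spec$fs
    f[f > spec$fs / 2] <- spec$fs - f[f > spec$fs / 2]
    lo <- spec$osc_center - spec$osc_bandwidth / 2
    hi <- spec$osc_center + spec$osc_bandwidth / 2
    Xb <- fft(white) * raised_cosine_mask(f, lo, hi, min(2, lo / 2))
    carrier <- Re(fft(Xb, inverse = TRUE)) / n
    env <- gen_fgn_envelope(n, spec$envelope_hurst, seeds[2])
    # contrast sharpening: the shifted fGn envelope has CV ~ 1/3, too flat to
    # dominate the Rayleigh fluctuations of the noise carrier; a smooth
    # monotone power map raises the CV to a realistic ~1 while preserving
    # the long-memory exponent (Hermite rank 1 transform)
    env <- (env / 3)^spec$env_contrast
    # band-limit the modulator: raw fGn has a flat high-frequency tail that
    # would smear oscillatory power across the whole spectrum; a physical
    # amplitude envelope varies no faster than the oscillation's bandwidth
    env_lp <- fft_bandpass(env - mean(env), spec$fs, low = 0,
                           high = spec$osc_bandwidth, transition = 2)
    env <- pmax(env_lp + mean(env), 0.001 * mean(env))
    # analytic decomposition of the carrier: slow LRTC level a(t) modulates
    # the oscillation, and the E-I coupling compresses (fei_coupling > 0,
    # excitation-dominated: relatively quieter high-amplitude epochs) or
    # expands (< 0) the carrier's own Rayleigh fluctuations as a function of
    # the local amplitude -- the relationship the fE/I statistic measures
    h <- numeric(n)                        # analytic-signal weights
    if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 } else {
      h[1] <- 1; h[2:((n + 1) / 2)] <- 2
    }
    ca <- Mod(fft(Xb * h, inverse = TRUE) / n)
    cr <- ca / mean(ca)                    # Rayleigh-distributed, mean 1
    phase_cos <- ifelse(ca > 0, carrier / ca, 0)
    a_rel <- moving_mean(env, max(2L, round(5 * spec$fs))) / mean(env)
    g <- pmin(pmax(a_rel^(-spec$fei_coupling), 0.25), 4)
    osc <- env * cr^g * phase_cos
    osc <- osc * sqrt(spec$osc_power) / sd(osc)
  }
  bg <- gen_aperiodic_background(n, spec$fs, spec$aperiodic_exponent,
                                 spec$aperiodic_power, seeds[3])
  wn <- if (spec$white_noise_power > 0) {
    withr::with_seed(derive_seed(spec$seed, 4),
                     rnorm(n, sd = sqrt(spec$white_noise_power)))
  } else numeric(n)

  roi_ts(matrix(osc + bg + wn, ncol = 1), fs = spec$fs,
         roi_labels = roi_label, params = unclass(spec))
}

#' Cohort specification
#'
#' Describes a synthetic cohort: one template [signal_spec()] per group with
#' per-subject Gaussian jitter on selected parameters, a shared ROI label
#' list, and a linear cognitive-score model tied to each subject's true
#' generative parameters (an MMSE-like covariate).
#'
#' @param groups A list of group definitions; each element is a list with
#'   fields `label`, `n_subjects`, `template` (a `signal_spec`), and
#'   optionally `jitter` — a named list of SDs for any numeric spec field
#'   (e.g. `list(envelope_hurst = 0.03)`).
#' @param rois Character vector of ROI labels generated per subject.
#' @param score_model List with `baseline`, `slope_hurst`, `slope_exponent`,
#'   `noise_sd`: score = baseline + slope_hurst * envelope_hurst +
#'   slope_exponent * aperiodic_exponent + N(0, noise_sd), clipped to [0, 30].
#' @param master_seed Integer master seed; per-subject seeds are derived by a
#'   deterministic hash of (master_seed, group, subject index).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(groups, rois = c("syn_roi_1", "syn_roi_2"),
                        score_model = list(baseline = 4, slope_hurst = 20,
                                           slope_exponent = 6, noise_sd = 1),
                        master_seed = 1L) {
  if (length(groups) == 0) rlang::abort("`groups` must be non-empty.")
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) rlang::abort("group labels must be unique.")
  if (anyDuplicated(rois)) rlang::abort("ROI labels must be unique.")
  for (g in groups) {
    stopifnot(inherits(g$template, "signal_spec"))
    if (g$n_subjects < 1) rlang::abort("each group needs n_subjects >= 1.")
  }
  structure(list(groups = groups, rois = rois, score_model = score_model,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws a jittered `signal_spec` per subject, generates one signal per ROI,
#' and computes a cognitive score from the subject's true parameters. Fully
#' deterministic given `master_seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `subjects` (a tibble: subject_id, group,
#'   cognitive_score plus true generative parameters) and `signals` (a named
#'   list of multi-ROI [roi_ts()] objects, one per subject).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sm <- spec$score_model
  rows <- list()
  signals <- list()
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[[gi]]
    for (si in seq_len(g$n_subjects)) {
      sid <- sprintf("%s_%02d", g$label, si)
      sseed <- derive_seed(spec$master_seed, g$label, si)
      subj_spec <- jitter_spec(g$template, g$jitter, sseed)
      cols <- lapply(seq_along(spec$rois), function(ri) {
        rspec <- subj_spec
        rspec$seed <- derive_seed(sseed, ri)
        gen_roi_signal(rspec, roi_label = spec$rois[ri])$data[, 1]
      })
      score <- withr::with_seed(
        derive_seed(sseed, "score"),
        sm$baseline + sm$slope_hurst * subj_spec$envelope_hurst +
          sm$slope_exponent * subj_spec$aperiodic_exponent +
          rnorm(1, sd = sm$noise_sd)
      )
      score <- min(max(score, 0), 30)
      signals[[sid]] <- roi_ts(do.call(cbind, cols), fs = subj_spec$fs,
                               roi_labels = spec$rois, subject_id = sid,
                               group = g$label, cognitive_score = score,
                               params = unclass(subj_spec))
      rows[[sid]] <- tibble::tibble(
        subject_id = sid, group = g$label, cognitive_score = score,
        envelope_hurst = subj_spec$envelope_hurst,
        aperiodic_exponent = subj_spec$aperiodic_exponent,
        osc_center = subj_spec$osc_center,
        fei_coupling = subj_spec$fei_coupling
      )
    }
  }
  list(subjects = dplyr::bind_rows(rows), signals = signals)
}

# Apply per-subject Gaussian jitter to selected template fields, respecting
# each field's domain (hurst clipped into (0.05, 0.95), powers/exponent >= 0).
jitter_spec <- function(template, jitter, seed) {
  s <- unclass(template)
  s$seed <- seed
  if (!is.null(jitter) && length(jitter) > 0) {
    draws <- withr::with_seed(derive_seed(seed, "jitter"),
                              rnorm(length(jitter)))
    for (i in seq_along(jitter)) {
      f <- names(jitter)[i]
      s[[f]] <- s[[f]] + draws[i] * jitter[[i]]
    }
    s$envelope_hurst <- min(max(s$envelope_hurst, 0.05), 0.95)
    s$aperiodic_exponent <- max(s$aperiodic_exponent, 0)
    for (f in c("osc_power", "aperiodic_power", "white_noise_power")) {
      s[[f]] <- max(s[[f]], 0)
    }
  }
  do.call(signal_spec, s[setdiff(names(s), character(0))])
}

#' Group presets for synthetic cohorts
#'
#' Returns template [signal_spec()]s emulating a healthy-elderly-like (HE)
#' group — a 10 Hz alpha oscillation with strong envelope LRTC (Hurst 0.80), a
#' steep aperiodic background (chi = 1.6) and mildly inhibition-tilted
#' amplitude-fluctuation coupling — and an Alzheimer-like (AD) group with
#' oscillatory slowing (center 7.5 Hz), weaker LRTC (Hurst 0.65), a flatter
#' background (chi = 1.1), relatively more low-frequency power, and coupling
#' shifted toward excitation.
#'
#' @param duration_s Per-subject recording length in seconds (default 140,
#'   within the 137-277 s range typical of artifact-cleaned resting state).
#' @param fs Sampling rate, Hz.
#' @return Named list with elements `HE` and `AD`.
#' @export
cohort_presets <- function(duration_s = 140, fs = 1250) {
  list(
    HE = signal_spec(duration_s = duration_s, fs = fs, osc_center = 10,
                     osc_bandwidth = 4, envelope_hurst = 0.80, osc_power = 1,
                     aperiodic_exponent = 1.6, aperiodic_power = 0.3,
                     white_noise_power = 0.001, fei_coupling = -1),
    AD = signal_spec(duration_s = duration_s, fs = fs, osc_center = 7.5,
                     osc_bandwidth = 4, envelope_hurst = 0.65, osc_power = 1,
                     aperiodic_exponent = 1.1, aperiodic_power = 0.3,
                     white_noise_power = 0.001, fei_coupling = 1)
  )
}

#' Default two-group demonstration cohort specification
#'
#' HE-like vs AD-like groups (n per group configurable) with modest
#' between-subject jitter and a cognitive-score model in which higher envelope
#' Hurst and steeper aperiodic exponent predict better scores.
#'
#' @param n_per_group Subjects per group.
#' @param master_seed Master seed.
#' @param duration_s Recording length per subject, seconds.
#' @return A [cohort_spec()].
#' @export
demo_cohort_spec <- function(n_per_group = 20, master_seed = 1L,
                             duration_s = 140) {
  p <- cohort_presets(duration_s = duration_s)
  jit <- list(envelope_hurst = 0.04, aperiodic_exponent = 0.12,
              osc_center = 0.5, fei_coupling = 0.15)
  cohort_spec(
    groups = list(
      list(label = "HE", n_subjects = n_per_group, template = p$HE, jitter = jit),
      list(label = "AD", n_subjects = n_per_group, template = p$AD, jitter = jit)
    ),
    rois = c("syn_roi_1", "syn_roi_2"),
    score_model = list(baseline = 2, slope_hurst = 22, slope_exponent = 5,
                       noise_sd = 1.5),
    master_seed = master_seed
  )
}
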