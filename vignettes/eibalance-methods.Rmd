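---
title: "Estimating cortical excitation–inhibition balance from resting-state oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cortical excitation–inhibition balance from resting-state oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(eibalance)
```

## The problem

The ratio of excitatory to inhibitory synaptic drive (E–I balance) shapes
cortical dynamics but cannot be measured directly in humans. Three
non-invasive markers computed from resting-state source-space MEG/EEG are
implemented here, together with the preprocessing, statistics and a
synthetic-cohort generator whose ground truth makes every stage testable by
parameter recovery.

A recording enters the pipeline as a samples × ROIs matrix (`roi_ts`) with a
sampling rate, ROI labels, group label, optional cognitive score and an
optional artifact mask. Bad segments are excised and the clean pieces
concatenated sample-exactly (`apply_artifact_mask()`; splice times are kept
so envelope stages *could* exclude windows spanning them — by default they do
not, matching the common practice of concatenating without further
correction). Spectral analyses run on data decimated by 4; envelope analyses
(DFA, fE/I) run at the original rate.

## The three markers

**DFA.** Long-range temporal correlations (LRTC) of the oscillation
amplitude envelope are quantified by detrended fluctuation analysis: demean
the envelope, integrate it into a profile, cut the profile into
50%-overlapping windows of log-spaced sizes, remove a linear trend per
window, average the per-window RMS into the fluctuation function $F(t)$, and
fit $\alpha$ as the slope of $\log_{10} F$ against $\log_{10} t$. An
uncorrelated signal gives $\alpha = 0.5$; persistent envelope correlations
give $\alpha > 0.5$ and are strongest near criticality / E–I balance.

Defaults: extended alpha band 6–13 Hz (widened downward because the dominant
rhythm slows in Alzheimer's disease), window sizes 1–20 s (15 log-spaced
sizes, 50% overlap), order-1 detrending. The window range balances the
envelope's autocorrelation floor (well below 1 s for a 7-Hz-wide band)
against the ≥ 120 s recordings (20 s ≤ 1/6 of the shortest signal); all
three settings are arguments. A caveat quantified in the test suite: because
the envelope of a band-limited signal is itself band-limited, $F(t)$ bends
upward below a few seconds even for temporally uncorrelated input, so the
1–20 s fit of filtered *white noise* averages ≈ 0.55 rather than the
asymptotic 0.5 (local slopes fall from ≈ 0.64 at 1 s to ≈ 0.5 by 10–20 s).
Estimates of genuinely long-memory envelopes are essentially unbiased (the
fractional-Gaussian-noise recovery tests hold to ±0.05), but the *null* value
of this estimator at these window sizes sits above 0.5, which matters when
interpreting exponents near the fE/I validity threshold.

**fE/I.** The functional E/I ratio asks how the size of envelope
fluctuations covaries with the local amplitude. The envelope is cut into
non-overlapping 5-s windows aligned to signal start (trailing partial window
dropped). Per window: $A_w$ is the mean amplitude; the window's demeaned
envelope is divided by $A_w$ (making it dimensionless — the
"amplitude-normalized" fluctuation), integrated, linearly detrended, and its
RMS is $nF_w$. Then $\mathrm{fE/I} = 1 - r(A_w, nF_w)$ with Pearson $r$
(rank correlation available as a sensitivity option). In a balanced network
amplitude and normalized fluctuations are uncoupled and fE/I ≈ 1; excitation
dominance quiets high-amplitude epochs relatively ($r < 0$, fE/I > 1);
inhibition dominance does the opposite. Because the statistic is meaningless
without LRTC, it is gated on the channel's DFA exponent: below the 0.55
threshold (0.60 conservative) the ROI is excluded and counted, and a region
with no valid ROIs legitimately has no value.

**Aperiodic exponent.** The 30–48 Hz power spectrum is parameterized in
log–log coordinates into an aperiodic line and up to 2 Gaussian peaks: a
robust initial line (bins above the upper Tukey fence of the residuals are
treated as peak bins and excluded), greedy peak extraction from the residual
(absolute height floor 0.05 log₁₀ units plus a relative floor of 2 SD of the
flattened spectrum), a line refit on the peak-subtracted spectrum, and a
bounded joint refinement of line plus peaks. Peaks whose center sits within
one SD of a range edge are discarded — over an 18-Hz range a half-Gaussian
is indistinguishable from aperiodic curvature. No "knee" parameter is fitted:
a knee is unidentifiable over 0.2 decades. $R^2$ is computed on log₁₀ power
(the scale of the fit) and fits with $R^2 < 0.8$ are rejected and recorded
as missing. The region-level exponent fits the *region-average* spectrum
(one spectrum per region), not a mean of per-ROI exponents. Peak width
bounds are 0.5–3.4 Hz (SD), i.e. roughly 1–8 Hz full width.

## Spectral conventions

Power spectra use a plain rectangular-window FFT per 4096-sample epoch
(13.1 s at 312.5 Hz; the epoch length is the largest power of two under
14 s at the decimated rate), averaged over the first 10 epochs, on the
fs/4096 ≈ 0.076 Hz grid restricted to 1–48 Hz. Power is normalized as
one-sided amplitude²/bin so Parseval holds. Smoothing is a centered 20-bin
(~1.5 Hz) moving mean with MATLAB `movmean` window alignment (for even
spans, k/2 bins before through k/2 − 1 after) and shrinking edge windows.
For the synthetic cohorts the steep 1/f background makes the *aperiodic* fit
sensitive to rectangular-window leakage; a Hann taper is available
(`power_spectrum(..., taper = "hann")`) but the default pipeline stays
rectangular and instead relies on the generator band-limiting its envelope
(below). Band-pass filtering is an FFT-domain raised-cosine mask (transition
width `min(2 Hz, low/2)`): exactly zero-phase at all frequencies and stable
for the 1-Hz-wide sweep bands where time-domain designs need impractically
long filters. One second at each edge is trimmed before envelope analyses.
Decimation uses the same machinery with cutoff at 0.8× the target Nyquist
and the transition closed by 0.95× Nyquist.

## The synthetic cohort

Each ROI signal is the sum of three components with variances set by the
spec: (1) an oscillation — a band-limited Gaussian carrier decomposed into
its Rayleigh envelope and phase, multiplied by an LRTC modulator; (2) a
1/f^χ aperiodic background (white noise shaped in the frequency domain);
(3) white sensor noise. The modulator starts as exact fractional Gaussian
noise (circulant embedding, so the target Hurst exponent is unbiased by
construction), made positive by a 3-SD shift with clipping at a small floor
(clipping touches ≪ 1% of samples; the induced DFA distortion is below 0.01
in the recovery tests). Two further transforms make the oscillation
physically plausible and the regimes realizable:

- *Contrast*: the shifted fGn has CV ≈ 1/3, too flat for its LRTC to
  dominate the carrier's own Rayleigh fluctuations; a monotone power map
  (exponent `env_contrast` = 3) raises the CV to ≈ 1, as real alpha
  envelopes show, while preserving the long-memory exponent (a smooth
  Hermite-rank-1 transform).
- *Band-limiting*: raw fGn is spectrally flat to the Nyquist; multiplying
  the carrier by it would smear oscillatory power across the whole spectrum,
  including the 30–48 Hz fit range. The modulator is low-passed to the
  oscillation bandwidth — a physical envelope varies no faster than the
  band it modulates.

The E–I dial, `fei_coupling` $c$, scales the carrier's fluctuations by
$(a(t)/\bar a)^{-c}$ where $a(t)$ is the 5-s local amplitude: $c > 0$
compresses fluctuations in loud epochs (excitation-like, fE/I > 1), $c < 0$
expands them (inhibition-like). $c = 0$ leaves the carrier untouched.

Cohort presets encode the study conditions: a healthy-elderly-like group
(10 Hz center, envelope Hurst 0.80, χ = 1.6, c = −1, giving fE/I ≈ 0.79)
and an AD-like group (center 7.5 Hz — oscillatory slowing expressed as theta
excess and alpha deficit; Hurst 0.65, χ = 1.1, c = +1, fE/I ≈ 1.2), 140-s
recordings (within the 137–277 s range typical after artifact cleaning, and
long enough for the ten 4096-sample epochs), 1250 Hz, two synthetic ROIs per
subject, modest between-subject jitter, and an MMSE-like score
(2 + 22·Hurst + 5·χ + N(0, 1.5), clipped to [0, 30]) so better scores
accompany stronger LRTC and steeper slopes. The coupling values were
calibrated by simulation so the group contrast is inside the healthy
inhibition-tilted range reported for elderly controls (median 0.88,
IQR 0.72–0.95) on one side and the AD-ward excitation shift on the other,
with a separation large enough that a 20-vs-20 cohort detects it reliably;
they were then frozen. Per-subject seeds derive
from a documented hash of (master seed, group label, subject index), giving
reproducible yet independent streams; everything is bit-deterministic given
the master seed.

What the generator does *not* emulate: volume conduction and source leakage
between ROIs (synthetic ROIs are independent), non-Rayleigh envelope laws of
real alpha (the modulated-carrier envelope is Rayleigh-mixed, a modelling
choice), nonstationary artifacts, or a beta rhythm — so the AD-like spectral
deficit is generated in the alpha band, and passing recovery tests show the
estimators work under this model, not that real MEG satisfies it.

## Statistics

The statistical layer mirrors standard nonparametric practice: values more
than 3×IQR outside the quartiles (type-7 linear-interpolation quantiles) are
flagged per group/region/measure and excluded; Kruskal–Wallis (tie-corrected,
χ² p on k−1 df) tests overall differences; each group is compared with the
reference by a two-sided Mann–Whitney U (exact for both n ≤ 8 without ties,
tie-corrected normal approximation otherwise) reporting pooled mean ranks;
pairwise results are reported regardless of omnibus significance and flagged
as such. Per-frequency power comparisons form one FDR family per
(group-vs-reference, region) across bins, controlled by the two-stage
Benjamini–Krieger–Yekutieli step-up at q = 1% (stage 1 at q/(1+q), stage 2
at q/(1+q)·m/m₀), and contiguous significant bins are summarized into
ranges. Spearman correlations with the cognitive score are exact for n ≤ 9
without ties. Fully tied comparisons return p = 1 rather than NA.

## Numerical choices and degenerate inputs

Window sizes below 8 samples are dropped from DFA; a constant envelope makes
$F(t)$ vanish and yields a flagged warning with an undefined exponent rather
than a number. Zero-amplitude fE/I windows are dropped with a warning; fewer
than two usable windows is an error. fE/I is bounded in [0, 2] by
construction and invariant to positive rescaling of the envelope (both
properties are tested to 10⁻¹⁰). The aperiodic fitter requires strictly
positive power on the fit range, and a diverged or poor fit is a recorded
rejection, never an abort. At the cohort level, any per-subject failure
excludes that subject with a logged warning and the run continues — the
missingness codes (`outlier`, `dfa_gated`, `r2_rejected`) keep every cell of
the measures table accountable.

## Problem sizes used in the automated checks

The test suite and the acceptance script run at desk scale, chosen to keep
the full run in tens of minutes on one CPU: 20 realizations of 300-s signals
for the white-noise DFA calibration; fractional-Gaussian-noise recovery on
10⁵-sample envelopes (20 seeds per Hurst value); 100 amplitude permutations
for the fE/I null; 50 random gamma spectra for the aperiodic cross-check;
and 20 master seeds of a 20-vs-20-subject cohort for the end-to-end
direction-of-effect check. Larger runs only narrow the Monte-Carlo error of
quantities whose expected values the smaller runs already pin down.
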