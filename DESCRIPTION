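Package: eibalance
Title: Spectral and Temporal-Correlation Markers of Cortical Excitation-Inhibition Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state source-space MEG/EEG markers of
    the cortical excitation-inhibition (E-I) ratio: power spectra (1-48 Hz) with
    moving-mean smoothing, detrended fluctuation analysis (DFA) of oscillation
    amplitude envelopes, the functional excitation/inhibition ratio (fE/I) with
    DFA-validity gating, and parameterization of the gamma-range (30-48 Hz)
    aperiodic spectral exponent. Includes a synthetic-cohort generator with
    known ground-truth long-range temporal correlations, aperiodic structure and
    amplitude-fluctuation coupling so every stage admits parameter-recovery
    tests, plus the nonparametric statistical layer (3xIQR outlier flagging,
    Kruskal-Wallis, pairwise Mann-Whitney with mean ranks, two-stage
    Benjamini-Krieger-Yekutieli FDR, Spearman correlations with cognitive
    scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
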