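#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with defaults matching the
#' reference protocol: decimation factor 4, 10 epochs of the largest
#' power-of-two length under 14 s (4096 samples at 312.5 Hz), 1-48 Hz
#' spectra smoothed over 20 bins, extended alpha band 6-13 Hz, DFA windows
#' 1-20 s (15 log-spaced sizes, 50% overlap), 5-s fE/I windows with DFA
#' validity threshold 0.55 (0.60 for sensitivity), 30-48 Hz aperiodic fit
#' with R-squared >= 0.8 acceptance, FDR q = 1%, and the 3 x IQR outlier
#' rule.
#'
#' @param ... Overrides for any default field.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_epochs = 10,
    spectrum_range = c(1, 48),
    smooth_bins = 20,
    band = alpha_band(),
    dfa_window_range_s = c(1, 20),
    dfa_n_windows = 15,
    dfa_overlap = 0.5,
    fei_window_s = 5,
    fei_threshold = 0.55,
    fei_threshold_sensitivity = 0.60,
    aperiodic_range = c(30, 48),
    aperiodic_r2_min = 0.8,
    fdr_q = 0.01,
    outlier_k = 3,
    min_duration_s = 120
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    rlang::abort(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Simulate a cohort and write it to disk
#'
#' Deterministic given the cohort spec's master seed; a manifest records the
#' spec and a content hash so identical runs are verifiable.
#'
#' @param spec A [cohort_spec()] (e.g. [demo_cohort_spec()]).
#' @param dir Output directory.
#' @return Invisibly, the directory. Side effects: per-subject matrix + JSON
#'   sidecar files, `subjects.csv`, `manifest.json`.
#' @export
run_simulate <- function(spec, dir) {
  cohort <- gen_cohort(spec)
  write_cohort(cohort, dir)
  digest <- sum(vapply(cohort$signals,
                       function(s) sum(abs(s$data[seq(1, nrow(s$data), by = 997), 1])),
                       numeric(1)))
  manifest <- list(master_seed = spec$master_seed,
                   n_subjects = nrow(cohort$subjects),
                   rois = spec$rois,
                   groups = vapply(spec$groups, `[[`, character(1), "label"),
                   checksum = signif(digest, 12))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Analyse one subject
#'
#' Runs the full measure chain on a single recording: artifact-mask excision;
#' decimation by 4, epoching and per-ROI spectra with region averaging and
#' smoothing; alpha-band envelope DFA and gated fE/I per ROI at the original
#' rate, averaged within regions; aperiodic fit of each region-average
#' spectrum. Failures of individual measures become missingness codes, never
#' aborts.
#'
#' @param ts A [roi_ts()].
#' @param regions List of [region_set()]s.
#' @param config A [pipeline_config()].
#' @return List with `measures` (tibble: subject_id, group, region, measure,
#'   value, missing_reason), `spectrum` (tibble: subject_id, group, region,
#'   freq_hz, power), `exclusions` (fE/I exclusion report rows).
#' @export
analyze_subject <- function(ts, regions, config = pipeline_config()) {
  stopifnot(inherits(ts, "roi_ts"))
  ts <- apply_artifact_mask(ts, min_duration_s = config$min_duration_s)

  dec <- decimate_by_4(ts)
  ep <- epoch(dec, n_epochs = config$n_epochs)
  spec <- power_spectrum(ep, f_range = config$spectrum_range)

  env_list <- list()
  dfa_vals <- numeric(0)
  for (lbl in ts$roi_labels) {
    env_list[[lbl]] <- band_envelope(ts$data[, lbl], config$band, ts$fs)
    d <- dfa(env_list[[lbl]], ts$fs,
             window_range_s = config$dfa_window_range_s,
             n_windows = config$dfa_n_windows,
             overlap_frac = config$dfa_overlap, band = config$band, roi = lbl)
    dfa_vals[lbl] <- d$exponent
  }

  measures <- list()
  spectra <- list()
  exclusions <- list()
  for (region in regions) {
    rspec <- smooth_spectrum(region_average(spec, region), config$smooth_bins)
    spectra[[region$name]] <- tibble::tibble(
      subject_id = ts$subject_id, group = ts$group, region = region$name,
      freq_hz = rspec$freqs, power = rspec$power[, 1]
    )

    dfa_region <- mean(dfa_vals[region$members])
    fei_res <- lapply(region$members, function(lbl) {
      fei(env_list[[lbl]], ts$fs, dfa_exponent = dfa_vals[[lbl]],
          window_s = config$fei_window_s, threshold = config$fei_threshold,
          roi = lbl)
    })
    names(fei_res) <- region$members
    fr <- fei_region(fei_res, region, subject_id = ts$subject_id)
    exclusions[[region$name]] <- fr$exclusions

    ap <- tryCatch(
      fit_aperiodic(rspec, f_range = config$aperiodic_range,
                    r2_min = config$aperiodic_r2_min) |>
        glance(),
      error = function(e) tibble::tibble(exponent = NA_real_, accepted = FALSE)
    )

    measures[[region$name]] <- tibble::tibble(
      subject_id = ts$subject_id, group = ts$group, region = region$name,
      measure = c("dfa", "fei", "aperiodic_exponent", "n_excluded_rois"),
      value = c(dfa_region, fr$fei,
                if (ap$accepted) ap$exponent else NA_real_,
                fr$exclusions$n_rois_excluded),
      missing_reason = c(
        if (is.na(dfa_region)) "degenerate" else NA_character_,
        if (is.na(fr$fei)) "dfa_gated" else NA_character_,
        if (!ap$accepted) "r2_rejected" else NA_character_,
        NA_character_
      )
    )
  }
  list(measures = dplyr::bind_rows(measures),
       spectrum = dplyr::bind_rows(spectra),
       exclusions = dplyr::bind_rows(exclusions))
}

#' Analyse a cohort
#'
#' Maps [analyze_subject()] over a cohort (from [gen_cohort()] or
#' [load_cohort()]); per-subject errors are logged and the subject excluded,
#' mirroring a per-subject exclusion workflow rather than aborting the run.
#'
#' @param cohort List with `subjects` and `signals`.
#' @param regions List of [region_set()]s; default a single synthetic region
#'   covering all ROIs of the first subject.
#' @param config A [pipeline_config()].
#' @return List with tibbles `measures`, `spectra`, `exclusions`, and the
#'   cohort `subjects` table.
#' @export
run_analyze <- function(cohort, regions = NULL, config = pipeline_config()) {
  if (is.null(regions)) {
    rois <- cohort$signals[[1]]$roi_labels
    regions <- list(region_set("synthetic", rois))
  }
  res <- purrr::map(cohort$signals, function(ts) {
    tryCatch(analyze_subject(ts, regions, config),
             error = function(e) {
               rlang::warn(sprintf("subject %s excluded: %s",
                                   ts$subject_id, conditionMessage(e)))
               NULL
             })
  })
  res <- purrr::compact(res)
  list(
    measures = purrr::map_dfr(res, "measures"),
    spectra = purrr::map_dfr(res, "spectrum"),
    exclusions = purrr::map_dfr(res, "exclusions"),
    subjects = cohort$subjects
  )
}

#' Group-level statistics over analysed measures
#'
#' Applies the statistical layer to [run_analyze()] output: 3 x IQR outlier
#' removal per group/measure/region, Kruskal-Wallis omnibus tests, pairwise
#' Mann-Whitney tests of every group against the reference with mean ranks
#' (reported regardless of omnibus significance, and so flagged), Spearman
#' correlations between each measure and the cognitive score per group, and
#' per-frequency spectral comparisons with two-stage FDR.
#'
#' @param results Output of [run_analyze()].
#' @param reference_group Reference group label (default `"HE"`).
#' @param config A [pipeline_config()].
#' @return List of tibbles: `omnibus`, `pairwise`, `correlations`,
#'   `frequency_bins`, `frequency_ranges`, `outliers`.
#' @export
group_statistics <- function(results, reference_group = "HE",
                             config = pipeline_config()) {
  m <- dplyr::filter(results$measures, !is.na(.data$value))

  flagged <- m |>
    dplyr::group_by(.data$group, .data$region, .data$measure) |>
    dplyr::mutate(outlier = if (dplyr::n() >= 4)
      iqr_outliers(.data$value, k = config$outlier_k)$outlier else FALSE) |>
    dplyr::ungroup()
  outliers <- dplyr::filter(flagged, .data$outlier)
  m <- dplyr::filter(flagged, !.data$outlier)

  omnibus <- m |>
    dplyr::group_by(.data$region, .data$measure) |>
    dplyr::group_modify(function(d, key) {
      kruskal_wallis(split(d$value, d$group))
    }) |>
    dplyr::ungroup()

  pairwise <- m |>
    dplyr::group_by(.data$region, .data$measure) |>
    dplyr::group_modify(function(d, key) {
      ref <- d$value[d$group == reference_group]
      others <- split(d$value, d$group)
      others <- others[setdiff(names(others), reference_group)]
      if (length(ref) == 0 || length(others) == 0) return(tibble::tibble())
      mann_whitney_pairwise(ref, others, ref_label = reference_group)
    }) |>
    dplyr::ungroup()

  scores <- results$subjects[, c("subject_id", "cognitive_score")]
  correlations <- m |>
    dplyr::inner_join(scores, by = "subject_id") |>
    dplyr::group_by(.data$group, .data$region, .data$measure) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) return(tibble::tibble())
      spearman(d$value, d$cognitive_score)
    }) |>
    dplyr::ungroup()

  freq <- purrr::map(split(results$spectra, results$spectra$region),
                     function(d) {
                       per_frequency_comparison(d, reference_group,
                                                q = config$fdr_q)
                     })
  frequency_bins <- purrr::imap_dfr(freq, function(f, rg)
    dplyr::mutate(f$bins, region = rg, .before = 1))
  frequency_ranges <- purrr::imap_dfr(freq, function(f, rg)
    dplyr::mutate(f$ranges, region = rg, .before = 1))

  list(omnibus = omnibus, pairwise = pairwise, correlations = correlations,
       frequency_bins = frequency_bins, frequency_ranges = frequency_ranges,
       outliers = outliers)
}

#' Summary report of a full run
#'
#' Renders the group-level summaries: per-measure medians and interquartile
#' ranges per group and region, exclusion counts, the correlation table, and
#' group-mean spectra with significant-bin ranges. Purely a deterministic
#' reshaping of saved results — regenerating from the same inputs gives
#' identical tables.
#'
#' @param results Output of [run_analyze()].
#' @param stats Output of [group_statistics()] (computed if omitted).
#' @param reference_group Reference group label.
#' @param config A [pipeline_config()].
#' @return List with `group_summaries`, `exclusion_summary`, `correlations`,
#'   `significant_ranges`, `spectra_plot` (ggplot), `measures_plot` (ggplot).
#' @export
run_report <- function(results, stats = NULL, reference_group = "HE",
                       config = pipeline_config()) {
  if (is.null(stats)) {
    stats <- group_statistics(results, reference_group, config)
  }
  group_summaries <- results$measures |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$region, .data$measure, .data$group) |>
    dplyr::summarise(n = dplyr::n(), median = median(.data$value),
                     q1 = quantile(.data$value, 0.25, names = FALSE),
                     q3 = quantile(.data$value, 0.75, names = FALSE),
                     .groups = "drop")
  exclusion_summary <- results$exclusions |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_subjects = dplyr::n(),
                     total_excluded_rois = sum(.data$n_rois_excluded),
                     .groups = "drop")

  mean_spec <- results$spectra |>
    dplyr::group_by(.data$region, .data$group, .data$freq_hz) |>
    dplyr::summarise(power = mean(.data$power), .groups = "drop")
  spectra_plot <- ggplot2::ggplot(
    mean_spec, ggplot2::aes(x = .data$freq_hz, y = .data$power,
                            colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (a.u.)", colour = "Group")
  if (nrow(stats$frequency_ranges) > 0) {
    spectra_plot <- spectra_plot +
      ggplot2::geom_segment(
        data = stats$frequency_ranges,
        ggplot2::aes(x = .data$f_low, xend = .data$f_high),
        y = -Inf, yend = -Inf, colour = "darkred", linewidth = 2,
        inherit.aes = FALSE)
  }

  measures_plot <- results$measures |>
    dplyr::filter(!is.na(.data$value)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::facet_grid(measure ~ region, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)

  list(group_summaries = group_summaries,
       exclusion_summary = exclusion_summary,
       correlations = stats$correlations,
       significant_ranges = stats$frequency_ranges,
       spectra_plot = spectra_plot, measures_plot = measures_plot)
}
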