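#' Flag extreme outliers by the 3 x IQR rule
#'
#' Flags values more than 3 interquartile ranges above the third or below the
#' first quartile. Quartiles use linear interpolation between order statistics
#' (R's default quantile type 7).
#'
#' @param values Numeric vector.
#' @param k Multiplier on the IQR (default 3).
#' @return A tibble with one row per input: `value`, `outlier` (logical).
#'   With fewer than 4 values nothing is flagged and a warning is issued.
#' @export
iqr_outliers <- function(values, k = 3) {
  if (length(values) < 4) {
    rlang::warn("fewer than 4 values; no outlier flagging performed.")
    return(tibble::tibble(value = values, outlier = FALSE))
  }
  q <- quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  tibble::tibble(
    value = values,
    outlier = !is.na(values) &
      (values > q[2] + k * iqr | values < q[1] - k * iqr)
  )
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom (wraps [stats::kruskal.test()]).
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return One-row tibble: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) rlang::abort("need at least 2 groups.")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) rlang::abort("need pooled n >= 3.")
  g <- factor(rep(names(groups) %||% seq_along(groups),
                  vapply(groups, length, integer(1))))
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- kruskal.test(values, g)
  tibble::tibble(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value)
}

#' Pairwise Mann-Whitney U tests against a reference group
#'
#' Two-sided U tests of each group against the reference (wraps
#' [stats::wilcox.test()]): exact distribution when both samples have n <= 8
#' and no ties, tie-corrected normal approximation otherwise. The U statistic
#' reported is the number of (reference, other) pairs where the reference
#' value is greater (the `wilcox.test` W convention with the reference as
#' `x`). Mean ranks are computed on each pooled pair.
#'
#' @param reference Numeric vector (the reference group's values).
#' @param others Named list of numeric vectors.
#' @param ref_label Label for the reference group in the output.
#' @return Tibble with one row per comparison: `group_a` (reference),
#'   `group_b`, `U`, `mean_rank_a`, `mean_rank_b`, `p`.
#' @export
mann_whitney_pairwise <- function(reference, others, ref_label = "reference") {
  if (is.null(names(others))) names(others) <- paste0("group_", seq_along(others))
  purrr::imap_dfr(others, function(y, lbl) {
    rk <- rank(c(reference, y))
    if (length(unique(c(reference, y))) == 1L) {
      # fully tied samples: no evidence of any difference
      return(tibble::tibble(
        group_a = ref_label, group_b = lbl,
        U = length(reference) * length(y) / 2,
        mean_rank_a = mean(rk[seq_along(reference)]),
        mean_rank_b = mean(rk[-seq_along(reference)]), p = 1
      ))
    }
    exact <- length(reference) <= 8 && length(y) <= 8 &&
      !anyDuplicated(c(reference, y))
    wt <- suppressWarnings(
      wilcox.test(reference, y, exact = exact, correct = !exact)
    )
    tibble::tibble(
      group_a = ref_label, group_b = lbl, U = unname(wt$statistic),
      mean_rank_a = mean(rk[seq_along(reference)]),
      mean_rank_b = mean(rk[-seq_along(reference)]),
      p = wt$p.value
    )
  })
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR control
#'
#' The two-stage sharpened step-up procedure: stage 1 runs Benjamini-Hochberg
#' at q' = q/(1+q) to estimate the number of true nulls m0 = m - r1; if any
#' but not all hypotheses are rejected, stage 2 reruns BH at level
#' q' * m / m0. Returns the rejection mask.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param q Desired FDR (default 0.01, i.e. 1%).
#' @return Logical vector, `TRUE` where rejected.
#' @export
bky_fdr <- function(pvalues, q = 0.01) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    rlang::abort("p-values must lie in [0, 1].")
  }
  m <- length(pvalues)
  q1 <- q / (1 + q)
  r1 <- sum(p.adjust(pvalues, method = "BH") <= q1)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  m0 <- m - r1
  p.adjust(pvalues, method = "BH") <= q1 * m / m0
}

#' Spearman rank correlation
#'
#' Rank correlation with tie handling and a two-sided p-value (exact for
#' n <= 9 without ties, t approximation otherwise; wraps
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return One-row tibble: `n`, `rho`, `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) rlang::abort("need n >= 3 complete pairs.")
  if (var(rank(x)) == 0 || var(rank(y)) == 0) {
    rlang::warn("zero variance in ranks; rho undefined.")
    return(tibble::tibble(n = length(x), rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble::tibble(n = length(x), rho = unname(ct$estimate), p = ct$p.value)
}

#' Per-frequency group comparison with two-stage FDR
#'
#' For each non-reference group and each frequency bin, a two-sided
#' Mann-Whitney U test of that group's per-subject power against the
#' reference group's, with [bky_fdr()] applied separately per
#' (group vs reference) family across bins. Contiguous significant bins are
#' summarised into ranges (the red-bar summary of a group-spectrum figure).
#'
#' @param power_tbl Tibble with columns `subject_id`, `group`, `freq_hz`,
#'   `power` — one row per subject per bin, all subjects on a common grid.
#' @param reference_group Reference group label.
#' @param q Desired FDR (default 0.01).
#' @return List with `bins` (tibble: `group`, `freq_hz`, `p`, `direction` —
#'   sign of group median minus reference median — and `significant`) and
#'   `ranges` (tibble of contiguous significant ranges: `group`, `f_low`,
#'   `f_high`, `direction`).
#' @export
per_frequency_comparison <- function(power_tbl, reference_group, q = 0.01) {
  stopifnot(all(c("subject_id", "group", "freq_hz", "power") %in% names(power_tbl)))
  grids <- power_tbl |>
    dplyr::summarise(g = paste(sort(unique(.data$freq_hz)), collapse = ","),
                     .by = "subject_id")
  if (length(unique(grids$g)) != 1L) {
    rlang::abort("subjects are not on a common frequency grid.")
  }
  ref <- dplyr::filter(power_tbl, .data$group == reference_group)
  if (nrow(ref) == 0) rlang::abort("reference group absent.")
  other_groups <- setdiff(unique(power_tbl$group), reference_group)
  freqs <- sort(unique(power_tbl$freq_hz))

  ref_mat <- ref |>
    dplyr::arrange(.data$subject_id, .data$freq_hz)
  ref_split <- split(ref_mat$power, ref_mat$freq_hz)

  bins <- purrr::map_dfr(other_groups, function(gl) {
    gd <- power_tbl |>
      dplyr::filter(.data$group == gl) |>
      dplyr::arrange(.data$subject_id, .data$freq_hz)
    g_split <- split(gd$power, gd$freq_hz)
    p <- vapply(seq_along(freqs), function(i) {
      if (length(unique(c(g_split[[i]], ref_split[[i]]))) == 1L) return(1)
      suppressWarnings(wilcox.test(g_split[[i]], ref_split[[i]],
                                   exact = FALSE)$p.value)
    }, numeric(1))
    dir <- vapply(seq_along(freqs), function(i) {
      sign(median(g_split[[i]]) - median(ref_split[[i]]))
    }, numeric(1))
    tibble::tibble(group = gl, freq_hz = freqs, p = p, direction = dir,
                   significant = bky_fdr(p, q = q))
  })

  sig <- bins |>
    dplyr::mutate(bin = match(.data$freq_hz, freqs)) |>
    dplyr::filter(.data$significant) |>
    dplyr::arrange(.data$group, .data$bin)
  ranges <- if (nrow(sig) == 0) {
    tibble::tibble(group = character(0), f_low = numeric(0),
                   f_high = numeric(0), direction = numeric(0))
  } else {
    sig |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(run = cumsum(c(1, diff(.data$bin) != 1))) |>
      dplyr::group_by(.data$group, .data$run) |>
      dplyr::summarise(f_low = min(.data$freq_hz), f_high = max(.data$freq_hz),
                       direction = sign(sum(.data$direction)),
                       .groups = "drop") |>
      dplyr::select(-"run")
  }

  list(bins = bins, ranges = ranges)
}
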