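#' Excise artifact segments and concatenate the remainder
#'
#' Removes the (merged union of the) masked bad segments from a recording and
#' concatenates the clean pieces in temporal order. Samples are copied
#' bit-exactly — no filtering or tapering across splice points; the splice
#' times are recorded in `splice_points_s` so envelope-based stages can
#' optionally exclude windows spanning them.
#'
#' @param ts A [roi_ts()] with an optional `artifact_mask`.
#' @param min_duration_s Warn if the cleaned recording is shorter than this
#'   (default 120 s, the minimum usable resting-state length).
#' @return A [roi_ts()] without mask, with `splice_points_s` populated.
#' @export
apply_artifact_mask <- function(ts, min_duration_s = 120) {
  stopifnot(inherits(ts, "roi_ts"))
  mask <- ts$artifact_mask
  if (is.null(mask) || nrow(mask) == 0) return(ts)
  mask <- merge_intervals(mask$start_s, mask$end_s)
  n <- nrow(ts$data)
  bad <- rep(FALSE, n)
  for (i in seq_len(nrow(mask))) {
    lo <- max(1L, floor(mask$start_s[i] * ts$fs) + 1L)
    hi <- min(n, ceiling(mask$end_s[i] * ts$fs))
    bad[lo:hi] <- TRUE
  }
  if (all(bad)) {
    rlang::abort("artifact mask removes the entire recording.",
                 class = "eibalance_empty_signal")
  }
  keep <- which(!bad)
  # splice points: positions in the cleaned signal where a gap was closed
  gaps <- which(diff(keep) > 1L)
  splices <- gaps / ts$fs
  out <- roi_ts(ts$data[keep, , drop = FALSE], fs = ts$fs,
                roi_labels = ts$roi_labels, subject_id = ts$subject_id,
                group = ts$group, cognitive_score = ts$cognitive_score,
                params = ts$params, splice_points_s = splices)
  if (ts_duration(out) < min_duration_s) {
    rlang::warn(sprintf(
      "cleaned recording for %s is %.1f s, below the %g s minimum.",
      ts$subject_id, ts_duration(out), min_duration_s))
  }
  out
}

#' Decimate a recording by a factor of 4
#'
#' Zero-phase anti-alias low-pass (FFT-domain raised-cosine mask with cutoff
#' at 0.8 x the target Nyquist and a transition reaching the new Nyquist),
#' then retention of every 4th sample. For 1250 Hz input the output rate is
#' 312.5 Hz, the rate at which spectra are computed.
#'
#' @param ts A [roi_ts()].
#' @return A [roi_ts()] at `fs/4`.
#' @export
decimate_by_4 <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  factor <- 4L
  n <- nrow(ts$data)
  if (n < 8L * factor) {
    rlang::abort("signal too short to decimate.")
  }
  new_nyq <- ts$fs / factor / 2
  cutoff <- 0.8 * new_nyq
  f <- (seq_len(n) - 1) / n * ts$fs
  f[f > ts$fs / 2] <- ts$fs - f[f > ts$fs / 2]
  # transition ends at 0.95 x the new Nyquist: everything that could alias
  # into the analysis band is fully removed before subsampling
  mask <- raised_cosine_mask(f, low = -1, high = cutoff,
                             transition = 0.95 * new_nyq - cutoff)
  idx <- seq(1L, n, by = factor)
  filtered <- apply(ts$data, 2, function(col) {
    Re(fft(fft(col) * mask, inverse = TRUE)) / n
  })
  roi_ts(filtered[idx, , drop = FALSE], fs = ts$fs / factor,
         roi_labels = ts$roi_labels, subject_id = ts$subject_id,
         group = ts$group, cognitive_score = ts$cognitive_score,
         params = ts$params, splice_points_s = ts$splice_points_s)
}

#' Cut a recording into fixed-length spectral epochs
#'
#' Returns the first `n_epochs` consecutive non-overlapping epochs. The epoch
#' length is the largest power of two not exceeding 14 s at the recording's
#' rate — 4096 samples (13.1 s) at 312.5 Hz — keeping the FFT radix-2.
#'
#' @param ts A [roi_ts()], typically after [decimate_by_4()].
#' @param n_epochs Number of epochs requested (default 10).
#' @return A 3-D array (samples x ROIs x epochs) with attributes `fs` and
#'   `roi_labels`. If fewer than `n_epochs` fit, the count is reduced with a
#'   warning; if none fit, an error is raised.
#' @export
epoch <- function(ts, n_epochs = 10) {
  stopifnot(inherits(ts, "roi_ts"))
  len <- 2^floor(log2(14 * ts$fs))
  n <- nrow(ts$data)
  avail <- floor(n / len)
  if (avail < 1) {
    rlang::abort(sprintf(
      "recording too short for one %d-sample epoch (have %d samples).", len, n))
  }
  if (avail < n_epochs) {
    rlang::warn(sprintf("only %d of %d requested epochs fit; using %d.",
                        avail, n_epochs, avail))
    n_epochs <- avail
  }
  out <- array(NA_real_, dim = c(len, ncol(ts$data), n_epochs))
  for (e in seq_len(n_epochs)) {
    out[, , e] <- ts$data[((e - 1) * len + 1):(e * len), , drop = FALSE]
  }
  attr(out, "fs") <- ts$fs
  attr(out, "roi_labels") <- ts$roi_labels
  out
}
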