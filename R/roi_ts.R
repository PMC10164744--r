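#' ROI time-series container
#'
#' A `roi_ts` holds a multichannel source-space recording: a numeric matrix of
#' samples by regions of interest (ROIs), the sampling rate, ROI labels and
#' subject-level metadata. It is the unit all analysis stages consume.
#'
#' @param data Numeric matrix, samples in rows, ROIs in columns. Amplitude
#'   units are arbitrary (source-reconstructed MEG has no absolute scale);
#'   only relative quantities are analysed downstream.
#' @param fs Sampling rate in Hz.
#' @param roi_labels Character vector of ROI names, one per column.
#' @param subject_id Subject identifier.
#' @param group Group label (e.g. `"HE"`, `"AD"`, or a synthetic label).
#' @param cognitive_score Optional global cognition score (MMSE-like, 0-30).
#' @param artifact_mask Optional data frame with columns `start_s`, `end_s`
#'   marking bad segments (seconds from recording start) to be excised.
#' @param params Optional named list of ground-truth generative parameters
#'   (populated by the synthetic generator, `NULL` for real data).
#' @param splice_points_s Numeric vector of times (s) where non-contiguous
#'   pieces were concatenated; populated by [apply_artifact_mask()].
#'
#' @return An object of class `roi_ts`.
#' @seealso [load_subject()], [apply_artifact_mask()], [decimate_by_4()]
#' @export
roi_ts <- function(data, fs, roi_labels = colnames(data),
                   subject_id = "subject", group = "synthetic",
                   cognitive_score = NA_real_, artifact_mask = NULL,
                   params = NULL, splice_points_s = numeric(0)) {
  if (is.vector(data)) data <- matrix(data, ncol = 1L)
  if (!is.matrix(data) || !is.numeric(data)) {
    rlang::abort("`data` must be a numeric matrix (samples x ROIs).")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    rlang::abort("`data` contains NaN/Inf values.", class = "eibalance_data_error")
  }
  check_positive_scalar(fs, "fs")
  if (is.null(roi_labels)) roi_labels <- paste0("roi_", seq_len(ncol(data)))
  if (length(roi_labels) != ncol(data)) {
    rlang::abort("`roi_labels` length must equal the number of columns.",
                 class = "eibalance_format_error")
  }
  dur <- nrow(data) / fs
  if (!is.null(artifact_mask)) {
    artifact_mask <- tibble::as_tibble(artifact_mask)
    stopifnot(all(c("start_s", "end_s") %in% names(artifact_mask)))
    if (nrow(artifact_mask) > 0 &&
        (any(artifact_mask$start_s < 0) || any(artifact_mask$end_s > dur + 1e-9) ||
         any(artifact_mask$end_s <= artifact_mask$start_s))) {
      rlang::abort("artifact mask segments must satisfy 0 <= start < end <= duration.",
                   class = "eibalance_format_error")
    }
  }
  colnames(data) <- roi_labels
  structure(
    list(data = data, fs = fs, roi_labels = roi_labels,
         subject_id = subject_id, group = group,
         cognitive_score = cognitive_score, artifact_mask = artifact_mask,
         params = params, splice_points_s = splice_points_s),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %s [%s]: %d ROIs, %.1f s @ %g Hz\n",
              x$subject_id, x$group, ncol(x$data), nrow(x$data) / x$fs, x$fs))
  if (!is.null(x$artifact_mask) && nrow(x$artifact_mask) > 0) {
    cat(sprintf("  artifact mask: %d segment(s)\n", nrow(x$artifact_mask)))
  }
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

#' Duration of a `roi_ts` in seconds
#' @param ts A [roi_ts()] object.
#' @return Duration in seconds.
#' @export
ts_duration <- function(ts) nrow(ts$data) / ts$fs

#' @describeIn roi_ts Long-format view: one row per sample per ROI.
#' @param x A `roi_ts`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.roi_ts <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    time_s = rep((seq_len(nrow(x$data)) - 1) / x$fs, times = ncol(x$data)),
    roi = rep(x$roi_labels, each = nrow(x$data)),
    value = as.vector(x$data)
  )
}
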