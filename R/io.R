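#' Write a subject's recording to disk
#'
#' One whitespace-delimited numeric matrix (samples x ROIs, plain text, dot
#' decimal) plus a JSON sidecar holding the sampling rate, ROI labels, group,
#' cognitive score, optional artifact mask, and any ground-truth generative
#' parameters.
#'
#' @param ts A [roi_ts()].
#' @param matrix_path Path for the data matrix (`.txt`/`.tsv`).
#' @param sidecar_path Path for the JSON sidecar; defaults to `matrix_path`
#'   with a `.json` extension.
#' @return Invisibly, the two paths.
#' @export
write_subject <- function(ts, matrix_path,
                          sidecar_path = sub("\\.[^.]+$", ".json", matrix_path)) {
  stopifnot(inherits(ts, "roi_ts"))
  utils::write.table(format(ts$data, digits = 17, trim = TRUE, scientific = TRUE),
                     matrix_path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(
    fs = ts$fs, roi_labels = as.list(ts$roi_labels),
    subject_id = ts$subject_id, group = ts$group,
    cognitive_score = if (is.na(ts$cognitive_score)) NULL else ts$cognitive_score,
    artifact_mask = if (is.null(ts$artifact_mask)) NULL else
      lapply(seq_len(nrow(ts$artifact_mask)), function(i)
        list(start_s = ts$artifact_mask$start_s[i],
             end_s = ts$artifact_mask$end_s[i])),
    params = ts$params
  )
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(matrix_path, sidecar_path))
}

#' Load a subject's recording from disk
#'
#' Reads a delimited numeric matrix and its JSON sidecar and validates them
#' against each other. Parsing is locale-independent (dot decimal separator).
#'
#' @param matrix_path Path to the samples x ROIs text matrix (whitespace- or
#'   comma-delimited).
#' @param sidecar_path Path to the JSON sidecar; defaults to `matrix_path`
#'   with a `.json` extension.
#' @return A validated [roi_ts()].
#' @export
load_subject <- function(matrix_path,
                         sidecar_path = sub("\\.[^.]+$", ".json", matrix_path)) {
  if (!file.exists(matrix_path)) rlang::abort(paste("missing file:", matrix_path))
  if (!file.exists(sidecar_path)) rlang::abort(paste("missing file:", sidecar_path))
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  first <- readLines(matrix_path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  mat <- as.matrix(utils::read.table(matrix_path, sep = sep,
                                     colClasses = "numeric"))
  dimnames(mat) <- NULL
  labels <- unlist(meta$roi_labels)
  if (length(labels) != ncol(mat)) {
    rlang::abort(sprintf(
      "sidecar lists %d ROIs but the matrix has %d columns.",
      length(labels), ncol(mat)), class = "eibalance_format_error")
  }
  mask <- NULL
  if (!is.null(meta$artifact_mask) && length(meta$artifact_mask) > 0) {
    mask <- tibble::as_tibble(meta$artifact_mask)
  }
  roi_ts(mat, fs = meta$fs, roi_labels = labels,
         subject_id = meta$subject_id %||% "subject",
         group = meta$group %||% "unknown",
         cognitive_score = meta$cognitive_score %||% NA_real_,
         artifact_mask = mask,
         params = meta$params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a generated cohort to a directory
#'
#' One matrix + sidecar pair per subject and a cohort-level `subjects.csv`.
#'
#' @param cohort Result of [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$signals)) {
    write_subject(cohort$signals[[sid]], file.path(dir, paste0(sid, ".txt")))
  }
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  invisible(dir)
}

#' Load a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list with `subjects` (tibble) and `signals` (named list of
#'   [roi_ts()]), mirroring [gen_cohort()] output.
#' @export
load_cohort <- function(dir) {
  subjects <- readr::read_csv(file.path(dir, "subjects.csv"),
                              show_col_types = FALSE)
  signals <- lapply(subjects$subject_id, function(sid) {
    load_subject(file.path(dir, paste0(sid, ".txt")))
  })
  names(signals) <- subjects$subject_id
  list(subjects = subjects, signals = signals)
}
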