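make_ts <- function(n = 1000, k = 2, fs = 100, seed = 1, ...) {
  roi_ts(withr::with_seed(seed, matrix(rnorm(n * k), ncol = k)), fs = fs, ...)
}

test_that("subject files round-trip to full precision with metadata intact", {
  ts <- make_ts(500, 3, fs = 250, subject_id = "s1", group = "HE",
                cognitive_score = 27.5)
  path <- tempfile(fileext = ".txt")
  write_subject(ts, path)
  back <- load_subject(path)
  expect_equal(back$data, ts$data, tolerance = 1e-15)
  expect_identical(back$roi_labels, ts$roi_labels)
  expect_identical(back$group, "HE")
  expect_equal(back$cognitive_score, 27.5)
  expect_equal(back$fs, 250)
})

test_that("loading validates shape and finiteness", {
  ts <- make_ts(100, 2)
  path <- tempfile(fileext = ".txt")
  write_subject(ts, path)
  # corrupt sidecar: drop one ROI label
  sc <- jsonlite::read_json(sub("\\.txt$", ".json", path), simplifyVector = TRUE)
  sc$roi_labels <- sc$roi_labels[1]
  jsonlite::write_json(sc, sub("\\.txt$", ".json", path), auto_unbox = TRUE)
  expect_error(load_subject(path), class = "eibalance_format_error")

  expect_error(roi_ts(matrix(c(1, NaN, 3, 4), 2), fs = 10),
               class = "eibalance_data_error")
  expect_error(load_subject(tempfile()), "missing file")
})

test_that("artifact-mask excision conserves retained samples and merges overlaps", {
  ts <- make_ts(3000, 2, fs = 10)  # 300 s
  ts$artifact_mask <- tibble::tibble(start_s = c(10, 50, 55), end_s = c(20, 60, 75))
  # brute-force oracle: mark bad samples directly
  bad <- rep(FALSE, 3000)
  for (i in seq_len(3)) {
    lo <- floor(ts$artifact_mask$start_s[i] * 10) + 1
    hi <- ceiling(ts$artifact_mask$end_s[i] * 10)
    bad[lo:hi] <- TRUE
  }
  out <- suppressWarnings(apply_artifact_mask(ts))
  expect_identical(out$data, ts$data[!bad, ])
  expect_equal(nrow(out$data), 3000 - sum(bad))
  expect_equal(length(out$splice_points_s), 2L)  # two gaps closed

  # empty mask is the identity
  ts2 <- make_ts(100, 1)
  expect_identical(apply_artifact_mask(ts2)$data, ts2$data)

  # total removal errors
  ts3 <- make_ts(100, 1, fs = 10)
  ts3$artifact_mask <- tibble::tibble(start_s = 0, end_s = 10)
  expect_error(apply_artifact_mask(ts3), class = "eibalance_empty_signal")
})

test_that("short cleaned recordings trigger the minimum-duration warning", {
  ts <- make_ts(2000, 1, fs = 10)  # 200 s
  ts$artifact_mask <- tibble::tibble(start_s = 0, end_s = 150)
  expect_warning(apply_artifact_mask(ts), "below the 120")
})

test_that("decimation by 4 preserves the passband and suppresses high frequencies", {
  fs <- 1250
  t <- seq(0, 20, by = 1 / fs)[-1]
  slow <- sin(2 * pi * 5 * t)
  fast <- sin(2 * pi * 150 * t)
  ts <- roi_ts(cbind(slow, fast), fs = fs)
  dec <- decimate_by_4(ts)
  expect_equal(dec$fs, 312.5)
  expect_equal(nrow(dec$data), length(t) / 4)
  mid <- seq(1000, nrow(dec$data) - 1000)
  # 5 Hz amplitude preserved within 1%
  expect_lt(abs(max(dec$data[mid, 1]) - 1), 0.01)
  # 150 Hz attenuated by >= 40 dB
  att <- 20 * log10(sd(dec$data[mid, 2]) / sd(fast))
  expect_lt(att, -40)
})

test_that("epoching cuts consecutive non-overlapping 4096-sample epochs at 312.5 Hz", {
  fs <- 312.5
  ts <- roi_ts(matrix(rnorm(300 * fs * 2), ncol = 2), fs = fs)
  ep <- epoch(ts, n_epochs = 10)
  expect_equal(dim(ep), c(4096, 2, 10))
  # concatenating the epochs reproduces the signal prefix bit-exactly
  flat <- do.call(rbind, lapply(1:10, function(e) ep[, , e]))
  expect_identical(flat, unname(ts$data[1:40960, ]))

  # exactly 10 x 4096 samples: no warning
  ts2 <- roi_ts(matrix(rnorm(40960), ncol = 1), fs = fs)
  expect_silent(epoch(ts2, 10))
  # 45000 samples: still 10 epochs, remainder unused
  ts3 <- roi_ts(matrix(rnorm(45000), ncol = 1), fs = fs)
  expect_equal(dim(epoch(ts3, 10))[3], 10)
  # fewer than requested: reduced with a warning
  ts4 <- roi_ts(matrix(rnorm(3 * 4096), ncol = 1), fs = fs)
  expect_warning(ep4 <- epoch(ts4, 10), "only 3")
  expect_equal(dim(ep4)[3], 3)
  # shorter than one epoch: error
  ts5 <- roi_ts(matrix(rnorm(1000), ncol = 1), fs = fs)
  expect_error(epoch(ts5), "too short")
})

test_that("cohorts round-trip through a directory", {
  co <- gen_cohort(demo_cohort_spec(n_per_group = 1, master_seed = 4,
                                    duration_s = 8))
  dir <- tempfile()
  write_cohort(co, dir)
  back <- load_cohort(dir)
  expect_equal(back$subjects$subject_id, co$subjects$subject_id)
  expect_equal(back$signals[["HE_01"]]$data, co$signals[["HE_01"]]$data,
               tolerance = 1e-15)
  expect_equal(back$signals[["AD_01"]]$cognitive_score,
               co$signals[["AD_01"]]$cognitive_score)
})
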