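test_that("the 3xIQR rule flags exactly the extreme values", {
  expect_false(any(iqr_outliers(c(1, 2, 3, 4, 5))$outlier))
  out <- iqr_outliers(c(1, 2, 3, 4, 1000))
  expect_identical(which(out$outlier), 5L)
  expect_warning(iqr_outliers(c(1, 2, 3)), "fewer than 4")

  # randomized sets match a brute-force application of the rule
  for (s in 1:20) {
    v <- withr::with_seed(s, rt(30, df = 2))
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    expected <- v > q[2] + 3 * (q[2] - q[1]) | v < q[1] - 3 * (q[2] - q[1])
    expect_identical(iqr_outliers(v)$outlier, expected)
  }
})

test_that("Kruskal-Wallis matches the rank-sum definition and degenerate cases", {
  expect_equal(kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))$H,
               oracle_kw_h(list(c(1, 2, 3), c(4, 5, 6))))
  expect_equal(kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))$df, 1)

  same <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  for (s in 1:10) {
    g <- withr::with_seed(s, list(rnorm(5), rnorm(4), rnorm(6)))
    expect_equal(kruskal_wallis(g)$H, oracle_kw_h(g), tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(list(a = 1:3)), "2 groups")
})

test_that("Kruskal-Wallis p-values are uniform under the permutation null", {
  vals <- withr::with_seed(21, rnorm(15))
  ps <- withr::with_seed(22, replicate(500, {
    idx <- sample(rep(1:3, each = 5))
    kruskal_wallis(split(vals, idx))$p
  }))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Mann-Whitney tests match exact enumeration and report pooled mean ranks", {
  r <- mann_whitney_pairwise(c(1, 2), list(b = c(3, 4)), ref_label = "a")
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$mean_rank_a, 1.5)
  expect_equal(r$mean_rank_b, 3.5)

  # exact p equals enumeration over all C(n1+n2, n1) labelings
  x <- c(0.3, 1.1, 2.2)
  y <- c(0.9, 1.4, 3.0, 3.3)
  obs <- mann_whitney_pairwise(x, list(g = y))$p
  pool <- c(x, y)
  combos <- combn(7, 3)
  u_stat <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_stat(x, y)
  u_all <- apply(combos, 2, function(i) u_stat(pool[i], pool[-i]))
  # two-sided exact p: distance of U from its mean
  p_exact <- mean(abs(u_all - 6) >= abs(u_obs - 6))
  expect_equal(obs, p_exact)

  same <- mann_whitney_pairwise(c(5, 6, 7), list(b = c(5, 6, 7)))
  expect_equal(same$p, 1)
  expect_equal(same$mean_rank_a, same$mean_rank_b)

  # p decreases monotonically with the shift under a location alternative
  ps <- sapply(c(0.3, 1, 2.5), function(d) {
    withr::with_seed(5, mann_whitney_pairwise(rnorm(30), list(b = rnorm(30) + d))$p)
  })
  expect_true(all(diff(ps) < 0))
})

test_that("two-stage BKY FDR control matches an independent step-up reference", {
  expect_false(any(bky_fdr(rep(1, 20), q = 0.01)))
  expect_true(all(bky_fdr(rep(1e-8, 100), q = 0.01)))
  expect_error(bky_fdr(c(0.5, 1.2)), "0, 1")

  for (s in 1:30) {
    m <- withr::with_seed(s, sample(5:200, 1))
    p <- withr::with_seed(s + 1000, {
      mix <- runif(m)
      hot <- sample(m, ceiling(m / 4))
      mix[hot] <- rbeta(length(hot), 0.2, 8)
      mix
    })
    expect_identical(bky_fdr(p, q = 0.05), bky_reference(p, q = 0.05))
    expect_identical(bky_fdr(p, q = 0.01), bky_reference(p, q = 0.01))
  }
})

test_that("Spearman correlation handles monotone, reversed, and exact small-n cases", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, rev(x))$rho, -1)

  # n = 6 exact p equals full enumeration over 720 rank orders
  xx <- withr::with_seed(8, rnorm(6))
  yy <- withr::with_seed(9, rnorm(6))
  obs <- spearman(xx, yy)
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(all_perms(rank(yy)), function(p) cor(rank(xx), p), numeric(1))
  p_exact <- mean(abs(rhos) >= abs(obs$rho) - 1e-12)
  expect_equal(obs$p, p_exact, tolerance = 1e-10)

  expect_warning(z <- spearman(c(1, 1, 1, 1), c(1, 2, 3, 4)), "zero variance")
  expect_true(is.na(z$rho))
  expect_error(spearman(1:3, 1:4), "equal length")
})

test_that("per-frequency comparisons apply FDR per family and summarize ranges", {
  freqs <- seq(1, 20, by = 0.5)
  mk <- function(group, n, shift_band = NULL, seed = 1) {
    purrr::map_dfr(seq_len(n), function(i) {
      pw <- withr::with_seed(seed * 1000 + i, exp(rnorm(length(freqs), sd = 0.2)))
      if (!is.null(shift_band)) {
        sel <- freqs >= shift_band[1] & freqs <= shift_band[2]
        pw[sel] <- pw[sel] * 3
      }
      tibble::tibble(subject_id = sprintf("%s%02d", group, i), group = group,
                     freq_hz = freqs, power = pw)
    })
  }
  null_tbl <- dplyr::bind_rows(mk("HE", 12, seed = 1), mk("X", 12, seed = 2))
  res0 <- per_frequency_comparison(null_tbl, "HE", q = 0.01)
  expect_equal(nrow(res0$ranges), 0)

  eff_tbl <- dplyr::bind_rows(mk("HE", 12, seed = 3),
                              mk("AD", 12, shift_band = c(4, 7), seed = 4))
  res1 <- per_frequency_comparison(eff_tbl, "HE", q = 0.01)
  sig <- res1$bins[res1$bins$significant, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$freq_hz >= 3.5 & sig$freq_hz <= 7.5))
  expect_true(all(sig$direction == 1))

  # mask cardinality equals direct application of bky_fdr to the p-vector
  expect_equal(sum(res1$bins$significant),
               sum(bky_fdr(res1$bins$p, q = 0.01)))

  bad <- eff_tbl[-5, ]
  expect_error(per_frequency_comparison(bad, "HE"), "common frequency grid")
})
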