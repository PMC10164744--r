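# Internal helpers shared across modules.

# Deterministic child-seed derivation: every stream in a cohort run is a pure
# function of (master_seed, group index, subject index, role). Kept below
# 2^31 - 1 so the result is a valid R integer seed.
derive_seed <- function(master_seed, ...) {
  keys <- c(master_seed, ...)
  h <- 0
  for (k in keys) {
    kk <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.numeric(k)
    h <- (h * 69069 + kk + 1) %% 2147483647
  }
  as.integer(h)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    rlang::abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

# Union of possibly overlapping [start, end) intervals, in seconds.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  tibble::tibble(start_s = c(out_s, ms), end_s = c(out_e, me))
}

# Centered moving mean with MATLAB movmean semantics: for even k the window
# covers k/2 elements before through k/2 - 1 after; windows shrink at edges.
moving_mean <- function(x, k) {
  n <- length(x)
  before <- floor(k / 2)
  after <- ceiling(k / 2) - 1L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - before, 1L)
  hi <- pmin(i + after, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
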