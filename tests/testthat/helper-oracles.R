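# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (matrix-composed DWT, C++ multiplexed FIR).

# Direct causal per-channel FIR convolution via stats::filter.
direct_fir <- function(x, taps) {
  run <- function(v) {
    n <- length(v)
    pad <- c(rep(0, length(taps) - 1), v)
    as.numeric(stats::filter(pad, taps, sides = 1))[length(taps):(length(taps) - 1 + n)]
  }
  if (is.matrix(x)) apply(x, 2, run) else run(x)
}

# Brute-force periodized DWT: per-level double-loop circular convolution,
# recursing on the approximation.
brute_dwt <- function(x, h, levels) {
  g <- (-1)^(seq_along(h) - 1) * rev(h)
  one_level <- function(v) {
    n <- length(v)
    a <- numeric(n / 2)
    d <- numeric(n / 2)
    for (k in seq_len(n / 2)) {
      for (m in seq_along(h)) {
        j <- ((2 * (k - 1) + (m - 1)) %% n) + 1
        a[k] <- a[k] + h[m] * v[j]
        d[k] <- d[k] + g[m] * v[j]
      }
    }
    list(a = a, d = d)
  }
  details <- list()
  a <- x
  for (l in seq_len(levels)) {
    r <- one_level(a)
    a <- r$a
    details[[l]] <- r$d
  }
  # package order: a_L, d_L, d_{L-1}, ..., d_1
  c(a, unlist(rev(details)))
}

# A noisy snippet around a scaled biphasic template, in 16-bit code units.
noisy_snippet <- function(snr = 10, sigma = 130, seed = NULL) {
  tm <- ap_template()
  gen <- function() round(tm * snr * sigma + rnorm(48, 0, sigma))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
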