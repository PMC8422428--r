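two_unit_snippets <- function(n_per = 100, sep = 8, sigma = 15, seed = 19) {
  withr::with_seed(seed, {
    t1 <- ap_template(width = 2) * 150
    t2 <- -ap_template(width = 4) * 150 * 0.8 # opposite polarity, wider
    X <- rbind(
      t(replicate(n_per, t1 + rnorm(48, 0, sigma))),
      t(replicate(n_per, t2 + rnorm(48, 0, sigma)))
    )
    list(X = X, truth = rep(1:2, each = n_per))
  })
}

test_that("re-centering moves the absolute peak to the target index", {
  tm <- ap_template() * 100
  shifted <- c(tm[8:48], tm[1:7]) # peak now at index 10
  out <- refilter_and_center(shifted, center_index = 17L)
  expect_equal(which.max(abs(out)), 17)
  # already-centered snippet keeps its peak position
  out2 <- refilter_and_center(tm, center_index = 17L)
  expect_equal(which.max(abs(out2)), 17)
})

test_that("re-filtering removes mains contamination from snippets", {
  withr::with_seed(20, {
    tm <- ap_template() * 200
    hum <- 80 * sin(2 * pi * 60 * (0:47) / 20000 + runif(1, 0, 2 * pi))
    dirty <- tm + hum
    clean <- refilter_and_center(dirty, center_index = 17L)
    ref <- refilter_and_center(tm, center_index = 17L)
    expect_gte(stats::cor(clean, ref), stats::cor(dirty, tm))
  })
})

test_that("PCA + k-means separates two distinct units (ARI oracle)", {
  skip_if_not_installed("mclust")
  d <- two_unit_snippets()
  su <- sort_spikes(d$X, k = 2, seed = 1)
  ari <- mclust::adjustedRandIndex(su$labels, d$truth)
  expect_gte(ari, 0.95)
  expect_equal(dim(su$centers), c(2, 48))
  # automatic k selection finds the same structure
  su_auto <- sort_spikes(d$X, seed = 1)
  expect_equal(su_auto$k, 2)
})

test_that("sorting is deterministic and order-invariant", {
  d <- two_unit_snippets(n_per = 60)
  a <- sort_spikes(d$X, k = 2, seed = 7)
  b <- sort_spikes(d$X, k = 2, seed = 7)
  expect_identical(a$labels, b$labels)
  # permuted input gives the same partition (canonical labels)
  perm <- withr::with_seed(3, sample(nrow(d$X)))
  c2 <- sort_spikes(d$X[perm, ], k = 2, seed = 7)
  expect_identical(c2$labels, a$labels[perm])
})

test_that("identical snippets collapse to a single effective cluster", {
  X <- matrix(rep(ap_template() * 100, 30), nrow = 30, byrow = TRUE)
  X <- X + matrix(rnorm(30 * 48, 0, 1e-6), 30) # break exact ties only
  su <- sort_spikes(X, seed = 2)
  expect_equal(su$k, 1)
  expect_error(sort_spikes(X, k = 0), "at least 1")
  expect_error(sort_spikes(X[1:3, ], k = 5), "fewer snippets")
})

test_that("tidy and glance summarize sorted units", {
  d <- two_unit_snippets(n_per = 40)
  su <- sort_spikes(d$X, k = 2, seed = 1)
  td <- tidy(su)
  expect_tibble(td)
  expect_named(td, c("snippet", "cluster", "PC1", "PC2"))
  expect_equal(nrow(td), 80)
  gl <- glance(su)
  expect_equal(gl$k, 2)
  expect_equal(gl$n, 80)
})

test_that("band powers are 2-norm normalized and localize a 6 Hz tone", {
  fs <- 250
  t <- (0:(8 * fs - 1)) / fs
  bp <- band_power(sin(2 * pi * 6 * t), fs)
  expect_equal(sum(bp$percent), 100, tolerance = 1e-6)
  expect_gte(bp$percent[bp$band == "theta"], 99)
  expect_error(band_power(sin(t), fs, bands = list(bad = c(0, 10))), "bands")
  expect_error(band_power(rnorm(100), fs), "2 s")
})

test_that("white noise spreads band power proportionally to bandwidth", {
  withr::with_seed(22, {
    fs <- 250
    reps <- replicate(8, band_power(rnorm(60 * fs), fs)$percent)
    pct <- rowMeans(reps)
    widths <- vapply(default_bands(), diff, numeric(1))
    expected <- 100 * widths / sum(widths)
    expect_true(all(abs(pct - expected) / expected < 0.25))
  })
})

test_that("band power of a band-limited LFP concentrates in its band", {
  cfg <- synthesis_config(n_channels = 1L, duration = 4, noise_sigma = 0,
                          lfp_band = c(4, 8), lfp_slow_hz = 0,
                          lfp_exponent = 0, seed = 23L)
  sim <- synthesize_multimodal(cfg, list())
  x <- decimate_lfp(sim$ground_truth$components$lfp[, 1], 10)
  bp <- band_power(x, 2000)
  expect_gte(bp$percent[bp$band == "theta"], 90)
})

test_that("firing rate bins conserve counts and recover the true rate", {
  expect_equal(sum(firing_rate(numeric(0), 0.25, 10)$count), 0)
  tr <- generate_spike_train(50, 30, seed = 24)
  fr <- firing_rate(tr, 0.25, 30)
  expect_equal(sum(fr$count), nrow(tr))
  expect_equal(nrow(fr), 120)
  thinned_rate <- 50 / (1 + 50 * 0.0024)
  se <- stats::sd(fr$rate) / sqrt(nrow(fr))
  expect_lt(abs(mean(fr$rate) - thinned_rate), 3 * se + 0.5)
})

test_that("gated thresholding switches levels inside stimulation pulses", {
  fs <- 20000
  sched <- build_stim_schedule(2, pulse_width = 0.5, gap = 0.5, fs = fs)
  x <- numeric(2 * fs)
  x[10000] <- 50 # inside first pulse (0-0.5 s): below 60 -> missed
  x[25000] <- 50 # outside (1-1.25 s region is inside second pulse? no: pulses at 0-0.5, 1-1.5)
  x[18000] <- 50 # 0.9 s, outside: above 45 -> detected
  ev <- threshold_events_gated(x, thr_in = 60, thr_out = 45, sched, fs = fs)
  expect_true(18000 %in% ev$sample)
  expect_false(10000 %in% ev$sample)
  expect_false(25000 %in% ev$sample) # 1.2 s is inside the second pulse
  # empty schedule behaves as uniform thr_out
  ev2 <- threshold_events_gated(x, 60, 45, NULL, fs = fs)
  expect_equal(sort(ev2$sample), c(10000, 18000, 25000))
  # overlapping schedule intervals are rejected
  bad <- tibble::tibble(on_s = c(0, 0.2), off_s = c(0.5, 0.6),
                        on_sample = c(1L, 4001L), off_sample = c(10001L, 12001L))
  expect_error(threshold_events_gated(x, 60, 45, bad, fs = fs), "overlap")
})

test_that("differential EMG derivation cancels shared signal", {
  withr::with_seed(25, {
    shared <- rnorm(1000, 0, 50)
    a <- shared + rnorm(1000, 0, 5)
    expect_equal(emg_differential(a, a), numeric(1000))
    expect_lt(stats::sd(emg_differential(a, shared)), stats::sd(a))
    expect_error(emg_differential(1:5, 1:6), "equal length")
  })
})
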