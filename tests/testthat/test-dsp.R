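ap_spec <- design_kaiser_fir("high", 300, 41L, 0.1, 20000)
lfp_spec <- design_kaiser_fir("low", 500, 39L, 3, 20000)

test_that("Kaiser FIR designs are symmetric with the stated gain conventions", {
  for (spec in list(ap_spec, lfp_spec)) {
    expect_equal(spec$taps, rev(spec$taps))
  }
  # low-pass DC gain is unity
  expect_lt(abs(sum(lfp_spec$taps) - 1), 1e-6)
  # high-pass gain at Nyquist within 1 dB of unity
  g_nyq <- abs(fir_response(ap_spec, 10000))
  expect_lt(abs(20 * log10(g_nyq)), 1)
  # invalid designs
  expect_error(design_kaiser_fir("high", 300, 40L, 0.1, 20000), "odd")
  expect_error(design_kaiser_fir("low", 15000, 39L, 3, 20000), "fs/2")
})

test_that("designs violating the cycle budget are rejected by name", {
  b <- cycle_budget(20e6, 20000, 32)
  expect_s3_class(design_kaiser_fir("low", 500, 39L, 3, 20000, budget = b),
                  "filter_spec")
  expect_error(design_kaiser_fir("low", 500, 64L, 3, 20000, budget = b),
               "cycle budget")
})

test_that("multiplexed execution equals direct convolution for 1-32 channels", {
  withr::with_seed(99, {
    for (nc in 1:32) {
      n <- 200
      x <- matrix(rnorm(n * nc, 0, 50), n, nc)
      y <- filter_multiplexed(x, ap_spec)
      expect_equal(unclass(y), direct_fir(x, ap_spec$taps),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  })
  # channel isolation: impulse on channel 2 stays on channel 2
  x <- matrix(0, 100, 3)
  x[50, 2] <- 1
  y <- filter_multiplexed(x, lfp_spec)
  expect_equal(max(abs(y[, c(1, 3)])), 0)
  expect_gt(max(abs(y[, 2])), 0)
  # zero input, zero output; channel limit enforced
  expect_equal(max(abs(filter_multiplexed(matrix(0, 50, 4), ap_spec))), 0)
  expect_error(filter_multiplexed(matrix(0, 10, 33), ap_spec), "32")
})

test_that("linear phase: group delay equals (n_taps - 1) / 2 samples", {
  for (spec in list(ap_spec, lfp_spec)) {
    x <- numeric(400)
    x[200] <- 1
    y <- filter_multiplexed(x, spec)
    # symmetric impulse response centered at delay (n-1)/2
    delay <- (spec$n_taps - 1) / 2
    resp <- y[(200):(200 + spec$n_taps - 1)]
    expect_equal(resp, rev(resp), tolerance = 1e-12)
    com <- sum(seq_along(resp) * resp^2) / sum(resp^2)
    expect_equal(com - 1, delay, tolerance = 1e-6)
  }
})

test_that("decimation keeps every factor-th sample and preserves tones", {
  expect_equal(length(decimate_lfp(numeric(600), 10)), 60)
  rec <- sw_recording(matrix(0, 20000, 1), 20000)
  expect_equal(decimate_lfp(rec, 10)$fs, 2000)
  expect_error(decimate_lfp(1:10, 2.5), "positive integer")

  # a 400 Hz tone survives the low-pass + decimation chain within ripple
  t <- (0:39999) / 20000
  x <- 100 * sin(2 * pi * 400 * t)
  y <- decimate_lfp(filter_multiplexed(x, lfp_spec), 10)
  amp <- sqrt(2 * mean(tail(y, 2000)^2)) # RMS-derived amplitude
  gain_db <- 20 * log10(amp / 100)
  expected_db <- 20 * log10(abs(fir_response(lfp_spec, 400)))
  expect_lt(abs(gain_db - expected_db), 0.5)
})

test_that("cycle budget arithmetic matches the multiplexing model", {
  expect_equal(cycle_budget(20e6, 20000, 32)$n_cycles_max, 31.25)
  expect_equal(cycle_budget(20e6, 20000, 1)$n_cycles_max, 1000)
  expect_equal(cycle_budget(20e6, 20000, 64)$n_cycles_max, 15.625)
  expect_error(cycle_budget(20e6, 0, 32), "positive")
})

test_that("symmetric reuse halves the multiplication count", {
  expect_equal(multiplication_count(ap_spec, TRUE), 21)
  expect_equal(multiplication_count(ap_spec, FALSE), 41)
  for (nt in c(5L, 39L, 41L)) {
    s <- design_kaiser_fir("low", 500, nt, 3, 20000)
    expect_lte(multiplication_count(s, TRUE), multiplication_count(s, FALSE))
  }
})

test_that("AP path attenuates low-frequency LFP power by at least 30 dB", {
  cfg <- synthesis_config(n_channels = 1L, duration = 4, noise_sigma = 0,
                          ap_amplitude = c(0, 0), seed = 21L)
  sim <- synthesize_multimodal(cfg, list())
  lfp <- sim$ground_truth$components$lfp[, 1]
  out <- filter_multiplexed(lfp, ap_spec)
  power_below <- function(x, fs, f_hi) {
    sp <- Mod(fft(x))^2
    f <- (0:(length(x) - 1)) * fs / length(x)
    f_eff <- pmin(f, fs - f)
    sum(sp[f_eff > 0 & f_eff < f_hi])
  }
  atten_db <- 10 * log10(power_below(lfp, cfg$fs, 100) /
                           power_below(out, cfg$fs, 100))
  expect_gte(atten_db, 30)
})
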