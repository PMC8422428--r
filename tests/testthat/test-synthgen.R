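test_that("spike train generation follows the dead-time-thinned Poisson model", {
  # degenerate cases
  expect_equal(nrow(generate_spike_train(0, 30, seed = 1)), 0)
  expect_error(generate_spike_train(-1, 30), "non-negative")
  expect_error(generate_spike_train(50, -5), "non-negative")

  # determinism and ordering
  a <- generate_spike_train(50, 10, seed = 42)
  b <- generate_spike_train(50, 10, seed = 42)
  expect_identical(a, b)
  expect_true(all(diff(a$time_s) > 0))
  expect_true(all(diff(a$time_s) >= 0.0024 - 1e-12))
  expect_true(all(a$time_s >= 0 & a$time_s < 10))

  # Monte-Carlo mean against the analytic non-paralyzable dead-time rate
  # lambda / (1 + lambda * tau)
  counts <- vapply(1:200, function(s) {
    nrow(generate_spike_train(50, 30, seed = s))
  }, numeric(1))
  expected <- 50 / (1 + 50 * 0.0024) * 30
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1)
})

test_that("multimodal synthesis decomposes exactly and respects bands", {
  cfg <- synthesis_config(n_channels = 2L, duration = 2, seed = 3L)
  tr <- generate_spike_train(40, 2, channel = 1L, seed = 4L)
  sim <- synthesize_multimodal(cfg, tr)
  gt <- sim$ground_truth

  # sum decomposition is sample-exact
  resid <- sim$recording$samples -
    (gt$components$ap + gt$components$lfp + gt$components$emg +
       gt$components$stim + gt$noise)
  expect_equal(max(abs(resid)), 0)

  # seed determinism
  sim2 <- synthesize_multimodal(cfg, tr)
  expect_identical(sim$recording$samples, sim2$recording$samples)

  # LFP peak-to-peak inside the configured range
  p2p <- diff(range(gt$components$lfp[, 2]))
  expect_gte(p2p, 250)
  expect_lte(p2p, 5000)

  # spectral containment of each nonzero component (periodogram oracle)
  in_band_frac <- function(x, fs, band) {
    sp <- Mod(fft(x))^2
    n <- length(x)
    f <- (0:(n - 1)) * fs / n
    f_eff <- pmin(f, fs - f)
    sum(sp[f_eff >= band[1] & f_eff <= band[2]]) / sum(sp)
  }
  expect_gte(in_band_frac(gt$components$ap[, 1], cfg$fs, c(300, 5000)), 0.95)
  expect_gte(in_band_frac(gt$components$lfp[, 1], cfg$fs, c(1, 500)), 0.95)
})

test_that("silent configuration produces an all-zero recording", {
  cfg <- synthesis_config(n_channels = 2L, duration = 0.5,
                          ap_amplitude = c(0, 0), lfp_amplitude = c(0, 0),
                          emg_amplitude = c(0, 0), noise_sigma = 0, seed = 1L)
  sim <- synthesize_multimodal(cfg, list())
  expect_equal(max(abs(sim$recording$samples)), 0)
})

test_that("EMG channels carry band-limited EMG instead of neural signal", {
  cfg <- synthesis_config(n_channels = 3L, duration = 2, emg_channels = 3L,
                          noise_sigma = 0, seed = 9L)
  sim <- synthesize_multimodal(cfg, list())
  emg <- sim$ground_truth$components$emg
  expect_equal(max(abs(emg[, 1:2])), 0)
  sp <- Mod(fft(emg[, 3]))^2
  f <- (0:(length(emg[, 3]) - 1)) * cfg$fs / length(emg[, 3])
  f_eff <- pmin(f, cfg$fs - f)
  expect_gte(sum(sp[f_eff >= 10 & f_eff <= 300]) / sum(sp), 0.95)
  expect_equal(max(abs(sim$ground_truth$components$lfp[, 3])), 0)
})

test_that("stimulation schedules enumerate pulses correctly", {
  # 500 ms pulses separated by 4.5 s over 20 s: pulses start at 0, 5, 10, 15 s
  s <- build_stim_schedule(20, pulse_width = 0.5, gap = 4.5)
  expect_equal(nrow(s), 4)
  expect_equal(s$on_s, c(0, 5, 10, 15))
  expect_equal(s$off_s, s$on_s + 0.5)

  # trains: 10 x 5 ms pulses at 50 ms spacing, every 5.5 s, over 20 s
  s2 <- build_stim_schedule(20, pulse_width = 0.005, pulses_per_train = 10,
                            intra_period = 0.05, train_period = 5.5)
  expect_equal(nrow(s2), 40)
  expect_true(all(diff(s2$on_s) > 0))

  # empty pattern
  expect_equal(nrow(build_stim_schedule(20)), 0)

  # overlap is rejected
  expect_error(build_stim_schedule(20, pulse_width = 0.6, period = 0.5),
               "smaller than period")
  expect_error(
    build_stim_schedule(20, pulse_width = 0.06, pulses_per_train = 10,
                        intra_period = 0.05, train_period = 5.5),
    "overlap"
  )
})
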