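test_that("periodized DWT matches a brute-force oracle and reconstructs exactly", {
  withr::with_seed(5, {
    for (wav in c("sym4", "db4", "haar")) {
      h <- wavelet_filter(wav)
      x <- rnorm(48, 0, 1000)
      co <- dwt_forward(x, wav, 4L)
      expect_equal(co, brute_dwt(x, h, 4L), tolerance = 1e-10)
      # perfect reconstruction and energy conservation (orthogonality)
      expect_lt(max(abs(dwt_inverse(co, wav, 4L) - x)) / max(abs(x)), 1e-9)
      expect_equal(sum(co^2), sum(x^2), tolerance = 1e-9)
    }
  })
})

test_that("robust sigma estimation is accurate and spike-resistant", {
  expect_equal(estimate_noise_sigma(numeric(20)), 0)
  expect_error(estimate_noise_sigma(numeric(0)), "empty")
  withr::with_seed(6, {
    x <- rnorm(20000, 0, 20)
    expect_lt(abs(estimate_noise_sigma(x) - 20) / 20, 0.05)
    # 50 sparse large spikes barely move the estimate
    spiky <- x
    idx <- sample(20000, 50)
    spiky[idx] <- spiky[idx] + 500
    expect_lt(abs(estimate_noise_sigma(spiky) - estimate_noise_sigma(x)) /
                estimate_noise_sigma(x), 0.10)
  })
})

test_that("adaptive detection respects threshold, dead time and alignment", {
  expect_equal(nrow(detect_aps(numeric(10000))), 0)

  # two crossings 1 ms apart collapse into one event (2.4 ms dead time)
  withr::with_seed(7, {
    x <- rnorm(20000, 0, 10)
    x[5000] <- 200
    x[5020] <- 200 # 1 ms later
    ev <- detect_aps(x)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$sample, 5000)
    expect_equal(ev$timestamp, 4999) # 0-based crossing index
    expect_length(ev$snippet[[1]], 48)
    # snippet holds 16 pre- and 32 post-crossing samples
    expect_equal(ev$snippet[[1]][17], 200)
  })
})

test_that("detection count scales linearly with the true rate", {
  withr::with_seed(8, {
    counts <- vapply(c(10, 50, 100), function(r) {
      tr <- generate_spike_train(r, 10, seed = r)
      x <- rnorm(200000, 0, 20)
      tm <- ap_template()
      for (s in tr$sample) {
        idx <- (s - 16):(s + 31)
        ok <- idx >= 1 & idx <= 200000
        x[idx[ok]] <- x[idx[ok]] + 200 * tm[ok]
      }
      nrow(detect_aps(x))
    }, numeric(1))
    truth <- c(10, 50, 100) / (1 + c(10, 50, 100) * 0.0024) * 10
    expect_true(all(abs(counts - truth) <= 3 * sqrt(truth) + 3))
  })
})

test_that("codec payload honors the fixed bit budget and round-trips", {
  # zero snippet round-trips exactly
  z <- compress_ap(rep(0, 48))
  expect_equal(decompress_ap(z), rep(0, 48))

  # payload is always 184 bits = 23 bytes, giving CR 768/184
  withr::with_seed(9, {
    for (i in 1:20) {
      c1 <- compress_ap(round(rnorm(48, 0, 3000)))
      expect_length(c1$payload, 23)
      expect_equal(c1$bits, 184L)
    }
  })
  expect_equal(48 * 16 / 184, 4.1739, tolerance = 1e-4)

  expect_error(compress_ap(rep(0, 47)), "48 samples")
  bad <- compress_ap(rep(0, 48))
  bad$payload <- bad$payload[1:10]
  expect_error(decompress_ap(bad), "payload length")

  # determinism: identical snippet, identical payload
  s <- noisy_snippet(seed = 10)
  expect_identical(compress_ap(s)$payload, compress_ap(s)$payload)
})

test_that("codec error stays within the frozen float-oracle bound", {
  # An offline float-precision DWT/quantize/reconstruct oracle (same
  # retain-22, 6-bit, power-of-two-scale layout, run on 300 SNR-10 snippets)
  # measured mean range-normalized RMSE 0.0274 (max 0.0427). Bound: +1%.
  withr::with_seed(11, {
    nrmse <- vapply(1:100, function(i) {
      s <- noisy_snippet(snr = 10)
      r <- decompress_ap(compress_ap(s))
      sqrt(mean((r - s)^2)) / diff(range(s))
    }, numeric(1))
    expect_lt(mean(nrmse), 0.0274 + 0.01)
  })
})

test_that("round-trip preserves the peak sample within one position at SNR 8", {
  withr::with_seed(12, {
    for (i in 1:25) {
      s <- noisy_snippet(snr = 8)
      r <- decompress_ap(compress_ap(s))
      expect_lte(abs(which.min(r) - which.min(s)), 1)
    }
  })
})

test_that("round-trip error decreases as the bit budget grows", {
  snips <- withr::with_seed(13, lapply(1:30, function(i) noisy_snippet(snr = 10)))
  errs <- vapply(c(92L, 184L, 368L), function(b) {
    mean(vapply(snips, function(s) {
      r <- decompress_ap(compress_ap(s, budget_bits = b))
      sqrt(mean((r - s)^2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
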