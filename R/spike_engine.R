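#' Adaptive detector configuration
#'
#' The detector thresholds the absolute value of the high-pass (AP-path)
#' signal at `k` times a robust noise sigma, re-estimated over a sliding
#' window. Re-triggering is suppressed for `dead_time` samples (at least one
#' full 48-sample snippet).
#'
#' @param k Threshold multiplier on the noise sigma.
#' @param dead_time Re-trigger suppression, samples (>= 48).
#' @param window Sigma estimation window, samples.
#' @param pre,post Samples kept before / after the threshold crossing
#'   (snippet length is `pre + post`).
#' @return A `detector_config` list.
#' @export
detector_config <- function(k = 4, dead_time = 48L, window = 20000L,
                            pre = 16L, post = 32L) {
  if (k <= 0) abort("k must be positive")
  if (dead_time < pre + post) abort("dead_time must cover a full snippet")
  structure(
    list(k = k, dead_time = as.integer(dead_time),
         window = as.integer(window), pre = as.integer(pre),
         post = as.integer(post), snippet_len = as.integer(pre + post)),
    class = "detector_config"
  )
}

#' Robust noise sigma of a high-pass signal window
#'
#' Median absolute deviation about zero scaled to the Gaussian-consistent
#' sigma: `median(|x|) / 0.6745`. Robust to sparse large spikes riding on the
#' noise.
#'
#' @param x Numeric window of the AP-path signal.
#' @return Estimated sigma (same unit as `x`).
#' @export
estimate_noise_sigma <- function(x) {
  if (length(x) == 0) abort("cannot estimate noise sigma from an empty window")
  median(abs(x)) / 0.6745
}

#' Detect action potentials with an adaptive threshold
#'
#' Per window of `config$window` samples, sigma is estimated with
#' [estimate_noise_sigma()] and the threshold set to `k * sigma`. An event
#' fires where `|x|` first reaches the threshold; the snippet spans `pre`
#' samples before through `post - 1` samples after the crossing, and further
#' crossings within `dead_time` samples are ignored. Events whose snippet
#' would leave the signal are dropped.
#'
#' @param x Numeric vector (one channel of the AP path) or an
#'   [sw_recording()] (all channels detected).
#' @param config A [detector_config()].
#' @param channel Channel index recorded in the output (vector input).
#' @param fs Sampling rate used for `time_s` (vector input; recordings carry
#'   their own).
#' @return Tibble of class `ap_events`: `channel`, `timestamp` (0-based
#'   crossing sample, wrapped at 2^24), `sample` (1-based, unwrapped),
#'   `time_s`, `threshold`, `saturated`, and `snippet` (list of length-48
#'   vectors).
#' @export
detect_aps <- function(x, config = detector_config(), channel = 1L,
                       fs = 20000) {
  if (inherits(x, "sw_recording")) {
    res <- lapply(seq_len(x$n_channels), function(ch) {
      detect_aps(x$samples[, ch], config, channel = ch, fs = x$fs)
    })
    return(dplyr::bind_rows(res))
  }
  stopifnot(inherits(config, "detector_config"))
  x <- as.numeric(x)
  n <- length(x)
  empty <- tibble::tibble(
    channel = integer(), timestamp = numeric(), sample = integer(),
    time_s = numeric(), threshold = numeric(), saturated = logical(),
    snippet = list()
  )
  class(empty) <- c("ap_events", class(empty))
  if (n == 0) return(empty)

  # per-sample threshold from sliding sigma windows
  starts <- seq(1L, n, by = config$window)
  thr <- numeric(n)
  last_sigma <- NA_real_
  for (s in starts) {
    e <- min(n, s + config$window - 1L)
    seg <- x[s:e]
    sigma <- if (e - s + 1L >= 1000L || is.na(last_sigma)) {
      estimate_noise_sigma(seg)
    } else last_sigma
    last_sigma <- sigma
    thr[s:e] <- config$k * sigma
  }

  cand <- which(abs(x) >= thr & thr > 0)
  if (!length(cand)) return(empty)
  events <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= config$dead_time) {
      events <- c(events, i)
      last <- i
    }
  }
  # snippets fully inside the signal only
  ok <- events - config$pre >= 1L & events + config$post - 1L <= n
  events <- events[ok]
  if (!length(events)) return(empty)
  snips <- lapply(events, function(i) x[(i - config$pre):(i + config$post - 1L)])
  out <- tibble::tibble(
    channel = as.integer(channel),
    timestamp = (events - 1) %% 2^24,
    sample = as.integer(events),
    time_s = (events - 1) / fs,
    threshold = thr[events],
    saturated = vapply(snips, function(s) any(abs(s) >= 32767), logical(1)),
    snippet = snips
  )
  class(out) <- c("ap_events", class(out))
  out
}

# ---- wavelet codec ---------------------------------------------------------

codec_layout <- function(budget_bits) {
  # 4-bit scale exponent + 48-bit retention bitmap + 6-bit codes
  n_keep <- min(48L, (budget_bits - 4L - 48L) %/% 6L)
  if (n_keep < 1) abort("bit budget too small for the codec layout")
  list(n_keep = as.integer(n_keep), exp_bits = 4L, map_bits = 48L,
       code_bits = 6L)
}

#' Compress a 48-sample AP snippet with a 4-level DWT
#'
#' The snippet is transformed with the periodized orthogonal 4-level DWT, the
#' largest-magnitude coefficients are retained (as many as the bit budget
#' allows), quantized to 6-bit two's complement against a shared power-of-two
#' scale, and packed with a positional bitmap into a fixed-size payload. The
#' default 184-bit budget yields a compression ratio of 48x16 / 184 = 4.17.
#'
#' @param snippet Numeric vector of exactly 48 samples (16-bit code domain).
#' @param channel,timestamp Carried into the compressed event (timestamp
#'   wraps at 2^24).
#' @param wavelet Wavelet family (see [wavelet_filter()]).
#' @param budget_bits Total payload bit budget.
#' @return A `compressed_ap` with a raw `payload` of
#'   `ceiling(budget_bits / 8)` bytes.
#' @export
compress_ap <- function(snippet, channel = 1L, timestamp = 0,
                        wavelet = "sym4", budget_bits = 184L) {
  if (length(snippet) != 48L) abort("snippet must have exactly 48 samples")
  lay <- codec_layout(budget_bits)
  co <- dwt_forward(as.numeric(snippet), wavelet, 4L)
  keep_idx <- sort(order(-abs(co))[seq_len(lay$n_keep)])
  kept <- co[keep_idx]
  e <- 0L
  while (e < 15L && max(abs(round(kept / 2^e))) > 31) e <- e + 1L
  q <- clamp(round(kept / 2^e), -31, 31)
  bitmap <- integer(48)
  bitmap[keep_idx] <- 1L
  code_bits <- unlist(lapply(q, function(v) {
    int_to_bits(if (v < 0) v + 64L else as.integer(v), 6L)
  }))
  bits <- c(int_to_bits(e, 4L), bitmap, code_bits)
  if (length(bits) > budget_bits) abort("internal codec layout overflow")
  bits <- c(bits, integer(budget_bits - length(bits)))
  structure(
    list(channel = as.integer(channel), timestamp = timestamp %% 2^24,
         payload = pack_bits_msb(bits), bits = as.integer(budget_bits),
         wavelet = wavelet, scale_exp = e),
    class = "compressed_ap"
  )
}

#' @export
print.compressed_ap <- function(x, ...) {
  cat(sprintf("<compressed_ap> ch %d, t %.0f, %d-bit payload (%s), scale 2^%d\n",
              x$channel, x$timestamp, x$bits, x$wavelet, x$scale_exp))
  invisible(x)
}

#' Decompress a wavelet-coded AP snippet
#'
#' Inverse of [compress_ap()]: unpack the exponent, bitmap and 6-bit codes,
#' dequantize, inverse-transform, and round back to the integer code domain.
#'
#' @param compressed A `compressed_ap`.
#' @return Numeric vector of 48 reconstructed samples.
#' @export
decompress_ap <- function(compressed) {
  stopifnot(inherits(compressed, "compressed_ap"))
  budget <- compressed$bits
  lay <- codec_layout(budget)
  if (length(compressed$payload) != ceiling(budget / 8)) {
    abort("payload length does not match the declared bit budget")
  }
  bits <- unpack_bits_msb(compressed$payload, budget)
  e <- bits_to_int(bits[1:4])
  bitmap <- bits[5:52]
  keep_idx <- which(bitmap == 1L)
  if (length(keep_idx) > lay$n_keep) abort("corrupt payload: bitmap overflow")
  co <- numeric(48)
  pos <- 53L
  for (j in seq_along(keep_idx)) {
    v <- bits_to_int(bits[pos:(pos + 5L)])
    if (v >= 32L) v <- v - 64L
    co[keep_idx[j]] <- v * 2^e
    pos <- pos + 6L
  }
  round(dwt_inverse(co, compressed$wavelet, 4L))
}

#' Compress every detected event
#'
#' @param events An `ap_events` tibble from [detect_aps()].
#' @inheritParams compress_ap
#' @return The events tibble with a `compressed` list-column of
#'   `compressed_ap` objects.
#' @export
compress_events <- function(events, wavelet = "sym4", budget_bits = 184L) {
  events$compressed <- purrr::pmap(
    list(events$snippet, events$channel, events$timestamp),
    function(s, ch, ts) compress_ap(s, ch, ts, wavelet, budget_bits)
  )
  events
}
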