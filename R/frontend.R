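#' Analog front-end configuration
#'
#' Emulates a 32-channel recording chip: a tunable analog band-pass (1st-order
#' high-pass, 3rd-order Butterworth low-pass) ahead of a 16-bit ADC spanning
#' -5 to +5 mV. Every channel shares the same filter setting. Cutoffs are
#' validated against the chip's configurable ranges (high-pass 0.1-500 Hz,
#' low-pass 100 Hz - 20 kHz).
#'
#' @param hp_cutoff Analog high-pass cutoff, Hz.
#' @param lp_cutoff Analog low-pass cutoff, Hz. Cutoffs at or above ~fs/2 are
#'   transparent in the sampled emulation (their effect is above Nyquist).
#' @param fs Sampling rate, samples/s.
#' @param full_scale_mV Half-range of the ADC, mV.
#' @param bits ADC resolution.
#' @return A `frontend_config` list; `$lsb_uV` gives microvolts per code.
#' @export
frontend_config <- function(hp_cutoff = 0.25, lp_cutoff = 7500, fs = 20000,
                            full_scale_mV = 5, bits = 16L) {
  if (hp_cutoff < 0.1 || hp_cutoff > 500) {
    abort("high-pass cutoff outside the chip range 0.1-500 Hz")
  }
  if (lp_cutoff < 100 || lp_cutoff > 20000) {
    abort("low-pass cutoff outside the chip range 100 Hz - 20 kHz")
  }
  if (hp_cutoff >= lp_cutoff) abort("high-pass cutoff must be below low-pass cutoff")
  structure(
    list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff, fs = fs,
         full_scale_mV = full_scale_mV, bits = as.integer(bits),
         lsb_uV = 2 * full_scale_mV * 1000 / 2^bits),
    class = "frontend_config"
  )
}

#' Apply the analog band-pass of the front-end
#'
#' Causal cascade of a 1st-order high-pass and a 3rd-order Butterworth
#' low-pass (bilinear-transform discrete equivalents at `fs`), applied per
#' channel.
#'
#' @param x Numeric vector, matrix (samples x channels), or [sw_recording()].
#' @param config A [frontend_config()].
#' @return Filtered object of the same shape.
#' @export
analog_bandpass <- function(x, config = frontend_config()) {
  stopifnot(inherits(config, "frontend_config"))
  if (inherits(x, "sw_recording")) {
    out <- x
    out$samples <- analog_bandpass(x$samples, config)
    return(out)
  }
  hp <- signal::butter(1, config$hp_cutoff / (config$fs / 2), type = "high")
  lp <- if (config$lp_cutoff < 0.499 * config$fs) {
    signal::butter(3, config$lp_cutoff / (config$fs / 2), type = "low")
  } else NULL
  run <- function(v) {
    y <- as.numeric(signal::filter(hp, v))
    if (!is.null(lp)) y <- as.numeric(signal::filter(lp, y))
    y
  }
  if (is.matrix(x)) apply(x, 2, run) else run(as.numeric(x))
}

#' Quantize microvolt samples to ADC codes
#'
#' Mid-tread linear mapping of the +/- full-scale range to two's-complement
#' codes; out-of-range inputs saturate at the code extremes.
#'
#' @inheritParams analog_bandpass
#' @return Integer codes of the same shape (an [sw_recording()] gains
#'   `unit = "code"` and the LSB scale).
#' @export
adc_quantize <- function(x, config = frontend_config()) {
  stopifnot(inherits(config, "frontend_config"))
  if (inherits(x, "sw_recording")) {
    out <- x
    out$samples <- adc_quantize(x$samples, config)
    out$unit <- "code"
    out$scale <- config$lsb_uV
    return(out)
  }
  half <- 2^(config$bits - 1L)
  codes <- round(x / config$lsb_uV)
  out <- clamp(codes, -half, half - 1)
  storage.mode(out) <- "integer"
  out
}

#' Convert ADC codes back to microvolts
#'
#' @inheritParams analog_bandpass
#' @return Numeric microvolt values of the same shape.
#' @export
adc_to_uV <- function(x, config = frontend_config()) {
  if (inherits(x, "sw_recording")) {
    out <- x
    out$samples <- x$samples * config$lsb_uV
    out$unit <- "uV"
    out$scale <- NA_real_
    return(out)
  }
  x * config$lsb_uV
}
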