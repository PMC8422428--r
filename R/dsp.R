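#' Clock-cycle budget of the time-multiplexed datapath
#'
#' A single filter datapath serves all channels between two ADC samples, so
#' the cycles available per sample are `f_clk / (fs * n_channels)`.
#'
#' @param f_clk Datapath clock, Hz.
#' @param fs Sampling rate, samples/s.
#' @param n_channels Channels sharing the datapath.
#' @return A `cycle_budget` list with `n_cycles_max`.
#' @export
cycle_budget <- function(f_clk, fs, n_channels) {
  if (any(c(f_clk, fs, n_channels) <= 0)) {
    abort("f_clk, fs and n_channels must all be positive")
  }
  structure(
    list(f_clk = f_clk, fs = fs, n_channels = as.integer(n_channels),
         n_cycles_max = f_clk / (fs * n_channels)),
    class = "cycle_budget"
  )
}

#' @export
print.cycle_budget <- function(x, ...) {
  cat(sprintf("<cycle_budget> %g cycles/sample (f_clk=%g Hz, fs=%g, %d ch)\n",
              x$n_cycles_max, x$f_clk, x$fs, x$n_channels))
  invisible(x)
}

#' Design a symmetric Kaiser-window FIR filter
#'
#' Windowed-sinc design: the low-pass is a Kaiser-windowed sinc normalized to
#' unit DC gain (-6 dB at the cutoff); the high-pass is the spectral
#' inversion of the complementary low-pass (unit gain at Nyquist), which
#' requires an odd tap count. Taps are exactly symmetric, giving linear phase
#' with group delay `(n_taps - 1) / 2` samples.
#'
#' @param kind `"high"` or `"low"`.
#' @param cutoff Cutoff frequency, Hz (below `fs/2`).
#' @param n_taps Number of coefficients.
#' @param beta Kaiser shape parameter.
#' @param fs Sampling rate, samples/s.
#' @param budget Optional [cycle_budget()]: with symmetric-coefficient reuse a
#'   sample costs `ceiling(n_taps / 2)` multiplications, and designs that do
#'   not fit the budget are rejected.
#' @param quantize_taps If TRUE, round coefficients to 16-bit fixed point
#'   (scale 2^-15), mimicking a fixed-point datapath.
#' @return A `filter_spec` with `taps` and the design parameters.
#' @export
design_kaiser_fir <- function(kind = c("high", "low"), cutoff, n_taps, beta,
                              fs = 20000, budget = NULL,
                              quantize_taps = FALSE) {
  kind <- match.arg(kind)
  if (cutoff <= 0 || cutoff >= fs / 2) abort("cutoff must lie in (0, fs/2)")
  if (n_taps < 3) abort("n_taps must be at least 3")
  if (!is.null(budget)) {
    stopifnot(inherits(budget, "cycle_budget"))
    need <- ceiling(n_taps / 2)
    if (need > budget$n_cycles_max) {
      abort(sprintf(
        "n_taps = %d needs %d multiplications/sample but the cycle budget allows only %.2f cycles/sample",
        n_taps, need, budget$n_cycles_max
      ))
    }
  }
  if (kind == "high" && n_taps %% 2 == 0) {
    abort("high-pass design by spectral inversion requires an odd n_taps")
  }
  m <- (n_taps - 1) / 2
  k <- seq(0, n_taps - 1)
  x <- k - m
  fc <- cutoff / fs # cycles/sample
  sinc <- ifelse(x == 0, 2 * fc, sin(2 * pi * fc * x) / (pi * x))
  w <- as.numeric(signal::kaiser(n_taps, beta))
  lp <- sinc * w
  lp <- lp / sum(lp) # unit DC gain
  taps <- if (kind == "low") lp else {
    hp <- -lp
    hp[m + 1] <- hp[m + 1] + 1 # delta minus low-pass
    hp
  }
  if (quantize_taps) taps <- round(taps * 2^15) / 2^15
  structure(
    list(taps = taps, n_taps = as.integer(n_taps), kind = kind,
         cutoff = cutoff, window = "kaiser", beta = beta, fs = fs,
         quantized = quantize_taps),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s-pass, %d taps, cutoff %g Hz, Kaiser beta=%g, fs=%g\n",
              x$kind, x$n_taps, x$cutoff, x$beta, x$fs))
  invisible(x)
}

#' Frequency response of a FIR filter spec
#'
#' @param spec A `filter_spec`.
#' @param f Frequencies, Hz.
#' @return Complex response at `f`.
#' @export
fir_response <- function(spec, f) {
  k <- seq_along(spec$taps) - 1
  vapply(f, function(fi) {
    sum(spec$taps * exp(-2i * pi * fi / spec$fs * k))
  }, complex(1))
}

#' Run a FIR filter through the time-multiplexed datapath
#'
#' Models the embedded execution: one shared coefficient memory and one
#' delay-line bank holding a state per channel, visited round-robin once per
#' sample period, with symmetric-coefficient multiplication reuse. The output
#' equals direct causal per-channel convolution (zero initial state); the
#' first `n_taps - 1` samples are the settling transient (attribute
#' `settling`).
#'
#' @param x Numeric vector, matrix (samples x channels), or [sw_recording()];
#'   at most 32 channels.
#' @param spec A `filter_spec` designed at the recording's sampling rate.
#' @return Filtered object of the same shape.
#' @export
filter_multiplexed <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(x, "sw_recording")) {
    if (x$fs != spec$fs) abort("filter spec designed for a different fs")
    out <- x
    out$samples <- filter_multiplexed(x$samples, spec)
    out$unit <- x$unit
    return(out)
  }
  vec <- !is.matrix(x)
  m <- if (vec) matrix(as.numeric(x), ncol = 1) else x
  if (ncol(m) > 32) abort("the multiplexed datapath serves at most 32 channels")
  storage.mode(m) <- "double"
  y <- mux_fir(m, spec$taps)
  attr(y, "settling") <- spec$n_taps - 1L
  if (vec) {
    y <- drop(y)
    attr(y, "settling") <- spec$n_taps - 1L
  }
  y
}

#' Decimate a low-pass-filtered signal
#'
#' Keeps every `factor`-th sample starting at the first one. The input must
#' already be band-limited below the post-decimation Nyquist.
#'
#' @param x Numeric vector, matrix, or [sw_recording()].
#' @param factor Positive integer decimation factor.
#' @return Decimated object; a recording's `fs` is divided by `factor`.
#' @export
decimate_lfp <- function(x, factor = 10L) {
  if (length(factor) != 1 || factor != round(factor) || factor < 1) {
    abort("factor must be a positive integer")
  }
  factor <- as.integer(factor)
  if (inherits(x, "sw_recording")) {
    return(sw_recording(decimate_lfp(x$samples, factor), x$fs / factor,
                        unit = x$unit, scale = x$scale))
  }
  if (is.matrix(x)) {
    x[seq(1L, nrow(x), by = factor), , drop = FALSE]
  } else {
    x[seq(1L, length(x), by = factor)]
  }
}

#' Multiplications per sample of a FIR execution
#'
#' With symmetric coefficients the datapath adds the two samples sharing a
#' coefficient before the single multiplication, so a sample costs
#' `ceiling(n_taps / 2)` multiplications instead of `n_taps`.
#'
#' @param spec A `filter_spec`.
#' @param symmetric_reuse Reuse multiplications across the symmetric halves.
#' @return Multiplications per output sample.
#' @export
multiplication_count <- function(spec, symmetric_reuse = TRUE) {
  stopifnot(inherits(spec, "filter_spec"))
  if (symmetric_reuse) ceiling(spec$n_taps / 2) else spec$n_taps
}
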