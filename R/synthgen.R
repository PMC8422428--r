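#' Multichannel recording container
#'
#' A light container for time-aligned multichannel samples: a numeric or
#' integer matrix (rows = samples, columns = channels) plus sampling-rate and
#' unit metadata.
#'
#' @param samples Matrix, samples by channels.
#' @param fs Sampling rate, samples/s.
#' @param unit `"uV"` for analog microvolts or `"code"` for ADC codes.
#' @param scale Microvolts per LSB when `unit == "code"` (NA otherwise).
#' @return An object of class `sw_recording`.
#' @export
sw_recording <- function(samples, fs, unit = c("uV", "code"), scale = NA_real_) {
  unit <- match.arg(unit)
  samples <- as.matrix(samples)
  structure(
    list(samples = samples, fs = fs, unit = unit, scale = scale,
         n_channels = ncol(samples), duration = nrow(samples) / fs),
    class = "sw_recording"
  )
}

#' @export
print.sw_recording <- function(x, ...) {
  cat(sprintf(
    "<sw_recording> %d channel(s), %d samples @ %g samples/s (%.3f s), unit=%s\n",
    x$n_channels, nrow(x$samples), x$fs, x$duration, x$unit
  ))
  invisible(x)
}

#' Synthesis configuration for multimodal mixtures
#'
#' Amplitude ranges and band limits default to the typical extracellular
#' modalities: APs 300-5000 Hz at 50-500 uV (peak), LFP 1-500 Hz at
#' 250-5000 uV (peak-to-peak), EMG 10-300 Hz at 50-500 uV (peak-to-peak).
#'
#' @param n_channels Number of channels (at most 32).
#' @param duration Recording length in seconds.
#' @param fs Sampling rate, samples/s.
#' @param ap_amplitude,lfp_amplitude,emg_amplitude Two-element uV ranges.
#' @param ap_band,lfp_band,emg_band Two-element Hz ranges inside (0, fs/2).
#' @param noise_sigma Additive Gaussian noise sigma, uV.
#' @param lfp_exponent Spectral slope of the LFP surrogate: power falls as
#'   `1/f^exponent` across the band (2 mimics the low-frequency-dominated
#'   cortical LFP; 0 gives flat band noise).
#' @param lfp_slow_hz Frequency of the slow cortical oscillation added to the
#'   LFP component (set 0 to disable).
#' @param emg_channels Channel indices that carry EMG instead of AP+LFP.
#' @param stim_schedule Optional stimulation schedule (see
#'   [build_stim_schedule()]).
#' @param stim_artifact_uV Amplitude of the step transient injected at each
#'   stimulation edge (0 disables artifacts).
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @return A `synthesis_config` list.
#' @export
synthesis_config <- function(n_channels = 4L, duration = 5, fs = 20000,
                             ap_amplitude = c(50, 500),
                             lfp_amplitude = c(250, 5000),
                             emg_amplitude = c(50, 500),
                             ap_band = c(300, 5000),
                             lfp_band = c(1, 500),
                             emg_band = c(10, 300),
                             noise_sigma = 20,
                             lfp_exponent = 2,
                             lfp_slow_hz = 1,
                             emg_channels = integer(0),
                             stim_schedule = NULL,
                             stim_artifact_uV = 0,
                             seed = 1L) {
  if (n_channels < 1 || n_channels > 32) abort("n_channels must be in 1..32")
  if (duration <= 0) abort("duration must be positive")
  for (rng in list(ap_amplitude, lfp_amplitude, emg_amplitude)) {
    if (any(rng < 0)) abort("amplitude ranges must be non-negative")
  }
  for (band in list(ap_band, lfp_band, emg_band)) {
    if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2]) {
      abort("band limits must satisfy 0 < lo < hi < fs/2")
    }
  }
  if (any(emg_channels < 1 | emg_channels > n_channels)) {
    abort("emg_channels outside 1..n_channels")
  }
  structure(as.list(environment()), class = "synthesis_config")
}

#' Generate a refractory-thinned Poisson spike train
#'
#' Events are drawn as a homogeneous Poisson process of intensity `rate` and
#' thinned sequentially so that consecutive accepted events are at least
#' `refractory` seconds apart (non-paralyzable dead time). The expected
#' output rate is `rate / (1 + rate * refractory)`.
#'
#' @param rate Mean event rate before thinning, events/s.
#' @param duration Train length, s.
#' @param refractory Dead time, s; must cover a full snippet (2.4 ms default).
#' @param fs Sampling rate used to express event times in samples.
#' @param channel Channel index carried along in the output.
#' @param template_id Waveform template index carried along in the output.
#' @param seed Integer seed (NULL leaves the RNG state alone).
#' @return Tibble with `channel`, `template_id`, `time_s`, and 1-based
#'   `sample` columns, strictly increasing in time.
#' @export
generate_spike_train <- function(rate, duration, refractory = 0.0024,
                                 fs = 20000, channel = 1L, template_id = 1L,
                                 seed = NULL) {
  if (rate < 0) abort("rate must be non-negative")
  if (duration < 0) abort("duration must be non-negative")
  if (refractory < 0) abort("refractory must be non-negative")
  times <- with_seed(seed, {
    if (rate == 0 || duration == 0) {
      numeric(0)
    } else {
      # draw gaps in blocks until the horizon is passed
      t_all <- numeric(0)
      t_last <- 0
      while (t_last < duration) {
        gaps <- rexp(max(64L, ceiling(rate * duration / 2)), rate)
        t_all <- c(t_all, t_last + cumsum(gaps))
        t_last <- t_all[length(t_all)]
      }
      t_all <- t_all[t_all < duration]
      # sequential dead-time thinning
      keep <- logical(length(t_all))
      last <- -Inf
      for (i in seq_along(t_all)) {
        if (t_all[i] - last >= refractory) {
          keep[i] <- TRUE
          last <- t_all[i]
        }
      }
      t_all[keep]
    }
  })
  tibble::tibble(
    channel = as.integer(channel),
    template_id = as.integer(template_id),
    time_s = times,
    sample = as.integer(floor(times * fs)) + 1L
  )
}

#' Biphasic action-potential template
#'
#' A 48-sample biphasic waveform (sharp negative deflection followed by a
#' slower positive rebound), zero-mean, band-pass shaped to the AP band so
#' that the placed spike component is spectrally contained, and normalized to
#' a negative peak of -1 at `peak_index`.
#'
#' @param n_samples Template length (48 = 2.4 ms at 20 ksps).
#' @param peak_index Index of the negative peak (1-based).
#' @param width Gaussian width of the negative phase, samples.
#' @param fs Sampling rate, samples/s.
#' @param band Band used to shape the template, Hz.
#' @return Numeric template of length `n_samples`.
#' @export
ap_template <- function(n_samples = 48L, peak_index = 17L, width = 2,
                        fs = 20000, band = c(300, 5000)) {
  t <- seq_len(n_samples)
  w <- -exp(-((t - peak_index) / width)^2) +
    0.55 * exp(-((t - peak_index - 5) / (1.75 * width))^2)
  # shape into the AP band with a zero-phase biquad so the component
  # passes the spectral-containment check
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  pad <- rev(w)
  wf <- signal::filtfilt(bp, c(pad, w, pad))[(n_samples + 1):(2 * n_samples)]
  wf <- wf - mean(wf)
  wf / abs(min(wf))
}

#' Synthesize a ground-truthed multimodal recording
#'
#' Builds per-channel modality components and emits their sum plus Gaussian
#' noise. AP components place amplitude-scaled templates so the negative peak
#' lands on each train event's `sample`; LFP and EMG components are
#' band-limited Gaussian processes (frequency-domain synthesis) rescaled to a
#' peak-to-peak amplitude drawn from the configured range, the LFP optionally
#' carrying a slow ~1 Hz oscillation. The returned ground truth stores every
#' component and the noise so that `mixture == ap + lfp + emg + stim + noise`
#' holds sample-exactly.
#'
#' @param config A [synthesis_config()].
#' @param trains List of spike-train tibbles from [generate_spike_train()]
#'   (or a single tibble); channels must exist and must not be EMG channels.
#' @return List with elements `recording` (an [sw_recording()] in uV) and
#'   `ground_truth` (trains with drawn amplitudes, component matrices, noise,
#'   templates, stimulation schedule).
#' @export
synthesize_multimodal <- function(config, trains = list()) {
  stopifnot(inherits(config, "synthesis_config"))
  if (inherits(trains, "data.frame")) trains <- list(trains)
  n <- round(config$duration * config$fs)
  nc <- config$n_channels
  trains_tbl <- if (length(trains)) dplyr::bind_rows(trains) else
    tibble::tibble(channel = integer(), template_id = integer(),
                   time_s = numeric(), sample = integer())
  if (nrow(trains_tbl) && any(!trains_tbl$channel %in% seq_len(nc))) {
    abort("spike trains reference channels outside the configuration")
  }
  tmpl_len <- 48L
  peak_index <- 17L
  if (nrow(trains_tbl)) {
    gaps <- trains_tbl |>
      dplyr::group_by(.data$channel) |>
      dplyr::summarise(min_gap = if (dplyr::n() > 1) min(diff(sort(.data$time_s))) else Inf)
    if (any(gaps$min_gap < tmpl_len / config$fs)) {
      abort("template longer than the inter-event gap (refractory violated)")
    }
  }

  out <- with_seed(config$seed, {
    ap <- matrix(0, n, nc)
    lfp <- matrix(0, n, nc)
    emg <- matrix(0, n, nc)
    stim <- matrix(0, n, nc)

    templates <- list()
    amp_tbl <- NULL
    if (nrow(trains_tbl)) {
      ids <- sort(unique(trains_tbl$template_id))
      for (id in ids) {
        # small deterministic shape variation across template ids
        templates[[as.character(id)]] <-
          ap_template(tmpl_len, peak_index, width = 2 + 0.6 * (id - 1),
                      fs = config$fs, band = config$ap_band)
      }
      combos <- dplyr::distinct(trains_tbl, .data$channel, .data$template_id)
      combos$amplitude_uV <- runif(nrow(combos), config$ap_amplitude[1],
                                   config$ap_amplitude[2])
      amp_tbl <- combos
      ev <- dplyr::left_join(trains_tbl, combos, by = c("channel", "template_id"))
      for (i in seq_len(nrow(ev))) {
        pk <- ev$sample[i]
        idx <- (pk - peak_index + 1L):(pk - peak_index + tmpl_len)
        ok <- idx >= 1L & idx <= n
        if (!any(ok)) next
        tm <- templates[[as.character(ev$template_id[i])]]
        ch <- ev$channel[i]
        ap[idx[ok], ch] <- ap[idx[ok], ch] + ev$amplitude_uV[i] * tm[ok]
      }
    }

    for (ch in seq_len(nc)) {
      if (ch %in% config$emg_channels) {
        if (diff(range(config$emg_amplitude)) >= 0 && max(config$emg_amplitude) > 0) {
          e <- band_noise(n, config$fs, config$emg_band)
          target <- runif(1, config$emg_amplitude[1], config$emg_amplitude[2])
          if (diff(range(e)) > 0) emg[, ch] <- e * target / diff(range(e))
        }
      } else if (max(config$lfp_amplitude) > 0) {
        l <- band_noise(n, config$fs, config$lfp_band, config$lfp_exponent)
        if (config$lfp_slow_hz > 0) {
          tt <- (seq_len(n) - 1) / config$fs
          l <- l + 1.5 * stats::sd(l) *
            sin(2 * pi * config$lfp_slow_hz * tt + runif(1, 0, 2 * pi))
        }
        target <- runif(1, config$lfp_amplitude[1], config$lfp_amplitude[2])
        if (diff(range(l)) > 0) lfp[, ch] <- l * target / diff(range(l))
      }
    }

    if (!is.null(config$stim_schedule) && config$stim_artifact_uV > 0 &&
        nrow(config$stim_schedule)) {
      kern <- config$stim_artifact_uV * exp(-(0:39) / 8)
      for (i in seq_len(nrow(config$stim_schedule))) {
        for (edge in c(config$stim_schedule$on_sample[i],
                       config$stim_schedule$off_sample[i])) {
          idx <- edge:(edge + 39L)
          ok <- idx >= 1L & idx <= n
          sgn <- if (edge == config$stim_schedule$on_sample[i]) 1 else -1
          stim[idx[ok], ] <- stim[idx[ok], ] + sgn * kern[ok]
        }
      }
    }

    noise <- matrix(rnorm(n * nc, 0, config$noise_sigma), n, nc)
    list(ap = ap, lfp = lfp, emg = emg, stim = stim, noise = noise,
         templates = templates, amplitudes = amp_tbl)
  })

  mixture <- out$ap + out$lfp + out$emg + out$stim + out$noise
  list(
    recording = sw_recording(mixture, config$fs, unit = "uV"),
    ground_truth = list(
      trains = trains_tbl,
      amplitudes = out$amplitudes,
      components = list(ap = out$ap, lfp = out$lfp, emg = out$emg,
                        stim = out$stim),
      noise = out$noise,
      templates = out$templates,
      peak_index = peak_index,
      stim_schedule = config$stim_schedule,
      config = config
    )
  )
}

#' Build a stimulation pulse schedule
#'
#' Pulses (optionally grouped in trains) are laid out from time 0; a pulse is
#' kept only if it ends within the span. Intervals are returned in samples,
#' half-open `[on, off)`, 1-based.
#'
#' @param duration Span covered by the schedule, s.
#' @param pulse_width Pulse width, s (NULL gives an empty schedule).
#' @param gap Off time between single pulses, s (period = width + gap).
#' @param period Alternative to `gap`: full single-pulse period, s.
#' @param pulses_per_train Pulses per train (1 = simple periodic pulses).
#' @param intra_period Period between pulse onsets inside a train, s.
#' @param train_period Period between train onsets, s (defaults to `period`).
#' @param fs Sampling rate, samples/s.
#' @return Tibble with `on_s`, `off_s`, `on_sample`, `off_sample`, sorted and
#'   non-overlapping.
#' @export
build_stim_schedule <- function(duration, pulse_width = NULL, gap = NULL,
                                period = NULL, pulses_per_train = 1L,
                                intra_period = NULL, train_period = NULL,
                                fs = 20000) {
  empty <- tibble::tibble(on_s = numeric(), off_s = numeric(),
                          on_sample = integer(), off_sample = integer())
  if (is.null(pulse_width) || duration <= 0) return(empty)
  if (pulse_width <= 0) abort("pulse_width must be positive")
  if (is.null(period)) {
    if (is.null(gap) && pulses_per_train == 1L) abort("give gap or period")
    period <- if (!is.null(gap)) pulse_width + gap else NULL
  }
  if (pulses_per_train > 1L) {
    if (is.null(intra_period)) abort("intra_period required for pulse trains")
    if (pulse_width >= intra_period) abort("pulses inside a train overlap")
    if (is.null(train_period)) train_period <- period
    if (is.null(train_period)) abort("train_period required for pulse trains")
    train_len <- (pulses_per_train - 1) * intra_period + pulse_width
    if (train_len > train_period) abort("trains overlap")
    starts <- seq(0, duration, by = train_period)
    on <- as.vector(outer((0:(pulses_per_train - 1)) * intra_period, starts, "+"))
  } else {
    if (pulse_width >= period) abort("pulse_width must be smaller than period")
    on <- seq(0, duration, by = period)
  }
  off <- on + pulse_width
  keep <- off <= duration
  on <- sort(on[keep]); off <- sort(off[keep])
  if (length(on) > 1 && any(on[-1] < off[-length(off)])) {
    abort("schedule contains overlapping pulses")
  }
  tibble::tibble(
    on_s = on, off_s = off,
    on_sample = as.integer(round(on * fs)) + 1L,
    off_sample = as.integer(round(off * fs)) + 1L
  )
}

#' Membership mask for a stimulation schedule
#'
#' @param schedule Tibble from [build_stim_schedule()].
#' @param n_samples Length of the mask.
#' @return Logical vector: TRUE inside a pulse.
#' @export
stim_mask <- function(schedule, n_samples) {
  m <- logical(n_samples)
  if (is.null(schedule) || !nrow(schedule)) return(m)
  if (nrow(schedule) > 1) {
    o <- order(schedule$on_sample)
    s <- schedule[o, ]
    if (any(s$on_sample[-1] < s$off_sample[-nrow(s)])) {
      abort("schedule contains overlapping intervals")
    }
  }
  for (i in seq_len(nrow(schedule))) {
    lo <- max(1L, schedule$on_sample[i])
    hi <- min(n_samples, schedule$off_sample[i] - 1L)
    if (lo <= hi) m[lo:hi] <- TRUE
  }
  m
}
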