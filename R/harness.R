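#' Session configuration for the full pipeline
#'
#' One config plus a seed fully determines a run of
#' synthesis -> front-end -> dual-path separation -> detection/compression ->
#' packetization -> base-station reconstruction.
#'
#' @param n_channels Channels (<= 32).
#' @param duration Session length, s.
#' @param fs Sampling rate, samples/s.
#' @param firing_rate Per-channel spike rate, AP/s.
#' @param emg_channels Channels carrying EMG instead of AP+LFP.
#' @param seed Integer seed.
#' @param synth Extra arguments passed to [synthesis_config()].
#' @param frontend A [frontend_config()].
#' @param detector A [detector_config()].
#' @param ap_filter,lfp_filter FIR specs for the two digital paths (defaults:
#'   300 Hz high-pass, 41 taps, Kaiser beta 0.1; 500 Hz low-pass, 39 taps,
#'   Kaiser beta 3).
#' @param decimation LFP/EMG decimation factor.
#' @param wavelet Codec wavelet family.
#' @param keep_signals Keep intermediate signal matrices in the result
#'   (memory-heavy for long sessions).
#' @return A `session_config` list.
#' @export
session_config <- function(n_channels = 4L, duration = 5, fs = 20000,
                           firing_rate = 50, emg_channels = integer(0),
                           seed = 1L, synth = list(),
                           frontend = frontend_config(fs = fs),
                           detector = detector_config(window = fs),
                           ap_filter = NULL, lfp_filter = NULL,
                           decimation = 10L, wavelet = "sym4",
                           keep_signals = FALSE) {
  if (is.null(ap_filter)) {
    ap_filter <- design_kaiser_fir("high", 300, 41L, 0.1, fs)
  }
  if (is.null(lfp_filter)) {
    lfp_filter <- design_kaiser_fir("low", 500, 39L, 3, fs)
  }
  structure(as.list(environment()), class = "session_config")
}

#' Run a full synthetic session through the pipeline
#'
#' Executes synthesis, analog front-end emulation, 16-bit quantization,
#' dual-path multiplexed FIR separation, decimation, adaptive detection,
#' wavelet compression, packetization, and base-station reconstruction, then
#' reports detected counts, the recording-level data reduction ratio
#' computed from the session's own AP count, data rates, the link-budget
#' check, and detection precision/recall against ground truth (events
#' matched within `match_tol_s`).
#'
#' @param config A [session_config()].
#' @param match_tol_s Ground-truth matching tolerance, s.
#' @return A `session_report` list; `$packets` holds the raw packet stream,
#'   `$reconstructed` the decoded session, `$report` the summary tibble-ready
#'   list.
#' @export
run_session <- function(config = session_config(), match_tol_s = 0.001) {
  stopifnot(inherits(config, "session_config"))
  fs <- config$fs
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- synthesis ---
  sim <- stage("synthgen", {
    sc <- do.call(synthesis_config, utils::modifyList(list(
      n_channels = config$n_channels, duration = config$duration, fs = fs,
      emg_channels = config$emg_channels, seed = config$seed
    ), config$synth))
    neural <- setdiff(seq_len(config$n_channels), config$emg_channels)
    trains <- lapply(seq_along(neural), function(i) {
      generate_spike_train(config$firing_rate, config$duration,
                           fs = fs, channel = neural[i],
                           seed = config$seed + 1000L + neural[i])
    })
    synthesize_multimodal(sc, trains)
  })

  # --- analog front-end + ADC ---
  codes <- stage("frontend", {
    adc_quantize(analog_bandpass(sim$recording, config$frontend),
                 config$frontend)
  })
  uv <- adc_to_uV(codes, config$frontend)

  # --- dual-path separation ---
  ap_path <- stage("dsp_core", filter_multiplexed(uv, config$ap_filter))
  lfp_path <- stage("dsp_core", {
    lp <- filter_multiplexed(uv, config$lfp_filter)
    decimate_lfp(lp, config$decimation)
  })
  lfp_codes <- adc_quantize(lfp_path, config$frontend)

  # --- detection + compression ---
  events <- stage("spike_engine", detect_aps(ap_path, config$detector))
  events$snippet_codes <- lapply(events$snippet, function(s) {
    as.integer(clamp(round(s / config$frontend$lsb_uV), -32768, 32767))
  })
  compressed <- stage("spike_engine", {
    purrr::pmap(list(events$snippet_codes, events$channel, events$timestamp),
                function(s, ch, ts) compress_ap(s, ch, ts, config$wavelet))
  })

  # --- telemetry ---
  packets <- stage("telemetry", {
    # emit AP packets in detection-time order, as the platform would
    ord <- order(vapply(compressed, `[[`, numeric(1), "timestamp"))
    ap_raw <- if (length(compressed)) {
      do.call(c, lapply(compressed[ord], pack_ap))
    } else raw(0)
    c(ap_raw, pack_lfp_stream(lfp_codes$samples))
  })

  # --- base station ---
  recon <- stage("basestation", {
    decoded <- depacketize(packets, wavelet = config$wavelet)
    reconstruct_session(decoded, config$duration, config$n_channels, fs,
                        fs / config$decimation,
                        pre = config$detector$pre, post = config$detector$post)
  })

  # --- accounting ---
  n_aps <- nrow(events)
  cr <- 48 * 16 / 184
  cdrr <- compute_recording_cdrr(fs, config$duration, config$n_channels,
                                 max(n_aps, 0), 48, cr,
                                 fs / config$decimation)
  raw_rate <- raw_data_rate(config$n_channels, fs, 16)
  n_pkts <- length(packets) / 28
  reduced_rate <- length(packets) * 8 / config$duration
  budget <- check_link_budget(reduced_rate)

  pr <- detection_scores(events, sim$ground_truth, fs, match_tol_s)

  report <- list(
    schema_version = "1.0",
    seed = config$seed,
    n_channels = config$n_channels,
    duration_s = config$duration,
    fs = fs,
    n_aps_detected = n_aps,
    n_packets = n_pkts,
    cdrr = cdrr,
    compression_ratio = cr,
    raw_rate_bps = raw_rate,
    reduced_rate_bps = reduced_rate,
    link_budget_pass = budget$pass,
    precision = pr$precision,
    recall = pr$recall,
    dropped_events = recon$dropped
  )
  out <- list(report = report, events = events, packets = packets,
              reconstructed = recon, ground_truth = sim$ground_truth,
              config = config)
  if (config$keep_signals) {
    out$signals <- list(mixture = sim$recording, codes = codes,
                        ap_path = ap_path, lfp_path = lfp_codes)
  }
  structure(out, class = "session_report")
}

detection_scores <- function(events, ground_truth, fs, tol_s) {
  gt <- ground_truth$trains
  if (!nrow(gt) || !nrow(events)) {
    return(list(precision = if (nrow(events)) 0 else NA_real_,
                recall = if (nrow(gt)) 0 else NA_real_))
  }
  tol <- tol_s * fs
  tp <- 0L
  for (ch in unique(gt$channel)) {
    truth <- gt$sample[gt$channel == ch]
    det <- sort(events$sample[events$channel == ch])
    used <- logical(length(det))
    for (t in truth) {
      j <- which(!used & abs(det - t) <= tol)
      if (length(j)) {
        used[j[1]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  list(precision = tp / nrow(events), recall = tp / nrow(gt))
}

#' @export
print.session_report <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("<session_report> %d ch x %.1f s @ %g ksps\n",
           "  APs detected: %d   CDRR: %.2f\n",
           "  raw: %.2f Mbps -> reduced: %.2f Mbps (link budget: %s)\n",
           "  precision: %s  recall: %s  dropped: %d\n"),
    r$n_channels, r$duration_s, r$fs / 1000, r$n_aps_detected, r$cdrr,
    r$raw_rate_bps / 1e6, r$reduced_rate_bps / 1e6,
    if (r$link_budget_pass) "pass" else "FAIL",
    format(round(r$precision, 3)), format(round(r$recall, 3)),
    r$dropped_events
  ))
  invisible(x)
}

#' One-row summary of a session report
#'
#' @param x A `session_report`.
#' @param ... Unused.
#' @return Tibble with the session-level metrics.
#' @export
glance.session_report <- function(x, ...) {
  r <- x$report
  tibble::as_tibble(r[c("n_channels", "duration_s", "n_aps_detected",
                        "cdrr", "raw_rate_bps", "reduced_rate_bps",
                        "link_budget_pass", "precision", "recall")])
}

#' Write a session report to JSON
#'
#' @param session A `session_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_session_report <- function(session, path) {
  jsonlite::write_json(session$report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deterministic miniature sessions for tests and examples
#'
#' * `"two_units"`: 2 channels, 4 s, two spike-train templates on channel 1.
#' * `"silent"`: 2 channels, 2 s, no spikes.
#' * `"emg_mix"`: 3 channels, 3 s, channel 3 flagged EMG.
#'
#' @param name Fixture name.
#' @param seed Integer seed.
#' @return List with `config`, `trains`, `recording`, `ground_truth`.
#' @export
make_fixture <- function(name = c("two_units", "silent", "emg_mix"),
                         seed = 1L) {
  if (!is.character(name) || !name[1] %in% c("two_units", "silent", "emg_mix")) {
    abort(sprintf(
      "unknown fixture '%s'; available: two_units, silent, emg_mix",
      as.character(name)[1]
    ))
  }
  name <- match.arg(name)
  if (name == "two_units") {
    cfg <- synthesis_config(n_channels = 2L, duration = 4, seed = seed,
                            ap_amplitude = c(200, 250))
    trains <- list(
      generate_spike_train(20, 4, channel = 1L, template_id = 1L,
                           seed = seed + 1L),
      generate_spike_train(20, 4, channel = 1L, template_id = 2L,
                           refractory = 0.01, seed = seed + 2L),
      generate_spike_train(30, 4, channel = 2L, template_id = 1L,
                           seed = seed + 3L)
    )
    # avoid template overlap on channel 1: merge and re-thin sequentially
    merged <- dplyr::arrange(dplyr::bind_rows(trains[1:2]), .data$time_s)
    keep <- logical(nrow(merged))
    last <- -Inf
    for (i in seq_len(nrow(merged))) {
      if (merged$time_s[i] - last >= 0.0025) {
        keep[i] <- TRUE
        last <- merged$time_s[i]
      }
    }
    trains <- list(merged[keep, ], trains[[3]])
  } else if (name == "silent") {
    cfg <- synthesis_config(n_channels = 2L, duration = 2, seed = seed)
    trains <- list()
  } else {
    cfg <- synthesis_config(n_channels = 3L, duration = 3, seed = seed,
                            emg_channels = 3L)
    trains <- list(
      generate_spike_train(30, 3, channel = 1L, seed = seed + 1L),
      generate_spike_train(30, 3, channel = 2L, seed = seed + 2L)
    )
  }
  sim <- synthesize_multimodal(cfg, trains)
  list(config = cfg, trains = trains, recording = sim$recording,
       ground_truth = sim$ground_truth)
}
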