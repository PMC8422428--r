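#' Split a packet stream into AP events and LFP/EMG samples
#'
#' Records are partitioned by their type code in stream order. AP timestamps
#' wrap at 2^24 samples (~839 s at 20 ksps); an epoch counter increments
#' whenever a timestamp decreases, and `timestamp_abs` restores the absolute
#' sample index.
#'
#' @param stream Raw vector of 28-byte records, or a path to a packet stream
#'   file (see [write_packet_stream()]).
#' @param channel_base 1 to report 1-based channels.
#' @param wavelet Wavelet family assumed for AP payloads.
#' @return List: `events` tibble (`channel`, `timestamp`, `timestamp_abs`,
#'   `compressed` list-column), `lfp_samples` integer vector in stream order,
#'   `lfp_start_channels`, and `n_records`.
#' @export
depacketize <- function(stream, channel_base = 1L, wavelet = "sym4") {
  if (is.character(stream)) stream <- read_packet_stream(stream)
  n <- length(stream)
  if (n %% PKT_BYTES != 0) {
    abort(sprintf("truncated record at byte offset %d", (n %/% PKT_BYTES) * PKT_BYTES))
  }
  n_rec <- n %/% PKT_BYTES
  recs <- matrix(stream, nrow = PKT_BYTES) # one record per column
  types <- recs[1, ]
  bad <- which(types != TYPE_AP & types != TYPE_LFP)
  if (length(bad)) {
    abort(sprintf("unknown type code 0x%02x at byte offset %d",
                  as.integer(types[bad[1]]), (bad[1] - 1L) * PKT_BYTES))
  }

  ap_cols <- which(types == TYPE_AP)
  events <- lapply(ap_cols, function(r) {
    unpack_ap(recs[, r], channel_base, wavelet)
  })
  ts <- vapply(events, `[[`, numeric(1), "timestamp")
  ch <- vapply(events, `[[`, integer(1), "channel")
  # 24-bit rollover tracking per channel, in stream order: each channel's
  # detections are emitted time-ordered, so a decrease means a wrap
  ts_abs <- ts
  for (c0 in unique(ch)) {
    i <- which(ch == c0)
    epoch <- cumsum(c(0, diff(ts[i]) < 0))
    ts_abs[i] <- ts[i] + epoch * 2^24
  }
  for (i in seq_along(events)) events[[i]]$timestamp_abs <- ts_abs[i]

  lfp_cols <- which(types == TYPE_LFP)
  lfp_samples <- if (length(lfp_cols)) {
    le_int16(as.raw(recs[3:28, lfp_cols, drop = FALSE]))
  } else integer(0)
  lfp_start <- as.integer(recs[2, lfp_cols]) + channel_base

  ev_tbl <- if (length(events)) {
    tibble::tibble(
      channel = vapply(events, `[[`, integer(1), "channel"),
      timestamp = ts,
      timestamp_abs = ts_abs,
      compressed = events
    )
  } else {
    tibble::tibble(channel = integer(), timestamp = numeric(),
                   timestamp_abs = numeric(), compressed = list())
  }
  list(events = ev_tbl,
       lfp_samples = lfp_samples,
       lfp_start_channels = lfp_start,
       n_records = n_rec)
}

#' Reconstruct a dual-modality session from decoded packets
#'
#' Decompressed snippets are placed on their channel at
#' `[timestamp - pre, timestamp + post)` relative to the crossing sample
#' (last-writer-wins on overlap); events falling outside the session are
#' dropped with a warning and counted. LFP/EMG samples are de-interleaved
#' round-robin back onto channels and truncated to the session length.
#'
#' @param decoded Output of [depacketize()] (or a compatible list).
#' @param duration_s Session length, s.
#' @param n_channels Number of channels.
#' @param fs AP-path sampling rate, samples/s.
#' @param lfp_fs Decimated LFP/EMG sampling rate, samples/s.
#' @param pre,post Snippet alignment used at detection time.
#' @return A `reconstructed_session`: `ap` matrix at `fs` (zeros outside
#'   snippets), `lfp` matrix at `lfp_fs`, `events` tibble with decompressed
#'   snippets, and `dropped` count.
#' @export
reconstruct_session <- function(decoded, duration_s, n_channels, fs = 20000,
                                lfp_fs = 2000, pre = 16L, post = 32L) {
  n_ap <- round(duration_s * fs)
  n_lfp <- round(duration_s * lfp_fs)
  ap <- matrix(0, n_ap, n_channels)
  ev <- decoded$events
  dropped <- 0L
  snippets <- vector("list", nrow(ev))
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    snip <- decompress_ap(ev$compressed[[i]])
    snippets[[i]] <- snip
    cross <- ev$timestamp_abs[i] + 1 # 1-based crossing index
    idx <- (cross - pre):(cross + post - 1L)
    if (idx[1] < 1 || idx[length(idx)] > n_ap) {
      dropped <- dropped + 1L
      next
    }
    keep[i] <- TRUE
    ap[idx, ev$channel[i]] <- snip
  }
  if (dropped > 0) {
    warn(sprintf("%d event(s) outside the session were dropped", dropped))
  }
  ev$snippet <- snippets
  ev <- ev[keep, , drop = FALSE]

  lfp <- matrix(0L, n_lfp, n_channels)
  s <- decoded$lfp_samples
  usable <- min(length(s), n_lfp * n_channels)
  if (usable > 0) {
    m <- matrix(s[seq_len((usable %/% n_channels) * n_channels)],
                ncol = n_channels, byrow = TRUE)
    lfp[seq_len(nrow(m)), ] <- m
  }
  structure(
    list(ap = ap, lfp = lfp, events = ev, dropped = dropped,
         fs = fs, lfp_fs = lfp_fs, duration_s = duration_s),
    class = "reconstructed_session"
  )
}

#' @export
print.reconstructed_session <- function(x, ...) {
  cat(sprintf(
    "<reconstructed_session> %.3f s, %d ch, %d event(s), %d dropped\n",
    x$duration_s, ncol(x$ap), nrow(x$events), x$dropped
  ))
  invisible(x)
}
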