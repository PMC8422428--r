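REC_MAGIC <- charToRaw("SWREC")

#' Write a recording to the binary container
#'
#' Layout: 5 magic bytes `SWREC`, a 4-byte little-endian header length, a
#' JSON header (`fs`, `n_channels`, `scale_uV_per_LSB`, `duration_s`,
#' `unit`), then channel-interleaved little-endian signed 16-bit frames
#' (t1ch1, t1ch2, ..., t2ch1, ...). Microvolt recordings are quantized with
#' `scale` microvolts per LSB.
#'
#' @param rec An [sw_recording()].
#' @param path Output file.
#' @param scale Microvolts per LSB used when quantizing a uV recording.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, scale = 10000 / 65536) {
  stopifnot(inherits(rec, "sw_recording"))
  codes <- if (rec$unit == "code") rec$samples else {
    clamp(round(rec$samples / scale), -32768, 32767)
  }
  used_scale <- if (rec$unit == "code") {
    if (is.na(rec$scale)) 1 else rec$scale
  } else scale
  hdr <- jsonlite::toJSON(list(
    fs = rec$fs, n_channels = rec$n_channels,
    scale_uV_per_LSB = used_scale, duration_s = rec$duration,
    unit = "code"
  ), auto_unbox = TRUE)
  hdr_raw <- charToRaw(as.character(hdr))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(REC_MAGIC, con)
  writeBin(uint_le(length(hdr_raw), 4L), con)
  writeBin(hdr_raw, con)
  writeBin(int16_le(as.integer(t(codes))), con)
  invisible(path)
}

#' Read a recording from the binary container
#'
#' @param path File written by [write_recording()].
#' @param as_uV If TRUE, codes are scaled back to microvolts.
#' @return An [sw_recording()].
#' @export
read_recording <- function(path, as_uV = FALSE) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 9 || !identical(bytes[1:5], REC_MAGIC)) {
    abort("not a recording container (bad magic bytes)")
  }
  hlen <- le_uint(bytes[6:9])
  hdr <- jsonlite::fromJSON(rawToChar(bytes[10:(9 + hlen)]))
  body <- bytes[-(1:(9 + hlen))]
  codes <- le_int16(body)
  m <- matrix(codes, ncol = hdr$n_channels, byrow = TRUE)
  if (as_uV) {
    sw_recording(m * hdr$scale_uV_per_LSB, hdr$fs, unit = "uV")
  } else {
    sw_recording(m, hdr$fs, unit = "code", scale = hdr$scale_uV_per_LSB)
  }
}

#' Write ground truth to JSON plus delimited text
#'
#' Spike trains go to `<path>.json` (per-channel spike times) and
#' `<path>.tsv` (one row per event).
#'
#' @param ground_truth The `ground_truth` element of
#'   [synthesize_multimodal()]'s result.
#' @param path Output path stem.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  trains <- ground_truth$trains
  by_ch <- split(trains$time_s, trains$channel)
  jsonlite::write_json(
    list(spike_times_s = by_ch,
         peak_index = ground_truth$peak_index),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.table(trains, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write detected events as delimited text
#'
#' One row per event: channel, timestamp, then the 48 snippet samples.
#'
#' @param events `ap_events` tibble with a `snippet` list-column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  snips <- do.call(rbind, events$snippet)
  df <- data.frame(channel = events$channel, timestamp = events$timestamp)
  if (!is.null(snips)) {
    colnames(snips) <- paste0("s", seq_len(ncol(snips)))
    df <- cbind(df, snips)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
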