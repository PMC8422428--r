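PKT_BYTES <- 28L
TYPE_AP <- as.raw(0x01)
TYPE_LFP <- as.raw(0x02)
STREAM_MAGIC <- charToRaw("SWPK")
STREAM_VERSION <- as.raw(0x01)

#' Serialize a compressed AP into a 28-byte packet
#'
#' Layout: byte 0 type code (0x01), bytes 1-3 little-endian 24-bit timestamp,
#' byte 4 channel (low 5 bits, high 3 reserved zero), bytes 5-27 the 184-bit
#' wavelet payload.
#'
#' @param event A `compressed_ap` with a 184-bit payload; `channel` must be
#'   0-31 on the wire, so 1-based channels are shifted down by one.
#' @param channel_base 1 if `event$channel` is 1-based (default), 0 if
#'   already a wire channel.
#' @return Raw vector of 28 bytes.
#' @export
pack_ap <- function(event, channel_base = 1L) {
  stopifnot(inherits(event, "compressed_ap"))
  ch <- event$channel - channel_base
  if (ch < 0 || ch > 31) abort("channel does not fit the 5-bit field (0-31)")
  if (event$timestamp < 0 || event$timestamp >= 2^24) {
    abort("timestamp does not fit the 24-bit field")
  }
  if (event$bits != 184L || length(event$payload) != 23L) {
    abort("AP packets carry exactly a 184-bit payload")
  }
  c(TYPE_AP, uint_le(event$timestamp, 3L), as.raw(ch), event$payload)
}

#' Deserialize a 28-byte AP packet
#'
#' @param record Raw vector of 28 bytes with type code 0x01.
#' @inheritParams pack_ap
#' @param wavelet Wavelet family assumed for the payload (the wire format
#'   does not carry it).
#' @return A `compressed_ap`.
#' @export
unpack_ap <- function(record, channel_base = 1L, wavelet = "sym4") {
  if (length(record) != PKT_BYTES) abort("AP record must be 28 bytes")
  if (record[1] != TYPE_AP) abort("not an AP packet")
  payload <- record[6:28]
  bits <- unpack_bits_msb(payload, 184L)
  structure(
    list(channel = as.integer(record[5]) + channel_base,
         timestamp = le_uint(record[2:4]),
         payload = payload, bits = 184L, wavelet = wavelet,
         scale_exp = bits_to_int(bits[1:4])),
    class = "compressed_ap"
  )
}

#' Serialize 13 LFP/EMG samples into a 28-byte packet
#'
#' Layout: byte 0 type code (0x02), byte 1 wire channel of the first sample,
#' bytes 2-27 thirteen little-endian 16-bit samples. Consecutive packets of a
#' stream advance channels round-robin.
#'
#' @param samples Exactly 13 integer samples in the signed 16-bit range.
#' @param start_channel Channel of the first sample (1-based by default).
#' @inheritParams pack_ap
#' @return Raw vector of 28 bytes.
#' @export
pack_lfp <- function(samples, start_channel, channel_base = 1L) {
  if (length(samples) != 13L) abort("LFP/EMG packets carry exactly 13 samples")
  ch <- start_channel - channel_base
  if (ch < 0 || ch > 31) abort("channel does not fit 0-31")
  c(TYPE_LFP, as.raw(ch), int16_le(samples))
}

#' Deserialize a 28-byte LFP/EMG packet
#'
#' @param record Raw vector of 28 bytes with type code 0x02.
#' @inheritParams pack_ap
#' @return List with `samples` (13 integers) and `start_channel`.
#' @export
unpack_lfp <- function(record, channel_base = 1L) {
  if (length(record) != PKT_BYTES) abort("LFP record must be 28 bytes")
  if (record[1] != TYPE_LFP) abort("not an LFP/EMG packet")
  list(samples = le_int16(record[3:28]),
       start_channel = as.integer(record[2]) + channel_base)
}

#' Packetize a decimated multichannel LFP/EMG matrix
#'
#' Samples are interleaved time-major across channels (t1ch1, t1ch2, ...,
#' t2ch1, ...) and split into 13-sample packets; the final packet is
#' zero-padded. The header records the channel of each packet's first sample.
#'
#' @param codes Integer matrix, samples x channels, signed 16-bit range.
#' @return Raw vector: a multiple of 28 bytes.
#' @export
pack_lfp_stream <- function(codes) {
  codes <- as.matrix(codes)
  nc <- ncol(codes)
  flat <- as.integer(t(codes)) # time-major interleave
  total <- length(flat)
  n_pkts <- ceiling(total / 13L)
  pad <- n_pkts * 13L - total
  flat <- c(flat, integer(pad))
  first_idx <- (seq_len(n_pkts) - 1L) * 13L # 0-based index of first sample
  start_ch <- (first_idx %% nc) # wire channel (0-based)
  body <- int16_le(flat)
  dim(body) <- c(26L, n_pkts)
  out <- rbind(matrix(rep(TYPE_LFP, n_pkts), nrow = 1),
               matrix(as.raw(start_ch), nrow = 1),
               body)
  as.raw(out)
}

#' Combined data reduction ratio at a nominal firing rate
#'
#' Ratio of the raw per-channel sample rate to the reduced stream: detected
#' and compressed APs plus the decimated low-frequency band,
#' `f_SH / (NFR * Samples_AP / CR + f_SL)`.
#'
#' @param f_SH Raw sampling rate, samples/s.
#' @param NFR Neuron firing rate, AP/s (0 gives the LFP-only limit).
#' @param Samples_AP Samples per AP snippet.
#' @param CR Compression ratio of the AP codec.
#' @param f_SL Decimated low-band sampling rate, samples/s.
#' @return The ratio (dimensionless).
#' @export
compute_cdrr <- function(f_SH, NFR, Samples_AP, CR, f_SL) {
  if (f_SH <= 0 || Samples_AP <= 0 || CR <= 0 || f_SL < 0 || NFR < 0) {
    abort("rates, sample counts and CR must be positive (NFR may be zero)")
  }
  den <- NFR * Samples_AP / CR + f_SL
  if (den == 0) abort("zero denominator: no reduced stream")
  f_SH / den
}

#' Recording-level data reduction ratio
#'
#' Session-level form using the actually detected AP count:
#' `(f_SH * duration * n_channels) /
#'  (n_aps * Samples_AP / CR + f_SL * duration * n_channels)`.
#'
#' @param f_SH Raw sampling rate, samples/s.
#' @param duration_s Session length, s.
#' @param n_channels Recorded channels.
#' @param n_aps Total APs detected over all channels.
#' @param Samples_AP Samples per AP snippet.
#' @param CR Compression ratio of the AP codec.
#' @param f_SL Decimated low-band sampling rate, samples/s.
#' @return The ratio (dimensionless).
#' @export
compute_recording_cdrr <- function(f_SH, duration_s, n_channels, n_aps,
                                   Samples_AP, CR, f_SL) {
  if (any(c(f_SH, duration_s, n_channels, Samples_AP, CR) <= 0) || n_aps < 0 ||
      f_SL < 0) {
    abort("all quantities must be positive (n_aps may be zero)")
  }
  den <- n_aps * Samples_AP / CR + f_SL * duration_s * n_channels
  if (den == 0) abort("zero denominator: no reduced stream")
  (f_SH * duration_s * n_channels) / den
}

#' Raw (uncompressed) data rate
#'
#' @param n_channels Channels recorded in parallel.
#' @param fs Sampling rate, samples/s.
#' @param bits Bits per sample.
#' @return Rate in bits/s.
#' @export
raw_data_rate <- function(n_channels, fs, bits = 16L) {
  if (any(c(n_channels, fs, bits) < 0)) abort("arguments must be non-negative")
  n_channels * fs * bits
}

#' Check a data rate against the wireless link budget
#'
#' @param rate_bps Data rate, bits/s.
#' @param ceiling_bps Maximum effective link rate (default 1.4 Mbps);
#'   the bound is inclusive.
#' @return Tibble with `rate_bps`, `ceiling_bps`, `margin_bps`, `pass`.
#' @export
check_link_budget <- function(rate_bps, ceiling_bps = 1.4e6) {
  if (rate_bps < 0) abort("rate must be non-negative")
  tibble::tibble(
    rate_bps = rate_bps,
    ceiling_bps = ceiling_bps,
    margin_bps = ceiling_bps - rate_bps,
    pass = rate_bps <= ceiling_bps
  )
}

#' Write a packet stream file
#'
#' File layout: 4 magic bytes `SWPK`, 1 version byte, then 28-byte records.
#'
#' @param packets Raw vector (a multiple of 28 bytes).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_packet_stream <- function(packets, path) {
  if (length(packets) %% PKT_BYTES != 0) {
    abort("packet stream length must be a multiple of 28 bytes")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(STREAM_MAGIC, STREAM_VERSION, packets), con)
  invisible(path)
}

#' Read a packet stream file
#'
#' @param path File written by [write_packet_stream()].
#' @return Raw vector of 28-byte records (magic and version stripped).
#' @export
read_packet_stream <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 5 || !identical(bytes[1:4], STREAM_MAGIC)) {
    abort("not a packet stream file (bad magic bytes)")
  }
  bytes[-(1:5)]
}
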