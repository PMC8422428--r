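#' Run code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Pack a logical bit vector (MSB-first within each byte) into raw bytes
#' @noRd
pack_bits_msb <- function(bits) {
  n <- length(bits)
  pad <- (8L - n %% 8L) %% 8L
  bits <- c(as.integer(bits), integer(pad))
  m <- matrix(bits, nrow = 8L)
  as.raw(colSums(m * 2L^(7:0)))
}

#' Unpack raw bytes into a logical bit vector, MSB-first
#' @noRd
unpack_bits_msb <- function(bytes, n_bits = 8L * length(bytes)) {
  v <- as.integer(bytes)
  bits <- as.vector(vapply(v, function(b) bitwAnd(bitwShiftR(b, 7:0), 1L), integer(8)))
  bits[seq_len(n_bits)]
}

#' Integer (0 <= x < 2^nbits) to MSB-first bits
#' @noRd
int_to_bits <- function(x, nbits) {
  vapply(nbits:1, function(i) bitwAnd(bitwShiftR(as.integer(x), i - 1L), 1L), integer(1))
}

#' MSB-first bits to non-negative integer
#' @noRd
bits_to_int <- function(bits) {
  sum(as.integer(bits) * 2L^((length(bits) - 1L):0L))
}

#' Little-endian unsigned integer from raw bytes (up to 3 bytes)
#' @noRd
le_uint <- function(bytes) {
  sum(as.integer(bytes) * 256L^(seq_along(bytes) - 1L))
}

#' Non-negative integer to little-endian raw bytes
#' @noRd
uint_le <- function(x, n_bytes) {
  x <- as.numeric(x)
  out <- raw(n_bytes)
  for (i in seq_len(n_bytes)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

#' Signed 16-bit integers to little-endian raw (2 bytes each)
#' @noRd
int16_le <- function(x) {
  x <- as.integer(x)
  if (any(x < -32768L | x > 32767L)) {
    abort("samples exceed the signed 16-bit range")
  }
  u <- ifelse(x < 0L, x + 65536L, x)
  as.raw(rbind(u %% 256L, u %/% 256L))
}

#' Little-endian raw pairs to signed 16-bit integers
#' @noRd
le_int16 <- function(bytes) {
  v <- as.integer(bytes)
  lo <- v[seq(1L, length(v), by = 2L)]
  hi <- v[seq(2L, length(v), by = 2L)]
  u <- lo + 256L * hi
  ifelse(u >= 32768L, u - 65536L, u)
}

#' Clamp numeric values to a range
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Band-limited Gaussian noise synthesized in the frequency domain.
#'
#' White Gaussian spectrum masked to `band`, inverse-transformed; by
#' construction all power lies inside the band (up to the DC/Nyquist bins).
#' @noRd
band_noise <- function(n, fs, band, exponent = 0) {
  x <- rnorm(n)
  X <- fft(x)
  f <- (0:(n - 1)) * fs / n
  f_mirror <- fs - f
  f_eff <- pmin(f, f_mirror) # analog frequency of each bin
  keep <- f_eff >= band[1] & f_eff <= band[2]
  keep[1] <- FALSE # no DC
  X[!keep] <- 0
  if (exponent != 0) {
    w <- rep(0, n)
    w[keep] <- (pmax(f_eff[keep], band[1]))^(-exponent / 2)
    X <- X * w
  }
  Re(fft(X, inverse = TRUE)) / n
}
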