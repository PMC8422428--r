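#' Orthonormal wavelet decomposition filters
#'
#' Scaling (low-pass) decomposition filters for the wavelet families used by
#' the spike codec. Coefficients are the published orthonormal filter banks
#' (Daubechies least-asymmetric "sym4", extremal-phase "db4", and Haar).
#'
#' @param wavelet One of `"sym4"`, `"db4"`, `"haar"`.
#' @return Numeric vector of low-pass decomposition coefficients.
#' @export
wavelet_filter <- function(wavelet = c("sym4", "db4", "haar")) {
  wavelet <- match.arg(wavelet)
  switch(wavelet,
    sym4 = c(
      -0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
      0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
      -0.01260396726203783, 0.03222310060404270
    ),
    db4 = c(
      -0.01059740178506903, 0.03288301166688520, 0.03084138183556076,
      -0.18703481171909309, -0.02798376941685985, 0.63088076792985890,
      0.71484657055291570, 0.23037781330889650
    ),
    haar = c(1, 1) / sqrt(2)
  )
}

# Single-level periodized analysis operator on R^n (n even).
# Row k of the approximation block is h placed at offset 2k, wrapped mod n;
# detail rows use the quadrature-mirror filter g[m] = (-1)^m h[L-1-m].
# For orthonormal h this matrix is orthogonal for every even n, so synthesis
# is the transpose.
dwt_level_matrix <- function(h, n) {
  if (n %% 2L != 0L) abort("periodized DWT level requires an even length")
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  W <- matrix(0, n, n)
  half <- n %/% 2L
  for (k in seq_len(half)) {
    for (m in seq_len(L)) {
      j <- ((2L * (k - 1L) + (m - 1L)) %% n) + 1L
      W[k, j] <- W[k, j] + h[m]
      W[half + k, j] <- W[half + k, j] + g[m]
    }
  }
  W
}

#' Composed multi-level DWT analysis operator
#'
#' Builds (and caches) the `n x n` orthogonal matrix whose product with a
#' signal yields its periodized multi-level wavelet coefficients in
#' `c(a_L, d_L, d_{L-1}, ..., d_1)` order.
#'
#' @param wavelet Wavelet family name.
#' @param n Signal length; must be divisible by `2^levels`... the approximation
#'   length at every level must be even.
#' @param levels Number of decomposition levels.
#' @return Orthogonal matrix of dimension `n x n`.
#' @export
dwt_operator <- function(wavelet = "sym4", n = 48L, levels = 4L) {
  key <- paste(wavelet, n, levels, sep = "/")
  if (!is.null(the[[key]])) return(the[[key]])
  h <- wavelet_filter(wavelet)
  W <- diag(n)
  m <- n
  for (lev in seq_len(levels)) {
    if (m %% 2L != 0L) {
      abort(sprintf("level %d would act on odd length %d", lev, m))
    }
    B <- diag(n)
    B[seq_len(m), seq_len(m)] <- dwt_level_matrix(h, m)
    W <- B %*% W
    m <- m %/% 2L
  }
  the[[key]] <- W
  W
}

#' Forward multi-level discrete wavelet transform (periodized)
#'
#' @param x Numeric vector, or a matrix whose columns are transformed jointly.
#' @inheritParams dwt_operator
#' @return Coefficients in `c(a_L, d_L, ..., d_1)` order (vector or matrix).
#' @export
dwt_forward <- function(x, wavelet = "sym4", levels = 4L) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  W <- dwt_operator(wavelet, n, levels)
  out <- W %*% (if (is.matrix(x)) x else matrix(x, ncol = 1))
  if (is.matrix(x)) out else drop(out)
}

#' Inverse multi-level discrete wavelet transform (periodized)
#'
#' Exact inverse of [dwt_forward()] (the analysis operator is orthogonal).
#'
#' @param coef Coefficient vector or matrix from [dwt_forward()].
#' @inheritParams dwt_operator
#' @return Reconstructed signal (vector or matrix).
#' @export
dwt_inverse <- function(coef, wavelet = "sym4", levels = 4L) {
  n <- if (is.matrix(coef)) nrow(coef) else length(coef)
  W <- dwt_operator(wavelet, n, levels)
  out <- crossprod(W, if (is.matrix(coef)) coef else matrix(coef, ncol = 1))
  if (is.matrix(coef)) out else drop(out)
}
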