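#' Re-filter and re-center spike snippets
#'
#' Snippets are band-pass filtered (zero-phase biquad, symmetric padding) and
#' circularly shifted so the absolute peak sits at `center_index`.
#'
#' @param snippets Matrix (snippets x 48), list of length-48 vectors, or an
#'   `ap_events` tibble (its `snippet` column is replaced).
#' @param fs Sampling rate, Hz.
#' @param band Two-element pass band, Hz.
#' @param center_index Target index of the absolute peak (1-based).
#' @return Object of the same shape with processed snippets.
#' @export
refilter_and_center <- function(snippets, fs = 20000, band = c(300, 5000),
                                center_index = 17L) {
  if (inherits(snippets, "data.frame")) {
    out <- snippets
    out$snippet <- lapply(snippets$snippet, refilter_and_center,
                          fs = fs, band = band, center_index = center_index)
    return(out)
  }
  if (is.list(snippets)) {
    return(lapply(snippets, refilter_and_center, fs = fs, band = band,
                  center_index = center_index))
  }
  if (is.matrix(snippets)) {
    return(t(apply(snippets, 1, refilter_and_center, fs = fs, band = band,
                   center_index = center_index)))
  }
  x <- as.numeric(snippets)
  n <- length(x)
  bp <- signal::butter(2, c(band[1], min(band[2], 0.499 * fs)) / (fs / 2),
                       type = "pass")
  padded <- c(rev(x), x, rev(x))
  y <- signal::filtfilt(bp, padded)[(n + 1):(2 * n)]
  pk <- which.max(abs(y))
  shift <- (pk - center_index) %% n
  if (shift > 0) y <- c(y[(shift + 1):n], y[1:shift])
  y
}

#' Sorted spike units
#'
#' PCA on the snippet matrix followed by k-means on the leading principal
#' components. If `k` is NULL, k is selected by mean silhouette over
#' `2:k_max`, falling back to a single cluster when even the best split
#' scores below `min_silhouette`.
#'
#' @param snippets Matrix (snippets x 48), list of vectors, or `ap_events`
#'   tibble (column `snippet`).
#' @param n_components Principal components kept for clustering.
#' @param k Number of clusters (NULL = select by silhouette).
#' @param k_max Largest k considered when selecting.
#' @param min_silhouette Below this mean silhouette the data are treated as a
#'   single unit.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return A `sorted_units` object: `labels`, `centers` (mean waveform per
#'   cluster, k x 48), `scores`, `k`, `silhouette`.
#' @export
sort_spikes <- function(snippets, n_components = 2L, k = NULL, k_max = 4L,
                        min_silhouette = 0.5, seed = 1L, nstart = 10L) {
  X <- snippet_matrix(snippets)
  n <- nrow(X)
  if (!is.null(k)) {
    if (k < 1) abort("k must be at least 1")
    if (n < k) abort("fewer snippets than clusters")
  }
  if (n < 2) abort("need at least 2 snippets to sort")
  n_components <- min(n_components, ncol(X), n - 1L)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  # fix component signs (largest-magnitude loading positive) so results do
  # not depend on SVD sign conventions or row order
  for (j in seq_len(ncol(scores))) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }

  # run k-means on canonically ordered rows so the partition does not depend
  # on input order; labels are mapped back afterwards
  ord <- do.call(order, as.data.frame(scores))
  fit_k <- function(kk) {
    fit <- with_seed(seed, kmeans(scores[ord, , drop = FALSE], centers = kk,
                                  nstart = nstart, iter.max = 50L))
    cl <- integer(n)
    cl[ord] <- fit$cluster
    fit$cluster <- cl
    fit
  }
  sil <- NA_real_
  if (is.null(k)) {
    best <- NULL
    best_sil <- -Inf
    for (kk in 2:min(k_max, n - 1L)) {
      fit <- fit_k(kk)
      s <- mean_silhouette(scores, fit$cluster)
      if (!is.na(s) && s > best_sil) {
        best_sil <- s
        best <- fit
      }
    }
    if (is.null(best) || best_sil < min_silhouette) {
      k <- 1L
      fit <- list(cluster = rep(1L, n))
      sil <- best_sil
    } else {
      k <- max(best$cluster)
      fit <- best
      sil <- best_sil
    }
  } else if (k == 1L) {
    fit <- list(cluster = rep(1L, n))
  } else {
    fit <- fit_k(k)
    sil <- mean_silhouette(scores, fit$cluster)
  }
  labels <- canonical_labels(fit$cluster, scores)
  centers <- t(vapply(seq_len(max(labels)), function(cl) {
    colMeans(X[labels == cl, , drop = FALSE])
  }, numeric(ncol(X))))
  structure(
    list(labels = labels, centers = centers, scores = scores,
         k = as.integer(max(labels)), silhouette = sil, n = n),
    class = "sorted_units"
  )
}

# relabel clusters deterministically (by decreasing size, ties by first
# principal-component mean) so the partition is invariant to input order
canonical_labels <- function(cl, scores) {
  sizes <- table(cl)
  key <- order(-as.integer(sizes),
               vapply(names(sizes), function(g) {
                 mean(scores[cl == as.integer(g), 1])
               }, numeric(1)))
  map <- integer(length(sizes))
  map[as.integer(names(sizes))[key]] <- seq_along(key)
  map[cl]
}

# mean silhouette width from Euclidean distances (small n only)
mean_silhouette <- function(x, labels) {
  n <- nrow(x)
  if (length(unique(labels)) < 2 || n > 5000) return(NA_real_)
  d <- as.matrix(stats::dist(x))
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

snippet_matrix <- function(snippets) {
  if (inherits(snippets, "data.frame")) snippets <- snippets$snippet
  if (is.list(snippets)) snippets <- do.call(rbind, snippets)
  as.matrix(snippets)
}

#' @export
print.sorted_units <- function(x, ...) {
  cat(sprintf("<sorted_units> %d snippet(s) in %d cluster(s)", x$n, x$k))
  if (!is.na(x$silhouette)) cat(sprintf(", mean silhouette %.2f", x$silhouette))
  cat("\n")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Per-snippet tidy summary of sorted units
#'
#' @param x A `sorted_units`.
#' @param ... Unused.
#' @return Tibble with snippet id, cluster label, and PC scores.
#' @export
tidy.sorted_units <- function(x, ...) {
  out <- tibble::tibble(snippet = seq_len(x$n), cluster = x$labels)
  sc <- tibble::as_tibble(as.data.frame(x$scores))
  names(sc) <- paste0("PC", seq_len(ncol(sc)))
  dplyr::bind_cols(out, sc)
}

#' One-row summary of sorted units
#'
#' @param x A `sorted_units`.
#' @param ... Unused.
#' @return Tibble with `k`, `n`, `silhouette`, and the smallest cluster size.
#' @export
glance.sorted_units <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = x$n, silhouette = x$silhouette,
    min_cluster_size = min(tabulate(x$labels, x$k))
  )
}

#' Default LFP analysis bands
#'
#' Delta 1-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-100 Hz.
#' @return Named list of two-element Hz ranges.
#' @export
default_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 100))
}

#' Band powers of an LFP segment (2-norm normalized FFT)
#'
#' The segment is detrended (mean removed), Hann-windowed and Fourier
#' transformed; the one-sided magnitude spectrum is normalized by its 2-norm
#' so squared magnitudes sum to 1, and each band's power is the sum of
#' squared normalized magnitudes at frequencies inside the band
#' (half-open `[lo, hi)`). Percentages are relative to the total power over
#' the covered bands and sum to 100.
#'
#' @param x Numeric LFP segment (at least 2 s of samples).
#' @param fs Sampling rate, Hz.
#' @param bands Named list of two-element Hz ranges inside (0, fs/2).
#' @return A `band_power_table` tibble: `band`, `f_lo`, `f_hi`, `power`
#'   (fraction of total spectrum power), `percent` (of covered bands).
#' @export
band_power <- function(x, fs, bands = default_bands()) {
  x <- as.numeric(x)
  if (length(x) < 2 * fs) abort("segment must cover at least 2 s")
  for (b in bands) {
    if (b[1] <= 0 || b[2] > fs / 2 || b[1] >= b[2]) {
      abort("bands must satisfy 0 < lo < hi <= fs/2")
    }
  }
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)) # Hann
  X <- fft((x - mean(x)) * w)
  half <- floor(n / 2) + 1L
  mag <- Mod(X[seq_len(half)])
  mag <- mag / sqrt(sum(mag^2)) # 2-norm normalization
  f <- (seq_len(half) - 1) * fs / n
  pw <- vapply(bands, function(b) sum(mag[f >= b[1] & f < b[2]]^2), numeric(1))
  out <- tibble::tibble(
    band = names(bands),
    f_lo = vapply(bands, `[`, numeric(1), 1),
    f_hi = vapply(bands, `[`, numeric(1), 2),
    power = unname(pw),
    percent = unname(100 * pw / sum(pw))
  )
  class(out) <- c("band_power_table", class(out))
  out
}

#' Binned firing rate
#'
#' @param events Numeric event times in seconds, or a tibble with a `time_s`
#'   column (e.g. from [detect_aps()]).
#' @param bin_width Bin width, s.
#' @param duration Total duration, s.
#' @return Tibble with `bin_start`, `bin_mid`, `count`, `rate` (events/s).
#' @export
firing_rate <- function(events, bin_width = 0.25, duration) {
  if (bin_width <= 0) abort("bin_width must be positive")
  times <- if (inherits(events, "data.frame")) events$time_s else as.numeric(events)
  edges <- seq(0, duration + bin_width * 1e-9, by = bin_width)
  if (edges[length(edges)] < duration) edges <- c(edges, duration)
  counts <- if (length(times)) {
    tab <- table(cut(times, breaks = edges, right = FALSE))
    as.integer(tab)
  } else integer(length(edges) - 1L)
  widths <- diff(edges)
  tibble::tibble(
    bin_start = edges[-length(edges)],
    bin_mid = edges[-length(edges)] + widths / 2,
    count = counts,
    rate = counts / widths
  )
}

#' Fixed-threshold detection gated by a stimulation schedule
#'
#' Applies `thr_in` inside stimulation pulses and `thr_out` outside, on the
#' absolute signal, with the spike-engine dead-time rule.
#'
#' @param x Numeric signal, uV.
#' @param thr_in Threshold inside pulses, uV.
#' @param thr_out Threshold outside pulses, uV.
#' @param schedule Stimulation schedule tibble (possibly empty/NULL);
#'   overlapping intervals raise an error.
#' @param fs Sampling rate, Hz.
#' @param dead_time Re-trigger suppression, samples.
#' @return Tibble with `sample`, `time_s`, `in_stim`.
#' @export
threshold_events_gated <- function(x, thr_in, thr_out, schedule = NULL,
                                   fs = 20000, dead_time = 48L) {
  if (thr_in <= 0 || thr_out <= 0) abort("thresholds must be positive")
  x <- as.numeric(x)
  mask <- stim_mask(schedule, length(x))
  thr <- ifelse(mask, thr_in, thr_out)
  cand <- which(abs(x) >= thr)
  events <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= dead_time) {
      events <- c(events, i)
      last <- i
    }
  }
  tibble::tibble(
    sample = events,
    time_s = (events - 1) / fs,
    in_stim = mask[events]
  )
}

#' Differential EMG derivation
#'
#' EMG is recorded between two wire electrodes against a distant reference;
#' subtracting the two wires removes the shared background.
#'
#' @param a,b Numeric signals of equal length (uV).
#' @return `a - b`.
#' @export
emg_differential <- function(a, b) {
  if (length(a) != length(b)) abort("signals must have equal length")
  a - b
}
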