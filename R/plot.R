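#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot band powers as a bar chart
#'
#' @param object A `band_power_table` from [band_power()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.band_power_table <- function(object, ...) {
  object$band <- factor(object$band, levels = object$band)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$band, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Power (%)",
                  title = "LFP band power (2-norm normalized spectrum)") +
    ggplot2::theme_minimal()
}

#' Plot sorted spike waveforms by cluster
#'
#' Individual snippets in grey, cluster mean waveform in red.
#'
#' @param object A `sorted_units` from [sort_spikes()].
#' @param snippets Optional snippet matrix / list used for the fit (needed to
#'   draw individual traces; only means are drawn otherwise).
#' @param fs Sampling rate for the time axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sorted_units <- function(object, snippets = NULL, fs = 20000, ...) {
  tmin <- (seq_len(ncol(object$centers)) - 1) / fs * 1000
  means <- tidyr::pivot_longer(
    tibble::as_tibble(cbind(cluster = seq_len(object$k),
                            as.data.frame(object$centers))),
    -"cluster", names_to = "i", values_to = "uV"
  )
  means$t_ms <- rep(tmin, times = object$k)
  p <- ggplot2::ggplot(means, ggplot2::aes(x = .data$t_ms, y = .data$uV))
  if (!is.null(snippets)) {
    X <- snippet_matrix(snippets)
    traces <- tibble::tibble(
      cluster = rep(object$labels, each = ncol(X)),
      snippet = rep(seq_len(nrow(X)), each = ncol(X)),
      t_ms = rep(tmin, times = nrow(X)),
      uV = as.vector(t(X))
    )
    p <- p + ggplot2::geom_line(
      data = traces,
      ggplot2::aes(group = .data$snippet), colour = "grey70", linewidth = 0.2
    )
  }
  p + ggplot2::geom_line(colour = "red", linewidth = 0.8) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude",
                  title = "Sorted spike waveforms") +
    ggplot2::theme_minimal()
}

#' Plot a binned firing-rate series
#'
#' @param rates Tibble from [firing_rate()].
#' @param schedule Optional stimulation schedule to shade.
#' @return A ggplot.
#' @export
plot_firing_rate <- function(rates, schedule = NULL) {
  p <- ggplot2::ggplot(rates, ggplot2::aes(x = .data$bin_mid, y = .data$rate))
  if (!is.null(schedule) && nrow(schedule)) {
    p <- p + ggplot2::geom_rect(
      data = schedule, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$on_s, xmax = .data$off_s,
                   ymin = -Inf, ymax = Inf),
      fill = "lightblue", alpha = 0.5
    )
  }
  p + ggplot2::geom_step() +
    ggplot2::labs(x = "Time (s)", y = "Firing rate (AP/s)") +
    ggplot2::theme_minimal()
}

#' Plot recording traces
#'
#' @param object An [sw_recording()].
#' @param channels Channels to draw (default: first 8).
#' @param max_points Down-sampling cap per channel for display.
#' @param ... Unused.
#' @return A ggplot with one facet per channel.
#' @export
autoplot.sw_recording <- function(object, channels = NULL,
                                  max_points = 5000L, ...) {
  channels <- channels %||% seq_len(min(8L, object$n_channels))
  n <- nrow(object$samples)
  step <- max(1L, n %/% max_points)
  idx <- seq(1L, n, by = step)
  df <- purrr::map_dfr(channels, function(ch) {
    tibble::tibble(channel = ch, t = (idx - 1) / object$fs,
                   value = object$samples[idx, ch])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(channel ~ ., scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = object$unit) +
    ggplot2::theme_minimal()
}
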