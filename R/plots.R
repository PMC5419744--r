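# ggplot2 visualisations for the main result types.

#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(
    position_px = seq_len(nrow(object$image)),
    frame = seq_len(ncol(object$image))
  )
  df$intensity <- as.vector(object$image)
  df$time_s <- (df$frame - 1) * object$frame_interval_s
  ggplot(df, aes(.data$time_s, .data$position_px, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "time (s)", y = "position (px)", fill = "counts") +
    theme_minimal()
}

#' @export
autoplot.recovery_curve <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(.data$time_since_pulse_s, .data$intensity_norm)) +
    geom_point(alpha = 0.6) +
    labs(x = "time after FRAP pulse (s)", y = "normalized intensity") +
    theme_minimal()
  if (!is.null(fit) && is.finite(fit$tau)) {
    t <- seq(0, max(object$time_since_pulse_s), length.out = 200)
    pred <- tibble(time_since_pulse_s = t,
                   intensity_norm = fit$offset +
                     fit$amplitude * (1 - exp(-t / fit$tau)))
    p <- p + geom_line(data = pred, colour = "red")
  }
  p
}

#' @export
autoplot.ccf_curve <- function(object, ...) {
  ggplot(object, aes(.data$lag_s, .data$ccf)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_line() +
    labs(x = "lag (s)", y = "cross-correlation") +
    theme_minimal()
}

#' Plot a stoichiometry histogram with its integer-mixture fit
#'
#' @param counts Numeric vector of per-frame complex counts.
#' @param mix An `integer_mixture` fit.
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_stoichiometry <- function(counts, mix, binwidth = 0.1) {
  grid <- seq(0, mix$K + 1, length.out = 400)
  dens <- purrr::map(seq_len(mix$K), function(k) {
    tibble(count = grid, component = factor(k),
           density = mix$weights[k] * dnorm(grid, k, sqrt(k) * mix$rel_sd))
  }) |> purrr::list_rbind()
  total <- dens |> group_by(.data$count) |>
    summarise(density = sum(.data$density), .groups = "drop")
  ggplot(tibble(count = counts), aes(.data$count)) +
    ggplot2::geom_histogram(aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey80",
                            colour = "grey40") +
    geom_line(data = dens,
              aes(y = .data$density, colour = .data$component)) +
    geom_line(data = total, aes(y = .data$density), colour = "black") +
    labs(x = "Pol III* per replisome", y = "density") +
    theme_minimal()
}

#' Plot exchange time versus concentration
#'
#' @param series Result of [exchange_vs_concentration()].
#' @return A ggplot object (log-log axes).
#' @export
plot_exchange_series <- function(series) {
  p <- ggplot(series$table, aes(.data$conc, .data$tau)) +
    geom_point(size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    labs(x = "Pol III* concentration (nM)", y = "exchange time (s)") +
    theme_minimal()
  if (!is.null(series$model)) {
    C <- exp(seq(log(min(series$table$conc)), log(max(series$table$conc)),
                 length.out = 100))
    pred <- tibble(conc = C,
                   tau = 1 / (series$model$k_on * C) + 1 / series$model$k_handoff)
    p <- p + geom_line(data = pred, colour = "red")
  }
  p
}
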