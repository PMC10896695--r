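#' Plot a bleaching trace with its fitted steps
#'
#' @param object A [fit_steps()] result.
#' @param ... Unused.
#' @return A ggplot: raw trace with the piecewise-constant fit overlaid.
#' @export
autoplot.step_fit <- function(object, ...) {
  n <- length(object$values)
  t <- (seq_len(n) - 1) / object$frame_rate
  edges <- c(0L, object$change_points, n)
  fitted <- rep(object$levels, times = diff(edges))
  d <- tibble(t = t, intensity = object$values, fitted = fitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$intensity), colour = "grey55", linewidth = 0.3
    ) +
    ggplot2::geom_step(
      ggplot2::aes(y = .data$fitted), colour = "#00737d", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "time (s)", y = "intensity (AU)",
      title = sprintf("%d bleaching step(s)", object$n_steps)
    ) +
    ggplot2::theme_minimal()
}

#' Kymograph-style plot of a simulated track set
#'
#' @param object A [simulate_tracks()] result.
#' @param ... Unused.
#' @return A ggplot with position on the x axis and time increasing
#'   downwards, the convention of kymograph figures.
#' @export
autoplot.sim_tracks <- function(object, ...) {
  ggplot2::ggplot(
    object$spots,
    ggplot2::aes(
      x = .data$x, y = .data$t, group = .data$track_id
    )
  ) +
    ggplot2::geom_path(linewidth = 0.3, alpha = 0.7, colour = "#00737d") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position (µm)", y = "time (s)") +
    ggplot2::theme_minimal()
}

#' Plot a rendered kymograph matrix
#'
#' @param img Matrix from [render_kymograph()].
#' @return A ggplot raster of the image.
#' @export
plot_kymograph <- function(img) {
  pos <- attr(img, "positions")
  d <- tidyr::expand_grid(
    frame = seq_len(nrow(img)) - 1L, col = seq_len(ncol(img))
  )
  d$intensity <- as.vector(t(img))
  d$x <- pos[d$col]
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$frame, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "position (µm)", y = "frame") +
    ggplot2::theme_minimal()
}

#' Histogram of simulated or sampled arrival times
#'
#' @param object An `arrival_result` with samples.
#' @param ... Unused.
#' @return A ggplot histogram with the closed-form mean marked.
#' @export
autoplot.arrival_result <- function(object, ...) {
  d <- tibble(arrival_min = object$samples_min)
  ggplot2::ggplot(d, ggplot2::aes(.data$arrival_min)) +
    ggplot2::geom_histogram(bins = 30, fill = "#00737d", colour = "white") +
    ggplot2::geom_vline(
      xintercept = object$mean_min, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "first arrival (min)", y = "particles",
      title = sprintf("%s model", object$model)
    ) +
    ggplot2::theme_minimal()
}
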