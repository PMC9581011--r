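#' Plot nearest-neighbor CDF deviation curves
#'
#' One line per connector: the deviation `delta` of its nearest-neighbor
#' distance CDF from the ideal-connection CDF.  Dips below zero indicate
#' over-clustering, excursions above zero under-clustering.
#'
#' @param x An `fc_evaluation` from [evaluate_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_delta_curves <- function(x, ...) {
  ggplot2::ggplot(x$curves,
                  ggplot2::aes(x = .data$r, y = .data$delta,
                               colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "nearest-neighbor distance r (pixels)",
                  y = expression(delta == F - F[ideal]),
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' @rdname plot_delta_curves
#' @exportS3Method ggplot2::autoplot
autoplot.fc_evaluation <- function(x, ...) plot_delta_curves(x, ...)

#' Plot frame-connected duration histograms
#'
#' Normalized duration histograms per connector; when a [kinetic_model()] is
#' supplied, the expected geometric pmf with stop probability
#' `1 - exp(-(k_off + k_bleach))` is overlaid.
#'
#' @param x An `fc_evaluation` from [evaluate_methods()].
#' @param model Optional generative [kinetic_model()] for the overlay.
#' @param max_N Largest duration shown.
#' @return A ggplot object.
#' @export
plot_duration_histogram <- function(x, model = NULL, max_N = 15) {
  dur <- x$durations |>
    dplyr::group_by(.data$method) |>
    dplyr::mutate(p = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$N <= max_N)
  p <- ggplot2::ggplot(dur, ggplot2::aes(x = .data$N, y = .data$p,
                                         fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "duration N (frames)", y = "fraction of clusters",
                  fill = "method") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    pmf <- expected_duration_pmf(model$k_off + model$k_bleach, N = 1:max_N)
    p <- p + ggplot2::geom_point(
      data = pmf, ggplot2::aes(x = .data$N, y = .data$p),
      inherit.aes = FALSE, shape = 4, size = 2
    )
  }
  p
}

#' Plot a Gaussian reconstruction image
#'
#' @param locs A localization tibble.
#' @param roi,zoom Passed to [render_gaussian_image()].
#' @return A ggplot object (raster of rendered intensity).
#' @export
plot_reconstruction <- function(locs, roi = NULL, zoom = 10) {
  img <- render_gaussian_image(locs, roi = roi, zoom = zoom)
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$intensity <- img[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_void()
}
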