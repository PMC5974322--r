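# ggplot2 displays of the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

matrix_to_long <- function(m, value = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value := as.vector(m)
  )
}

#' @method autoplot corr_map
#' @export
autoplot.corr_map <- function(object, ...) {
  df <- matrix_to_long(object$values, "correlation")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "black", high = "yellow") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("Seed correlation map (seed %d, %d)",
                                  object$seed_pixel[1], object$seed_pixel[2]))
}

#' @method autoplot roi_set
#' @export
autoplot.roi_set <- function(object, ...) {
  if (n_rois(object) == 0L) {
    stop("roi_set has no ROIs to plot", call. = FALSE)
  }
  proj <- matrix(apply(object$spatial, 1, max), object$dims[1], object$dims[2])
  df <- matrix_to_long(proj, "footprint")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$footprint)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "green") +
    ggplot2::geom_point(
      data = object$centers,
      ggplot2::aes(.data$col, .data$row), inherit.aes = FALSE,
      colour = "red", shape = 3, size = 1
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("%d extracted ROI(s)", n_rois(object)))
}

#' @method autoplot noise_model_fit
#' @export
autoplot.noise_model_fit <- function(object, ...) {
  ggplot2::ggplot(object$pixel_stats,
                  ggplot2::aes(.data$mean, .data$variance)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$nr, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(
      x = "time-averaged normalized signal", y = "variance",
      title = sprintf("Pixel noise: NR = %.3g", object$nr)
    )
}

#' @method autoplot degradation_study
#' @export
autoplot.degradation_study <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$ratios[, c("nr", "roi_ratio", "event_ratio", "event_corr")],
    -"nr", names_to = "measure", values_to = "ratio"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$nr, .data$ratio,
                                     colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "noise ratio (NR)", y = "ratio vs NR = 0",
                  title = "Extraction degradation under injected noise")
}

#' @method autoplot pairwise_corr
#' @export
autoplot.pairwise_corr <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(width = 0.02) +
    ggplot2::labs(x = "pairwise correlation", y = "count",
                  title = "Pairwise ROI correlations")
}

#' Stacked dF/F traces of a trace bundle
#'
#' @param bundle a [trace_bundle()].
#' @param offset vertical offset between traces (dF/F units).
#' @param n_max plot at most this many ROIs.
#' @return a ggplot object.
#' @export
plot_traces <- function(bundle, offset = 0.5, n_max = 30) {
  stopifnot(inherits(bundle, "trace_bundle"))
  df <- bundle$traces %>%
    dplyr::filter(.data$roi <= n_max) %>%
    dplyr::mutate(y = .data$dff + (.data$roi - 1) * offset)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$y,
                                   group = .data$roi)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = sprintf("dF/F (offset %.2g)", offset))
}
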