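# ggplot2 renderers. Matrices are emitted raw by the builders; the gamma
# argument here is a lossless display transform only.

#' Plot a fragMap
#'
#' @param object A `dff_fragmap` object.
#' @param gamma Display gamma applied to counts (`count^gamma`); 1 = linear.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dff_fragmap <- function(object, gamma = 1, ...) {
  d <- tidy(object)
  d$display <- d$count^gamma
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$length,
                                  fill = .data$display)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick4",
                                 name = "count") +
    ggplot2::labs(x = "position relative to anchor (bp)",
                  y = "fragment length (bp)") +
    ggplot2::theme_minimal()
}

#' Plot a sorted coverage heatmap
#'
#' @param object A `dff_heatmap` object.
#' @param gamma Display gamma applied to counts.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dff_heatmap <- function(object, gamma = 1, ...) {
  d <- tidy(object)
  d$display <- d$count^gamma
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$row,
                                  fill = .data$display)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "navy",
                                 name = "coverage") +
    ggplot2::labs(x = "position relative to anchor (bp)",
                  y = "region (sorted)") +
    ggplot2::theme_minimal()
}

#' Plot a fragment-center profile
#'
#' @param object A `dff_profile` tibble from [center_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dff_profile <- function(object, ...) {
  sc <- attr(object, "size_class")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "center position relative to anchor (bp)",
      y = "normalized density",
      title = sprintf("fragment centers, %d-%d bp class", sc[1], sc[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot called peaks
#'
#' Summit positions against reads in peak, one panel per chromosome.
#'
#' @param object A `dff_peaks` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dff_peaks <- function(object, ...) {
  d <- object$peaks
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mu, y = .data$reads_in_peak)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mu, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "fitted summit (bp)", y = "reads in peak") +
    ggplot2::theme_minimal()
}
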