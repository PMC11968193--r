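#' Manhattan-style scan plot
#'
#' @param scan tibble with `chrom`, `pos` and the statistic named by `y`
#'   (e.g. `fst`, `std`, `stat`).
#' @param y column to plot (default `"fst"`).
#' @param threshold optional horizontal reference line.
#' @param highlight optional interval tibble (`chrom`, `start`, `end`) shaded
#'   behind the points, e.g. outlier windows or gene intervals.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, y = "fst", threshold = NULL,
                           highlight = NULL) {
  p <- ggplot2::ggplot(scan, ggplot2::aes(x = .data$pos, y = .data[[y]]))
  if (!is.null(highlight) && nrow(highlight) > 0) {
    p <- p + ggplot2::geom_rect(
      data = highlight, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "goldenrod", alpha = 0.3)
  }
  p <- p + ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = y)
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "firebrick")
  p
}

#' @rdname pca_structure
#' @param object a `migscan_pca`.
#' @param popmap optional tibble (`sample`, `population`) colouring scores.
#' @method autoplot migscan_pca
#' @export
autoplot.migscan_pca <- function(object, popmap = NULL, ...) {
  df <- object$scores
  if (!is.null(popmap))
    df <- dplyr::left_join(df, popmap, by = "sample")
  aes <- if (!is.null(popmap))
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$population)
  else ggplot2::aes(.data$PC1, .data$PC2)
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "PC1", y = "PC2")
}

#' @rdname classify_parallelism
#' @param object a `parallelism_report`.
#' @method autoplot parallelism_report
#' @export
autoplot.parallelism_report <- function(object, ...) {
  v <- object$venn[object$venn$count > 0 | !grepl("&", object$venn$region), ]
  ggplot2::ggplot(v, ggplot2::aes(x = stats::reorder(.data$region, -.data$count),
                                  y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Venn region", y = "items",
                  title = sprintf("%s-level parallelism", object$level))
}

#' Plot an EHH decay curve
#'
#' @param curve tibble from [ehh()].
#' @return A ggplot object.
#' @export
plot_ehh_decay <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$distance_bp, .data$ehh)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance from core (bp)", y = "EHH")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
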