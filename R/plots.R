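#' Manhattan plot of a genome scan
#'
#' @param scan A `leaf_scan` from [run_scan()].
#' @param use `"raw"` or `"gc"` p-values.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, use = c("gc", "raw")) {
  use <- match.arg(use)
  df <- tibble::as_tibble(scan) |>
    dplyr::mutate(
      score = -log10(if (use == "gc") .data$p_gc else .data$p_raw),
      chrom = factor(.data$chrom)
    ) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(x = .data$pos / max(.data$pos)) |>
    dplyr::ungroup() |>
    dplyr::mutate(x = as.numeric(.data$chrom) - 1 + .data$x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$score,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.7, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(attr(scan, "threshold")),
                        linetype = "dashed") +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](italic(p)))) +
    ggplot2::scale_x_continuous(
      breaks = seq_along(levels(df$chrom)) - 0.5,
      labels = levels(df$chrom)
    ) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of scan p-values
#'
#' @inheritParams plot_manhattan
#' @return A ggplot object.
#' @export
plot_qq <- function(scan, use = c("raw", "gc")) {
  use <- match.arg(use)
  df <- qq_table(scan, use)
  lab <- sprintf("lambda[GC] == %.3f", attr(scan, "lambda_gc"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::annotate("text", x = 0.5, y = max(df$observed),
                      label = lab, parse = TRUE, hjust = 0) +
    ggplot2::labs(x = expression(Expected ~ -log[10](italic(p))),
                  y = expression(Observed ~ -log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `leaf_scan` objects draw a Manhattan plot; `radial_profile` objects draw
#' the polar outline; `leaf_contour` objects draw the boundary.
#'
#' @param object The object to plot.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot object.
#' @export
autoplot.leaf_scan <- function(object, ...) plot_manhattan(object, ...)

#' @rdname autoplot.leaf_scan
#' @export
autoplot.radial_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius * cos(.data$angle),
                                   y = .data$radius * sin(.data$angle))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_path(alpha = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = attr(object, "kind")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.leaf_scan
#' @export
autoplot.leaf_contour <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
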