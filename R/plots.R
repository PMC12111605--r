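#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Manhattan plot of a selection scan
#'
#' @param object a `sweep_scan` tibble.
#' @param y column to plot (`"neglog10_p"` or `"score"`).
#' @param threshold optional horizontal significance line.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sweep_scan <- function(object, y = "neglog10_p", threshold = NULL,
                                ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$pos / 1e6, y = .data[[y]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, na.rm = TRUE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = y,
                  title = paste(toupper(attr(object, "method") %||% ""),
                                "scan")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, colour = "red",
                                 linetype = 2)
  }
  p
}

#' Manhattan plot of ROH island coverage
#'
#' @param object a `roh_island` tibble.
#' @param ... unused.
#' @return A ggplot with the island significance threshold drawn.
#' @export
autoplot.roh_island <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos / 1e6,
                                       y = .data$percent)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        colour = "red", linetype = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "% individuals in ROH") +
    ggplot2::theme_minimal()
}

#' ROH length-class spectrum plot
#'
#' @param spectrum output of [classify_spectrum()].
#' @param what `"n"` (counts) or `"mean_length_bp"`.
#' @return A ggplot bar chart, dodged by population when present.
#' @export
plot_roh_spectrum <- function(spectrum, what = c("n", "mean_length_bp")) {
  what <- match.arg(what)
  aes <- if ("pop" %in% names(spectrum)) {
    ggplot2::aes(x = .data$class, y = .data[[what]], fill = .data$pop)
  } else {
    ggplot2::aes(x = .data$class, y = .data[[what]])
  }
  ggplot2::ggplot(spectrum, aes) +
    ggplot2::geom_col(position = "dodge", na.rm = TRUE) +
    ggplot2::labs(x = "ROH length class",
                  y = if (what == "n") "segments" else "mean length (bp)") +
    ggplot2::theme_minimal()
}

#' Ne trajectory plot
#'
#' @param object a [ne_trajectory()] tibble.
#' @param ... unused.
#' @return A ggplot of Ne against generations ago (log-log).
#' @export
autoplot.ne_point <- function(object, ...) plot_ne_trajectory(object)

#' @rdname autoplot.ne_point
#' @param ne a [ne_trajectory()] tibble.
#' @export
plot_ne_trajectory <- function(ne) {
  ggplot2::ggplot(ne, ggplot2::aes(x = .data$t, y = .data$ne)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations ago (t = 1/2c)", y = "Ne") +
    ggplot2::theme_minimal()
}

#' PCA scatter plot
#'
#' @param object a `sweep_pca` from [grm_pca()].
#' @param pop optional population label per individual.
#' @param ... unused.
#' @return A ggplot of PC1 vs PC2 with percent variance in the axis
#'   labels.
#' @export
autoplot.sweep_pca <- function(object, pop = NULL, ...) {
  d <- object$scores
  if (!is.null(pop)) d$pop <- as.character(pop)
  aes <- if (is.null(pop)) ggplot2::aes(.data$PC1, .data$PC2) else
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$pop)
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.2f%%)", object$pct_var[1]),
                  y = sprintf("PC2 (%.2f%%)", object$pct_var[2])) +
    ggplot2::theme_minimal()
}

#' EHH decay plot
#'
#' @param object an `ehh_decay` from [ehh_at()]/[ehhs_at()].
#' @param ... unused.
#' @return A ggplot of the decay curve with the focal SNP marked.
#' @export
autoplot.ehh_decay <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$pos / 1e6,
                                              y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$focal_pos / 1e6,
                        linetype = 3) +
    ggplot2::labs(x = "position (Mb)", y = "EHH") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
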