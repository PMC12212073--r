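# ggplot2 views of the two result types: ADC value histograms (spike
# inspection) and compression reports (relative file sizes per method and
# bit depth).

#' Plot an ADC value histogram
#'
#' Frequency of each ADC value; injected or hardware spike artifacts show
#' as isolated vertical excursions on an otherwise smooth bimodal curve.
#'
#' @param object An [value_histogram()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot exzd_histogram
#' @export
autoplot.exzd_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$count)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "firebrick") +
    ggplot2::labs(x = "ADC value", y = "Frequency") +
    ggplot2::theme_minimal()
}

#' Plot a compression report
#'
#' Compressed size relative to the lossless baseline, grouped by method,
#' one bar per lossy bit depth.
#'
#' @param object A [compression_report()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot exzd_report
#' @export
autoplot.exzd_report <- function(object, ...) {
  object$bits <- factor(object$eliminate_bits)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$method, y = .data$pct_of_baseline,
                               fill = .data$bits)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Size, % of lossless baseline",
                  fill = "bits removed") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
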