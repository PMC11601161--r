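#' Plot a coverage-versus-error curve
#'
#' Sensitivity on the x axis, false-positive errors per query on a log y
#' axis, the layout conventional for homology-search benchmarks.
#'
#' @param object A [cve_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cve_curve
#' @export
autoplot.cve_curve <- function(object, ...) {
  df <- dplyr::filter(object, .data$fpepq > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tpr, y = .data$fpepq)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sensitivity (TPR over homolog pairs)",
                  y = "false-positive errors per query",
                  title = "Coverage versus error")
}

#' Plot a top-hit category curve
#'
#' @param object A [cate_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cate_curve
#' @export
autoplot.cate_curve <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$top_hit_accuracy), .data$fcr > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$top_hit_accuracy, y = .data$fcr)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fraction of queries with homologous top hit",
                  y = "false category rate",
                  title = "Top-hit category accuracy versus error")
}

#' Plot measured versus nominal E-value
#'
#' The diagonal marks perfect calibration (measured FPEPQ equal to the
#' nominal E-value threshold).
#'
#' @param object An [evalue_vs_fpepq()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evcal_curve
#' @export
autoplot.evcal_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$e_threshold, y = .data$fpepq)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "nominal E-value threshold",
                  y = "measured FPEPQ",
                  title = "E-value calibration")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
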