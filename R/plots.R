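#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot an ABP record
#'
#' Waveform with detected or annotated beat positions overlaid.
#'
#' @param object An [abp_record()].
#' @param beats Optional `beat_series` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abp_record
#' @export
autoplot.abp_record <- function(object, beats = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$pressure)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Pressure") +
    ggplot2::theme_minimal()
  ann <- abp_annotations(object)
  if (is.null(beats) && !is.null(ann)) {
    p <- p + ggplot2::geom_point(
      data = object[ann, ], colour = "firebrick", size = 0.8
    )
  }
  if (!is.null(beats)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(time = beats$peak_time,
                            pressure = beats$peak_amplitude),
      colour = "firebrick", size = 0.8
    )
  }
  p
}

#' Plot a feature importance table
#'
#' Lollipop chart of both importance scores, selected features highlighted.
#'
#' @param object An `importance_tbl`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot importance_tbl
#' @export
autoplot.importance_tbl <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("mda", "gini"),
                            names_to = "score", values_to = "value")
  df$score <- factor(df$score, c("mda", "gini"),
                     c("Mean decrease in accuracy", "Mean decrease in Gini"))
  df$feature <- stats::reorder(df$feature, df$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$feature,
                                   colour = factor(.data$h))) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$feature),
                          linewidth = 0.4) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~score, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`0` = "grey60", `1` = "firebrick"),
                                 name = "selected (h)") +
    ggplot2::labs(x = "Importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Mean and standard deviation of accuracy, kappa and per-class kappa over
#' the repeated hold-out runs.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  s <- object$summary
  pct <- ifelse(s$metric == "accuracy", 1, 100)
  df <- tibble::tibble(metric = factor(s$metric, levels = s$metric),
                       mean = s$mean * pct, sd = s$sd * pct)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "Score (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
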