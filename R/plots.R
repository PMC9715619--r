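#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot method-by-task performance of an experiment
#'
#' @param object A `moodcast_experiment`.
#' @param metric Which report column to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moodcast_experiment <- function(object, metric = "mae", ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$method, y = .data[[metric]],
                               fill = .data$method)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = NULL, y = metric,
                  title = "PHQ-2 performance by strategy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot per-subject MAE across methods
#'
#' Subjects on the x axis, sorted from best to worst under
#' `reference_method`, one bar group per method - showing how unevenly each
#' strategy's errors distribute over individuals.
#'
#' @param object A `moodcast_fairness` report.
#' @param task Task to display.
#' @param reference_method Method defining the subject ordering.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moodcast_fairness <- function(object, task = "prediction",
                                       reference_method = "baseline", ...) {
  ps <- attr(object, "per_subject")
  ps <- ps[ps$task == task, ]
  ref <- ps[ps$method == reference_method, ]
  lv <- ref$subject_id[order(ref$mae)]
  ps$subject_id <- factor(ps$subject_id, levels = lv)
  ggplot2::ggplot(ps, ggplot2::aes(x = .data$subject_id, y = .data$mae,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "subject (best to worst under reference)",
                  y = "MAE", fill = NULL,
                  title = sprintf("Per-subject PHQ-2 %s error", task)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the top random-forest feature importances
#'
#' @param importances Output of [feature_importance()].
#' @param top_n How many features to show.
#' @return A ggplot.
#' @export
plot_feature_importance <- function(importances, top_n = 10) {
  top <- utils::head(importances[order(importances$rank), ], top_n)
  top$feature <- factor(top$feature, levels = rev(top$feature))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$importance,
                                    y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "normalised importance", y = NULL,
                  title = sprintf("Top %d features for PHQ-2", top_n)) +
    ggplot2::theme_minimal()
}
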