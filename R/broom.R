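#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-window predictions of an experiment
#'
#' @param x A `moodcast_experiment`.
#' @param ... Unused.
#' @return The predictions tibble (one row per test window).
#' @export
tidy.moodcast_experiment <- function(x, ...) x$predictions

#' One-row-per-cell performance summary of an experiment
#'
#' @param x A `moodcast_experiment`.
#' @param ... Unused.
#' @return The report tibble (method x task MAE and Spearman metrics).
#' @export
glance.moodcast_experiment <- function(x, ...) x$report

#' Per-subject MAE table behind a fairness report
#'
#' @param x A `moodcast_fairness` report.
#' @param ... Unused.
#' @return Tibble with one row per subject x method x task.
#' @export
tidy.moodcast_fairness <- function(x, ...) attr(x, "per_subject")

#' Fitted-model summary
#'
#' @param x A `moodcast_model`.
#' @param ... Unused.
#' @return One-row tibble with strategy, owner, selected epoch, development
#'   MAE and parameter count.
#' @export
glance.moodcast_model <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, owner = x$owner,
                 selected_epoch = x$selected_epoch, dev_mae = x$dev_mae,
                 n_parameters = n_parameters(x))
}
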