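#' Group-level sex fairness of a prediction set
#'
#' Two complementary scores, both ideally 0. The sex fairness score is the
#' difference in MAE between female and male test samples
#' (`MAE_female - MAE_male`): positive values mean worse performance for
#' females. The sex fairness bias is the difference in mean signed
#' residuals (`mean(yhat_f - y_f) - mean(yhat_m - y_m)`): positive values
#' mean the model systematically predicts females as more depressed,
#' after accounting for the groups' label distributions.
#'
#' @param results Tibble with `y`, `yhat`, `sex`.
#' @return One-row tibble with group MAEs, mean residuals and both scores.
#' @export
sex_fairness <- function(results) {
  f <- results[results$sex == "female", ]
  m <- results[results$sex == "male", ]
  if (nrow(f) == 0 || nrow(m) == 0) {
    stop("both sexes must be present in the results", call. = FALSE)
  }
  tibble::tibble(
    mae_female = mae(f), mae_male = mae(m),
    mean_residual_female = mean(f$yhat - f$y),
    mean_residual_male = mean(m$yhat - m$y),
    sex_fairness_score = mae(f) - mae(m),
    sex_fairness_bias = mean(f$yhat - f$y) - mean(m$yhat - m$y),
    n_female = nrow(f), n_male = nrow(m))
}

#' Gini coefficient of per-subject errors
#'
#' `GC = sum_ij |MAE_i - MAE_j| / (2 n^2 mean(MAE))`: 0 when performance is
#' identical across subjects, approaching 1 when a few subjects carry much
#' higher error than the rest. Defined as 0 when the mean MAE is 0
#' (perfectly equal and perfectly accurate).
#'
#' @param per_subject_mae Non-negative per-subject MAE values.
#' @return The coefficient, in `[0, 1 - 1/n]`.
#' @export
gini_coefficient <- function(per_subject_mae) {
  x <- per_subject_mae
  stopifnot(length(x) >= 1, all(is.finite(x)))
  if (any(x < 0)) stop("MAE values must be non-negative", call. = FALSE)
  mu <- mean(x)
  if (mu == 0) return(0)
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mu)
}

#' Distance-to-median indices of per-subject errors
#'
#' Splits subjects at the median per-subject MAE (even-sized sets use the
#' midpoint of the two central values) and sums the absolute distances to
#' it: DMLI over subjects strictly below the median ("winners" - higher is
#' better), DMUI over subjects strictly above it ("losers" - lower is
#' better). Subjects exactly at the median contribute to neither.
#'
#' @param per_subject_mae Per-subject MAE values.
#' @return One-row tibble with `dmli`, `dmui` and `median_mae`.
#' @export
distance_to_median_indices <- function(per_subject_mae) {
  x <- per_subject_mae
  stopifnot(length(x) >= 1, all(is.finite(x)))
  med <- stats::median(x)
  tibble::tibble(
    dmli = sum(abs(x[x < med] - med)),
    dmui = sum(abs(x[x > med] - med)),
    median_mae = med)
}

#' Per-subject MAE over pooled test predictions
#'
#' @param results Prediction tibble with `subject_id`, `y`, `yhat` (and
#'   optionally `sex`).
#' @return Tibble with one row per subject.
#' @export
per_subject_mae <- function(results) {
  by <- intersect(c("subject_id", "sex"), names(results))
  mae(results, by = by)
}

#' Fairness report across methods and tasks
#'
#' For every method x task cell of an experiment: the group-level sex
#' fairness score and bias, and the individual-level Gini coefficient and
#' distance-to-median indices of the per-subject MAEs. The per-subject MAE
#' vectors behind the individual-level indices are attached for plotting.
#'
#' @param x A `moodcast_experiment` or its predictions tibble.
#' @return Tibble of class `moodcast_fairness`, one row per method x task,
#'   with the per-subject table in `attr(, "per_subject")`.
#' @export
fairness_report <- function(x) {
  results <- if (inherits(x, "moodcast_experiment")) x$predictions else x
  stopifnot(nrow(results) > 0)
  cells <- split(results, list(results$task, results$method), drop = TRUE)
  per_subject <- dplyr::bind_rows(lapply(cells, function(p) {
    dplyr::bind_cols(tibble::tibble(task = p$task[1], method = p$method[1]),
                     per_subject_mae(p))
  }))
  out <- dplyr::bind_rows(lapply(cells, function(p) {
    ps <- per_subject_mae(p)
    gf <- sex_fairness(p)
    dm <- distance_to_median_indices(ps$mae)
    tibble::tibble(
      task = p$task[1], method = p$method[1],
      sex_fairness_score = gf$sex_fairness_score,
      sex_fairness_bias = gf$sex_fairness_bias,
      gini = gini_coefficient(ps$mae),
      dmli = dm$dmli, dmui = dm$dmui,
      n_subjects = nrow(ps))
  }))
  out <- dplyr::arrange(out, .data$task,
                        match(.data$method, c("baseline",
                                              "transfer_learning",
                                              "subgroup", "sds")))
  attr(out, "per_subject") <- per_subject
  class(out) <- c("moodcast_fairness", class(out))
  out
}
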