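#' Data-quality configuration
#'
#' The three criteria applied before modelling: (1) a subject-day is valid
#' only if strictly less than `max_day_missing_rate` of the feature columns
#' are missing; (2) a PHQ label is kept only if at least
#' `min_valid_days_per_label` of its 7-day window are valid; (3) a subject
#' is kept only with at least `min_phq2_labels` retained PHQ-2 and
#' `min_phq9_labels` retained PHQ-9 entries.
#'
#' @param max_day_missing_rate Strict upper bound on the per-day missing
#'   fraction (default 0.20).
#' @param min_valid_days_per_label Minimum valid days in a label's window.
#' @param min_phq2_labels,min_phq9_labels Per-subject label minima.
#' @param prediction_includes_label_day Whether the 7-day window of the
#'   prediction task ends on (and includes) the label day; the forecasting
#'   window always ends the day before.
#' @return A list of class `quality_config`.
#' @export
quality_config <- function(max_day_missing_rate = 0.20,
                           min_valid_days_per_label = 5,
                           min_phq2_labels = 10,
                           min_phq9_labels = 5,
                           prediction_includes_label_day = TRUE) {
  stopifnot(max_day_missing_rate > 0, max_day_missing_rate <= 1,
            min_valid_days_per_label >= 1, min_phq2_labels >= 1,
            min_phq9_labels >= 1)
  structure(list(max_day_missing_rate = max_day_missing_rate,
                 min_valid_days_per_label = min_valid_days_per_label,
                 min_phq2_labels = min_phq2_labels,
                 min_phq9_labels = min_phq9_labels,
                 prediction_includes_label_day =
                   prediction_includes_label_day),
            class = "quality_config")
}

#' Flag valid subject-days (quality criterion 1)
#'
#' A day is valid iff its missing fraction over the feature universe is
#' strictly below the configured rate.
#'
#' @param features Daily feature table ([extract_features()]).
#' @param config A [quality_config()].
#' @param feature_universe Columns counted; defaults to all configured
#'   feature columns.
#' @return `features` with `n_missing` and `valid` columns appended.
#' @export
validate_days <- function(features, config = quality_config(),
                          feature_universe = feature_columns()) {
  if (length(feature_universe) == 0) {
    stop("empty feature universe", call. = FALSE)
  }
  stopifnot(all(feature_universe %in% names(features)))
  miss <- rowSums(is.na(features[, feature_universe, drop = FALSE]))
  features$n_missing <- miss
  features$valid <- (miss / length(feature_universe)) <
    config$max_day_missing_rate
  features
}

# the 7 calendar days feeding a label
window_dates <- function(label_date, task, config) {
  if (task == "prediction" && config$prediction_includes_label_day) {
    label_date - 6:0
  } else {
    label_date - 7:1
  }
}

#' Retain labels with enough valid context (quality criterion 2)
#'
#' A label is retained iff at least `min_valid_days_per_label` of the 7
#' days of its window (ending on the label day for the prediction task, on
#' the day before for forecasting; PHQ-9 uses the prediction convention)
#' are valid.
#'
#' @param days Output of [validate_days()].
#' @param labels Label table ([cohort_labels()]).
#' @param task `"prediction"` or `"forecasting"`.
#' @param config A [quality_config()].
#' @return `labels` with `phq2_window_valid`, `phq2_retained`,
#'   `phq9_window_valid`, `phq9_retained` columns.
#' @export
select_valid_labels <- function(days, labels,
                                task = c("prediction", "forecasting"),
                                config = quality_config()) {
  task <- match.arg(task)
  stopifnot("valid" %in% names(days))
  valid_key <- paste(days$subject_id, days$date)[days$valid]
  count_valid <- function(subject_id, label_date, tk) {
    wd <- window_dates(label_date, tk, config)
    sum(paste(subject_id, wd) %in% valid_key)
  }
  labels$phq2_window_valid <- NA_integer_
  labels$phq9_window_valid <- NA_integer_
  has2 <- !is.na(labels$phq2)
  has9 <- !is.na(labels$phq9)
  labels$phq2_window_valid[has2] <- mapply(
    count_valid, labels$subject_id[has2], labels$date[has2],
    MoreArgs = list(tk = task))
  labels$phq9_window_valid[has9] <- mapply(
    count_valid, labels$subject_id[has9], labels$date[has9],
    MoreArgs = list(tk = "prediction"))
  labels$phq2_retained <- has2 &
    labels$phq2_window_valid >= config$min_valid_days_per_label
  labels$phq9_retained <- has9 &
    labels$phq9_window_valid >= config$min_valid_days_per_label
  labels$phq2_retained[is.na(labels$phq2_retained)] <- FALSE
  labels$phq9_retained[is.na(labels$phq9_retained)] <- FALSE
  labels
}

#' Retain subjects with enough labels (quality criterion 3)
#'
#' @param labels Output of [select_valid_labels()].
#' @param config A [quality_config()].
#' @return Tibble with per-subject retained label counts and a `retained`
#'   flag.
#' @export
filter_subjects <- function(labels, config = quality_config()) {
  out <- dplyr::summarise(
    dplyr::group_by(labels, .data$subject_id),
    n_phq2 = sum(.data$phq2_retained),
    n_phq9 = sum(.data$phq9_retained),
    .groups = "drop")
  out$retained <- out$n_phq2 >= config$min_phq2_labels &
    out$n_phq9 >= config$min_phq9_labels
  out
}

#' Apply all three quality criteria
#'
#' Runs criteria 1-3 in sequence and reports the retention funnel
#' (how many subject-days, labels and subjects survive each criterion).
#'
#' @param features Daily feature table.
#' @param labels Label table.
#' @param task `"prediction"` or `"forecasting"`.
#' @param config A [quality_config()].
#' @return A list of class `quality_filter` with elements `days` (validated
#'   feature rows), `labels` (with retention flags; criterion 3 applied),
#'   `subjects`, `funnel` (stage counts), `task` and `config`.
#' @export
quality_filter <- function(features, labels,
                           task = c("prediction", "forecasting"),
                           config = quality_config()) {
  task <- match.arg(task)
  days <- validate_days(features, config)
  labels <- select_valid_labels(days, labels, task, config)
  subjects <- filter_subjects(labels, config)
  kept <- subjects$subject_id[subjects$retained]
  labels$subject_retained <- labels$subject_id %in% kept
  funnel <- tibble::tibble(
    stage = c("subjects", "subject_days", "valid_days",
              "phq2_labels", "phq2_labels_after_criterion2",
              "phq9_labels", "phq9_labels_after_criterion2",
              "subjects_after_criterion3", "phq2_labels_final"),
    n = c(length(unique(features$subject_id)),
          nrow(days), sum(days$valid),
          sum(!is.na(labels$phq2)), sum(labels$phq2_retained),
          sum(!is.na(labels$phq9)), sum(labels$phq9_retained),
          length(kept),
          sum(labels$phq2_retained & labels$subject_retained)))
  structure(list(days = days, labels = labels, subjects = subjects,
                 funnel = funnel, task = task, config = config),
            class = "quality_filter")
}

#' @export
print.quality_filter <- function(x, ...) {
  cat(sprintf("<quality_filter> task = %s\n", x$task))
  print(x$funnel)
  invisible(x)
}

#' Complete a label's 7-day feature block by weekly-mean imputation
#'
#' Each missing cell is filled with the mean of that feature over the
#' window days where it is observed. A feature missing on all 7 days falls
#' back to the subject's past mean (days up to the label date), then to the
#' population past mean; fallback use is flagged. Observed cells are never
#' altered.
#'
#' @param features Daily feature table (all subjects; used for fallbacks).
#' @param subject_id,label_date The label whose block to complete.
#' @param task `"prediction"` or `"forecasting"`.
#' @param config A [quality_config()].
#' @return List with `block` (7-row tibble, chronological), `imputed`
#'   (logical matrix), `fallback` (character vector of features that needed
#'   a fallback).
#' @export
impute_weekly_mean <- function(features, subject_id, label_date,
                               task = c("prediction", "forecasting"),
                               config = quality_config()) {
  task <- match.arg(task)
  fcols <- feature_columns()
  wd <- window_dates(label_date, task, config)
  sub <- features[features$subject_id == subject_id, ]
  block <- sub[match(wd, sub$date), c("date", fcols)]
  block$date <- wd
  imputed <- is.na(as.matrix(block[, fcols]))
  fallback <- character(0)
  for (f in fcols) {
    v <- block[[f]]
    if (!anyNA(v)) next
    obs <- v[!is.na(v)]
    if (length(obs) > 0) {
      v[is.na(v)] <- mean(obs)
    } else {
      past <- sub[[f]][sub$date <= label_date]
      fill <- if (any(!is.na(past))) mean(past, na.rm = TRUE) else {
        pop <- features[[f]][features$date <= label_date]
        mean(pop, na.rm = TRUE)
      }
      v[] <- fill
      fallback <- c(fallback, f)
    }
    block[[f]] <- v
  }
  list(block = block, imputed = imputed, fallback = fallback)
}

#' Build labelled 7-day windows
#'
#' One window per retained PHQ-2 label of each retained subject: a
#' chronological 7-day feature block (imputed via [impute_weekly_mean()])
#' paired with the PHQ-2 target. Prediction windows end on the label day;
#' forecasting windows end the day before. Labels whose window would start
#' before the subject's first observed day are skipped and counted in
#' `attr(, "skipped_underflow")`.
#'
#' @param qf A [quality_filter()] result.
#' @return Tibble with `window_id`, `subject_id`, `sex`, `label_date`,
#'   `task`, `target`, and list-columns `sequence` (7 x n_features matrix,
#'   oldest day first) and `imputed`. The feature ordering is recorded in
#'   `attr(, "feature_order")`.
#' @export
build_windows <- function(qf) {
  stopifnot(inherits(qf, "quality_filter"))
  fcols <- feature_columns()
  lab <- qf$labels[qf$labels$phq2_retained & qf$labels$subject_retained, ]
  first_day <- dplyr::summarise(
    dplyr::group_by(qf$days, .data$subject_id),
    first = min(.data$date), .groups = "drop")
  skipped <- 0L
  rows <- vector("list", nrow(lab))
  for (k in seq_len(nrow(lab))) {
    sid <- lab$subject_id[k]; ld <- lab$date[k]
    wd <- window_dates(ld, qf$task, qf$config)
    if (min(wd) < first_day$first[first_day$subject_id == sid]) {
      skipped <- skipped + 1L
      next
    }
    imp <- impute_weekly_mean(qf$days, sid, ld, qf$task, qf$config)
    seq_mat <- as.matrix(imp$block[, fcols])
    rownames(seq_mat) <- NULL
    rows[[k]] <- tibble::tibble(
      subject_id = sid, sex = lab$sex[k], label_date = ld,
      task = qf$task, target = lab$phq2[k],
      sequence = list(seq_mat), imputed = list(imp$imputed))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out <- dplyr::arrange(out, .data$subject_id, .data$label_date)
    out$window_id <- seq_len(nrow(out))
    out <- out[, c("window_id", "subject_id", "sex", "label_date", "task",
                   "target", "sequence", "imputed")]
  }
  attr(out, "feature_order") <- fcols
  attr(out, "skipped_underflow") <- skipped
  out
}

#' Fit a feature standardiser on training windows
#'
#' Per-feature z-scoring statistics computed over all day-rows of the
#' training windows, either pooled (`population`) or separately per subject
#' (`per_subject`). Features with zero training variance get sd 1, so their
#' training values map to 0.
#'
#' @param windows Training windows ([build_windows()]).
#' @param scope `"population"` or `"per_subject"`.
#' @return Object of class `standardiser`.
#' @export
fit_standardiser <- function(windows, scope = c("population",
                                                "per_subject")) {
  scope <- match.arg(scope)
  stopifnot(nrow(windows) > 0)
  fcols <- attr(windows, "feature_order") %||% feature_columns()
  stacked <- do.call(rbind, windows$sequence)
  sid <- rep(windows$subject_id, each = nrow(windows$sequence[[1]]))
  one <- function(mat) {
    mu <- colMeans(mat)
    sd <- apply(mat, 2, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    tibble::tibble(feature = fcols, mean = unname(mu), sd = unname(sd))
  }
  stats_tbl <- if (scope == "population") {
    dplyr::bind_cols(tibble::tibble(subject_id = NA_character_),
                     one(stacked))[, c("subject_id", "feature", "mean",
                                       "sd")]
  } else {
    dplyr::bind_rows(lapply(unique(sid), function(s) {
      dplyr::bind_cols(tibble::tibble(subject_id = s),
                       one(stacked[sid == s, , drop = FALSE]))
    }))
  }
  structure(list(scope = scope, stats = stats_tbl, feature_order = fcols),
            class = "standardiser")
}

#' Apply a fitted standardiser to windows
#'
#' @param std A [fit_standardiser()] result.
#' @param windows Windows to transform.
#' @return The windows with z-scored sequences; the scope is recorded in
#'   `attr(, "standardised_scope")`. Under `per_subject` scope, windows
#'   from subjects absent at fit time are an error.
#' @export
apply_standardiser <- function(std, windows) {
  stopifnot(inherits(std, "standardiser"))
  fcols <- std$feature_order
  get_ms <- function(sid) {
    s <- if (std$scope == "population") {
      std$stats
    } else {
      hit <- std$stats[!is.na(std$stats$subject_id) &
                         std$stats$subject_id == sid, ]
      if (nrow(hit) == 0) {
        stop("subject ", sid, " unseen by per-subject standardiser",
             call. = FALSE)
      }
      hit
    }
    list(mean = s$mean[match(fcols, s$feature)],
         sd = s$sd[match(fcols, s$feature)])
  }
  windows$sequence <- lapply(seq_len(nrow(windows)), function(k) {
    ms <- get_ms(windows$subject_id[k])
    mat <- windows$sequence[[k]][, fcols, drop = FALSE]
    sweep(sweep(mat, 2, ms$mean, "-"), 2, ms$sd, "/")
  })
  attr(windows, "feature_order") <- fcols
  attr(windows, "standardised_scope") <- std$scope
  windows
}
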