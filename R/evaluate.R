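#' Subject-dependent cross-validation splits
#'
#' Splits every subject's windows into `n_folds` chronological segments.
#' For CV round r, segment r of every subject is the test set; the
#' remaining windows are split per subject into the first 80% (train) and
#' the most recent 20% (development). Every subject therefore contributes
#' windows to train, development and test in every round, and the test
#' folds partition each subject's windows.
#'
#' @param windows Output of [build_windows()].
#' @param n_folds Number of folds (default 3).
#' @param dev_fraction Development share of the non-test windows.
#' @param seed Seed, used only when `chronological = FALSE`.
#' @param chronological Chronological (default) or random per-subject fold
#'   assignment.
#' @return Object of class `cv_splits`: list with `folds` (window_id,
#'   subject_id, fold) and `roles` (window_id, round, role).
#' @export
make_cv_splits <- function(windows, n_folds = 3, dev_fraction = 0.2,
                           seed = 1, chronological = TRUE) {
  stopifnot(nrow(windows) > 0, n_folds >= 2,
            dev_fraction > 0, dev_fraction < 1)
  counts <- table(windows$subject_id)
  if (any(counts < n_folds)) {
    stop("subjects with fewer than n_folds windows: ",
         paste(names(counts)[counts < n_folds], collapse = ", "),
         call. = FALSE)
  }
  ord_within <- function(id) {
    k <- windows$window_id[windows$subject_id == id]
    o <- order(windows$label_date[windows$subject_id == id])
    k <- k[o]
    if (!chronological) k <- sample(k)
    k
  }
  folds <- with_local_seed(seed, {
    dplyr::bind_rows(lapply(unique(windows$subject_id), function(id) {
      k <- ord_within(id)
      n <- length(k)
      tibble::tibble(window_id = k, subject_id = id,
                     fold = ceiling(seq_len(n) * n_folds / n),
                     pos = seq_len(n))
    }))
  })
  roles <- dplyr::bind_rows(lapply(seq_len(n_folds), function(r) {
    dplyr::bind_rows(lapply(split(folds, folds$subject_id), function(fs) {
      test <- fs$window_id[fs$fold == r]
      rem <- fs[fs$fold != r, ]
      rem <- rem[order(rem$pos), ]
      n_dev <- max(1L, ceiling(dev_fraction * nrow(rem)))
      dev <- utils::tail(rem$window_id, n_dev)
      train <- utils::head(rem$window_id, nrow(rem) - n_dev)
      tibble::tibble(
        window_id = c(train, dev, test),
        round = r,
        role = c(rep("train", length(train)), rep("dev", length(dev)),
                 rep("test", length(test))))
    }))
  }))
  structure(list(folds = folds[, c("window_id", "subject_id", "fold")],
                 roles = roles, n_folds = n_folds,
                 dev_fraction = dev_fraction,
                 chronological = chronological),
            class = "cv_splits")
}

#' Mean absolute error of a prediction set
#'
#' @param results Tibble with columns `y` and `yhat`.
#' @param by Optional grouping columns (e.g. `"subject_id"`, `"sex"`).
#' @return A scalar, or a tibble with one `mae` row per group. Empty input
#'   gives NA.
#' @export
mae <- function(results, by = NULL) {
  if (is.null(by)) {
    if (nrow(results) == 0) return(NA_real_)
    return(mean(abs(results$yhat - results$y)))
  }
  dplyr::summarise(dplyr::group_by(results, !!!rlang::syms(by)),
                   mae = mean(abs(.data$yhat - .data$y)),
                   n = dplyr::n(), .groups = "drop")
}

#' Spearman rank correlation between targets and predictions
#'
#' `spearman_global()` pools all samples; `spearman_local()` averages the
#' per-subject coefficients (subjects where the correlation is undefined -
#' fewer than two samples or a constant vector - are excluded and counted
#' in `attr(, "n_excluded")`). Ties receive average ranks.
#'
#' @param results Tibble with `y`, `yhat` (and `subject_id` for the local
#'   variant).
#' @return Correlation coefficient (NA when undefined).
#' @export
spearman_global <- function(results) {
  if (nrow(results) < 2 || stats::sd(results$y) == 0 ||
      stats::sd(results$yhat) == 0) {
    return(NA_real_)
  }
  stats::cor(results$y, results$yhat, method = "spearman")
}

#' @rdname spearman_global
#' @export
spearman_local <- function(results) {
  per <- lapply(split(results, results$subject_id), function(r) {
    if (nrow(r) < 2 || stats::sd(r$y) == 0 || stats::sd(r$yhat) == 0) {
      NA_real_
    } else {
      stats::cor(r$y, r$yhat, method = "spearman")
    }
  })
  per <- unlist(per)
  out <- if (all(is.na(per))) NA_real_ else mean(per[!is.na(per)])
  attr(out, "n_excluded") <- sum(is.na(per))
  out
}

#' Random-forest screen of feature relevance
#'
#' Trains a random-forest regressor (50 trees by default) of the daily
#' PHQ-2 score on the complete (imputed) daily feature matrix and reports
#' impurity-based importances, normalised to sum to one.
#'
#' @param x Complete feature matrix or data frame (one row per subject-day).
#' @param y Numeric targets.
#' @param n_trees Number of trees.
#' @param seed Seed for the forest's bootstrap sampling.
#' @return Tibble (`feature`, `importance`, `rank`), most important first.
#' @export
feature_importance <- function(x, y, n_trees = 50, seed = 1) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) > 0, nrow(x) == length(y), !anyNA(x))
  fit <- with_local_seed(seed, {
    randomForest::randomForest(x = x, y = y, ntree = n_trees)
  })
  imp <- fit$importance[, "IncNodePurity"]
  imp <- imp / sum(imp)
  out <- tibble::tibble(feature = names(imp), importance = unname(imp))
  out <- out[order(-out$importance), ]
  out$rank <- seq_len(nrow(out))
  out
}

canonical_method <- function(m) {
  map <- c(baseline = "baseline", b = "baseline",
           transfer_learning = "transfer_learning", tl = "transfer_learning",
           subgroup = "subgroup", s = "subgroup",
           sds = "sds")
  if (!all(m %in% names(map))) {
    stop("unknown method(s): ", paste(setdiff(m, names(map)),
                                      collapse = ", "), call. = FALSE)
  }
  unname(map[m])
}

#' Run the full prediction/forecasting experiment
#'
#' Extracts features, applies the quality criteria, builds labelled 7-day
#' windows, and evaluates the requested modelling strategies under
#' subject-dependent cross-validation, pooling test-fold predictions over
#' all rounds. The four strategies are the population `baseline`,
#' `transfer_learning` (shared frozen backbone, per-subject heads),
#' per-sex `subgroup` models, and `sds` (one model over subject-dependent
#' standardised inputs).
#'
#' @param cohort A `moodcast_cohort`.
#' @param tasks Any of `"prediction"` (PHQ-2 at the end of the day from
#'   the last 7 days) and `"forecasting"` (one day ahead).
#' @param methods Strategies to evaluate (aliases `tl`, `s`, `b` accepted).
#' @param quality A [quality_config()].
#' @param train A [train_config()]; its seed is combined with `seed`.
#' @param clustering Significant-place method for feature extraction.
#' @param seed Master seed for the experiment.
#' @param n_folds,dev_fraction Cross-validation layout.
#' @return Object of class `moodcast_experiment` with `predictions` (one
#'   row per test window: subject, sex, task, method, fold, y, yhat),
#'   `report` (method x task MAE / global and local Spearman), and
#'   `funnel` (quality-criterion retention counts per task).
#' @export
run_experiment <- function(cohort,
                           tasks = c("prediction", "forecasting"),
                           methods = c("baseline", "transfer_learning",
                                       "subgroup", "sds"),
                           quality = quality_config(),
                           train = train_config(),
                           clustering = "time_based",
                           seed = 1, n_folds = 3, dev_fraction = 0.2) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  methods <- canonical_method(methods)
  features <- extract_features(cohort, clustering = clustering)
  labels <- cohort_labels(cohort)
  preds <- list()
  funnels <- list()

  for (task in tasks) {
    qf <- quality_filter(features, labels, task, quality)
    funnels[[task]] <- dplyr::bind_cols(tibble::tibble(task = task),
                                        qf$funnel)
    windows <- build_windows(qf)
    if (nrow(windows) == 0) {
      stop("no windows survive the quality criteria for task ", task,
           call. = FALSE)
    }
    splits <- make_cv_splits(windows, n_folds = n_folds,
                             dev_fraction = dev_fraction, seed = seed)
    for (r in seq_len(n_folds)) {
      role <- splits$roles[splits$roles$round == r, ]
      pick <- function(which) {
        w <- windows[windows$window_id %in%
                       role$window_id[role$role == which], ]
        attr(w, "feature_order") <- attr(windows, "feature_order")
        w
      }
      tr <- pick("train"); dv <- pick("dev"); te <- pick("test")
      cfg <- train
      cfg$seed <- as.integer(seed * 100 + r)

      pop_std <- fit_standardiser(tr, "population")
      tr_p <- apply_standardiser(pop_std, tr)
      dv_p <- apply_standardiser(pop_std, dv)
      te_p <- apply_standardiser(pop_std, te)

      base <- NULL
      if (any(c("baseline", "transfer_learning") %in% methods)) {
        base <- train_baseline(tr_p, dv_p, config = cfg)
      }
      for (m in methods) {
        yhat <- switch(m,
          baseline = predict(base, te_p),
          transfer_learning = {
            tl <- personalise_transfer(base, tr_p, dv_p, cfg)
            predict(tl, te_p)
          },
          subgroup = {
            sg <- train_subgroup(tr_p, dv_p, config = cfg)
            predict(sg, te_p)
          },
          sds = {
            sub_std <- fit_standardiser(tr, "per_subject")
            sds <- train_sds(apply_standardiser(sub_std, tr),
                             apply_standardiser(sub_std, dv), config = cfg)
            predict(sds, apply_standardiser(sub_std, te))
          })
        preds[[length(preds) + 1]] <- tibble::tibble(
          subject_id = te$subject_id, sex = te$sex, task = task,
          method = m, fold = r, label_date = te$label_date,
          y = te$target, yhat = yhat)
      }
    }
  }
  predictions <- dplyr::bind_rows(preds)
  report <- dplyr::bind_rows(lapply(
    split(predictions, list(predictions$task, predictions$method),
          drop = TRUE),
    function(p) {
      loc <- spearman_local(p)
      tibble::tibble(task = p$task[1], method = p$method[1],
                     n = nrow(p), mae = mae(p),
                     spearman_global = spearman_global(p),
                     spearman_local = as.numeric(loc),
                     n_subjects_excluded_local = attr(loc, "n_excluded"))
    }))
  report <- dplyr::arrange(report, .data$task,
                           match(.data$method, c("baseline",
                                                 "transfer_learning",
                                                 "subgroup", "sds")))
  structure(list(predictions = predictions, report = report,
                 funnel = dplyr::bind_rows(funnels),
                 tasks = tasks, methods = methods, seed = seed,
                 quality = quality, train = train,
                 clustering = clustering),
            class = "moodcast_experiment")
}

#' @export
print.moodcast_experiment <- function(x, ...) {
  cat(sprintf("<moodcast_experiment> seed %d, %d predictions\n",
              x$seed, nrow(x$predictions)))
  print(x$report)
  invisible(x)
}
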