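# small synthetic feature/label tables used across the filtering tests
toy_days <- function(n_days = 20, n_missing_per_day = 0, universe = 24,
                     subject = "S01") {
  cols <- paste0("x", seq_len(universe))
  df <- tibble::as_tibble(
    stats::setNames(as.list(rep(1, universe)), cols))[rep(1, n_days), ]
  df$subject_id <- subject
  df$sex <- "female"
  df$date <- as.Date("2021-06-01") + seq_len(n_days) - 1
  if (length(n_missing_per_day) == 1) {
    n_missing_per_day <- rep(n_missing_per_day, n_days)
  }
  for (d in seq_len(n_days)) {
    if (n_missing_per_day[d] > 0) {
      df[d, cols[seq_len(n_missing_per_day[d])]] <- NA_real_
    }
  }
  df
}

test_that("a day is valid only strictly below the 20% missing rate", {
  uni <- paste0("x", 1:24)
  df <- toy_days(3, n_missing_per_day = c(0, 4, 5))
  v <- validate_days(df, quality_config(), feature_universe = uni)
  expect_equal(v$valid, c(TRUE, TRUE, FALSE))  # 0%, 16.7%, 20.8%
  expect_error(validate_days(df, quality_config(), feature_universe = character()),
               "empty")
})

test_that("labels need five valid days in their window", {
  uni <- paste0("x", 1:24)
  # invalid days made by missing 5/24 features
  mk <- function(invalid_days, label_day = 10) {
    miss <- rep(0, 20); miss[invalid_days] <- 5
    df <- toy_days(20, n_missing_per_day = miss)
    labels <- tibble::tibble(subject_id = "S01", sex = "female",
                             date = as.Date("2021-06-01") + label_day - 1,
                             phq2 = 3, phq9 = NA_real_)
    v <- validate_days(df, quality_config(), feature_universe = uni)
    select_valid_labels(v, labels, "prediction", quality_config())
  }
  expect_true(mk(integer(0))$phq2_retained)          # 7/7 valid
  expect_true(mk(c(4, 5))$phq2_retained)             # exactly 5 valid
  expect_false(mk(c(4, 5, 6))$phq2_retained)         # 4 valid
  # forecasting window excludes the label day: invalidating it changes nothing
  miss <- rep(0, 20); miss[10] <- 5
  df <- toy_days(20, n_missing_per_day = miss)
  v <- validate_days(df, quality_config(), feature_universe = uni)
  labels <- tibble::tibble(subject_id = "S01", sex = "female",
                           date = as.Date("2021-06-10"), phq2 = 3,
                           phq9 = NA_real_)
  out <- select_valid_labels(v, labels, "forecasting", quality_config())
  expect_equal(out$phq2_window_valid, 7)
})

test_that("subjects need both label-count minima", {
  mk_labels <- function(n2, n9) {
    tibble::tibble(
      subject_id = "S01",
      phq2_retained = c(rep(TRUE, n2), rep(FALSE, 20 - n2)),
      phq9_retained = c(rep(TRUE, n9), rep(FALSE, 20 - n9)))
  }
  expect_true(filter_subjects(mk_labels(12, 6))$retained)
  expect_true(filter_subjects(mk_labels(10, 5))$retained)   # inclusive
  expect_false(filter_subjects(mk_labels(9, 20))$retained)  # conjunction
})

test_that("weekly-mean imputation fills from the window and never alters data", {
  co <- simulate_cohort(cohort_config(n_subjects = 1, n_days = 20,
                                      seed = 23))
  fe <- extract_features(co)
  f1 <- feature_columns()[1]
  ld <- co$config$start_date + 9
  # constant mean
  fe_c <- fe
  fe_c[[f1]] <- 1
  fe_c[[f1]][fe_c$date == ld - 2] <- NA
  imp <- impute_weekly_mean(fe_c, "S01", ld, "prediction")
  expect_equal(imp$block[[f1]][imp$block$date == ld - 2], 1)
  # {2, 4} observed, rest missing -> mean 3
  fe_m <- fe
  fe_m[[f1]] <- NA_real_
  fe_m[[f1]][fe_m$date == ld - 1] <- 2
  fe_m[[f1]][fe_m$date == ld - 3] <- 4
  imp2 <- impute_weekly_mean(fe_m, "S01", ld, "prediction")
  filled <- imp2$block[[f1]]
  expect_equal(filled[imp2$block$date == ld - 2], 3)
  expect_equal(filled[imp2$block$date == ld - 1], 2)   # observed untouched
  expect_equal(sum(imp2$imputed[, f1]), 5)
  expect_length(imp2$fallback, 0)
  # feature absent all week -> subject past-mean fallback, flagged
  fe_a <- fe
  fe_a[[f1]][fe_a$date >= ld - 6 & fe_a$date <= ld] <- NA
  imp3 <- impute_weekly_mean(fe_a, "S01", ld, "prediction")
  expect_true(f1 %in% imp3$fallback)
  past_mean <- mean(fe_a[[f1]][fe_a$date <= ld], na.rm = TRUE)
  expect_equal(unique(imp3$block[[f1]]), past_mean)
})

test_that("imputation is idempotent", {
  co <- simulate_cohort(cohort_config(n_subjects = 2, n_days = 20, seed = 29,
                                      missing_feature_rate = 0.15))
  fe <- extract_features(co)
  ld <- co$config$start_date + 10
  a <- impute_weekly_mean(fe, "S01", ld, "prediction")
  fe2 <- fe
  rows <- which(fe2$subject_id == "S01")[
    match(a$block$date, fe2$date[fe2$subject_id == "S01"])]
  fe2[rows, feature_columns()] <- a$block[, feature_columns()]
  b <- impute_weekly_mean(fe2, "S01", ld, "prediction")
  expect_equal(as.data.frame(b$block), as.data.frame(a$block))
})

test_that("filtering is monotone in its thresholds", {
  co <- simulate_cohort(cohort_config(n_subjects = 8, n_days = 30, seed = 31,
                                      missing_day_rate = 0.15,
                                      missing_feature_rate = 0.1))
  fe <- extract_features(co)
  la <- cohort_labels(co)
  strict <- quality_filter(fe, la, "prediction",
                           quality_config(max_day_missing_rate = 0.15,
                                          min_valid_days_per_label = 6,
                                          min_phq2_labels = 12,
                                          min_phq9_labels = 3))
  loose <- quality_filter(fe, la, "prediction",
                          quality_config(max_day_missing_rate = 0.30,
                                         min_valid_days_per_label = 4,
                                         min_phq2_labels = 8,
                                         min_phq9_labels = 2))
  kept_strict <- strict$subjects$subject_id[strict$subjects$retained]
  kept_loose <- loose$subjects$subject_id[loose$subjects$retained]
  expect_true(all(kept_strict %in% kept_loose))
  lab_strict <- strict$labels[strict$labels$phq2_retained, ]
  lab_loose <- loose$labels[loose$labels$phq2_retained, ]
  expect_true(all(paste(lab_strict$subject_id, lab_strict$date) %in%
                    paste(lab_loose$subject_id, lab_loose$date)))
})

test_that("a missingness-free cohort passes the criteria wholesale", {
  co <- simulate_cohort(cohort_config(n_subjects = 5, n_days = 42,
                                      seed = 37))
  fe <- extract_features(co)
  la <- cohort_labels(co)
  for (task in c("prediction", "forecasting")) {
    qf <- quality_filter(fe, la, task)
    expect_equal(sum(qf$subjects$retained), 5)
    lab <- qf$labels[qf$labels$phq2_retained, ]
    from_day8 <- la[!is.na(la$phq2) & la$date >= co$config$start_date + 7, ]
    expect_true(all(paste(from_day8$subject_id, from_day8$date) %in%
                      paste(lab$subject_id, lab$date)))
  }
})

test_that("standardisers z-score their own training data", {
  w <- make_synthetic_windows(n_subjects = 3, n_per_subject = 8, seed = 41,
                              offsets = c(-2, 0, 2))
  for (scope in c("population", "per_subject")) {
    std <- fit_standardiser(w, scope)
    tw <- apply_standardiser(std, w)
    stacked <- do.call(rbind, tw$sequence)
    sid <- rep(tw$subject_id, each = 7)
    if (scope == "population") {
      expect_equal(unname(colMeans(stacked)), rep(0, 4), tolerance = 1e-10)
      expect_equal(unname(apply(stacked, 2, sd)), rep(1, 4),
                   tolerance = 1e-10)
    } else {
      for (s in unique(sid)) {
        expect_equal(unname(colMeans(stacked[sid == s, ])), rep(0, 4),
                     tolerance = 1e-10)
        expect_equal(unname(apply(stacked[sid == s, ], 2, sd)), rep(1, 4),
                     tolerance = 1e-10)
      }
    }
    expect_identical(attr(tw, "standardised_scope"), scope)
  }
})

test_that("zero-variance features map to zero and scopes coincide for n=1", {
  w <- make_synthetic_windows(n_subjects = 1, n_per_subject = 6, seed = 43)
  w$sequence <- lapply(w$sequence, function(m) { m[, 2] <- 5; m })
  pop <- apply_standardiser(fit_standardiser(w, "population"), w)
  per <- apply_standardiser(fit_standardiser(w, "per_subject"), w)
  expect_true(all(vapply(pop$sequence, function(m) all(m[, 2] == 0),
                         logical(1))))
  expect_equal(pop$sequence, per$sequence)
  # unseen subject under per_subject scope is an error
  w2 <- make_synthetic_windows(n_subjects = 2, n_per_subject = 6, seed = 44)
  std1 <- fit_standardiser(w2[w2$subject_id == "S01", ], "per_subject")
  expect_error(apply_standardiser(std1, w2[w2$subject_id == "S02", ]),
               "unseen")
})

test_that("standardiser fits depend on training windows only", {
  w <- make_synthetic_windows(n_subjects = 3, n_per_subject = 8, seed = 47)
  train <- w[w$window_id <= 12, ]
  attr(train, "feature_order") <- attr(w, "feature_order")
  s1 <- fit_standardiser(train, "population")
  s2 <- fit_standardiser(train, "population")
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("windows have the documented shape and date arithmetic", {
  co <- simulate_cohort(cohort_config(n_subjects = 2, n_days = 20,
                                      seed = 53))
  fe <- extract_features(co)
  la <- cohort_labels(co)
  # a 20-day window only carries 2 weekly PHQ-9 labels; relax criterion 3
  qc <- quality_config(min_phq2_labels = 5, min_phq9_labels = 2)
  for (task in c("prediction", "forecasting")) {
    qf <- quality_filter(fe, la, task, qc)
    w <- build_windows(qf)
    expect_true(all(vapply(w$sequence, nrow, integer(1)) == 7))
    ld <- co$config$start_date + 9   # label on study day 10
    k <- which(w$subject_id == "S01" & w$label_date == ld)
    expect_length(k, 1)
    blk_dates <- if (task == "prediction") ld - 6:0 else ld - 7:1
    imp <- impute_weekly_mean(qf$days, "S01", ld, task)
    expect_equal(imp$block$date, blk_dates)
    expect_equal(w$sequence[[k]][7, ],
                 unlist(imp$block[7, feature_columns()]))
    # labels whose window underflows the observation start are skipped
    expect_false(any(w$label_date < co$config$start_date +
                       (if (task == "prediction") 6 else 7)))
    expect_true(all(w$target >= 0 & w$target <= 6))
  }
})
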