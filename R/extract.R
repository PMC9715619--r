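#' Daily feature table for one subject
#'
#' Runs significant-place clustering over the subject's full GPS trace,
#' infers home, and computes one row per calendar day with the 19 passive
#' features plus the active EMA/diary features. A stream recorded as lost
#' for a day (the cohort's `dropped` table) yields NA for that stream's
#' features; an observed-but-empty call log yields zeros.
#'
#' @param streams One subject's raw-stream list (an element of
#'   `cohort$subjects`).
#' @param dates Calendar days of the observation window.
#' @param clustering Significant-place method passed to
#'   [detect_significant_places()].
#' @param ... Further clustering parameters.
#' @return Tibble with `subject_id`, `sex`, `date` and one column per
#'   feature in [feature_columns()].
#' @export
extract_daily_features <- function(streams, dates,
                                   clustering = "time_based", ...) {
  stopifnot(length(dates) > 0)
  dropped <- streams$dropped %||%
    tibble::tibble(date = as.Date(character()), stream = character())
  drop_key <- paste(dropped$stream, dropped$date)
  is_dropped <- function(stream, date) paste(stream, date) %in% drop_key

  places <- detect_significant_places(streams$gps, method = clustering, ...)
  home <- if (nrow(places) > 0) infer_home(streams$gps, places)
          else NA_integer_
  by_date <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(list())
    split(df, ts_date(df$timestamp))
  }
  gps <- streams$gps
  if (!is.null(gps) && nrow(gps) > 0) {
    gps$.place <- place_assignment(gps, places)
  }
  gps_by <- by_date(gps)
  calls_by <- by_date(streams$calls)
  apps_by <- by_date(streams$apps)
  ema_by <- by_date(streams$ema)
  usage <- phone_usage_daily_features(streams$screen)
  diary <- streams$diary
  diary_by <- if (is.null(diary) || nrow(diary) == 0) list()
              else split(diary, diary$date)

  dn <- paste0("diary_", names(DIARY_ITEMS))
  na_named <- function(nm) stats::setNames(rep(NA_real_, length(nm)), nm)
  gps_na <- na_named(c("location_variance", "location_entropy",
                       "normalised_location_entropy", "time_at_home",
                       "total_distance"))
  comm_na <- na_named(c("total_calling_frequency", "total_calling_duration",
                        "nonworking_calling_frequency",
                        "nonworking_calling_duration", "missed_calls",
                        "n_contacts", "calling_entropy",
                        "normalised_calling_entropy"))
  ema_na <- na_named(c("ema_happy", "ema_active", "ema_tense", "ema_sad",
                       "positive_affect", "negative_affect"))

  rows <- lapply(dates, function(day) {
    key <- as.character(day)
    g <- if (is_dropped("gps", day)) gps_na
         else gps_daily_vec(gps_by[[key]], places, home)
    cm <- if (is_dropped("calls", day)) comm_na
          else communication_daily_vec(calls_by[[key]])
    pu <- if (is_dropped("screen", day)) {
      c(phone_usage_frequency = NA_real_, phone_usage_duration = NA_real_)
    } else if (day %in% usage$date) {
      i <- match(day, usage$date)
      c(phone_usage_frequency = usage$phone_usage_frequency[i],
        phone_usage_duration = usage$phone_usage_duration[i])
    } else {
      c(phone_usage_frequency = 0, phone_usage_duration = 0)
    }
    lock <- if (is_dropped("screen", day)) NA_real_
            else 1440 - pu[["phone_usage_duration"]]
    if (is_dropped("apps", day)) {
      ua <- c(lock_screen_duration = lock, n_used_apps = NA_real_,
              midnight_app_usage = NA_real_, sleep_time = NA_real_)
    } else {
      da <- apps_by[[key]]
      prev <- if (is_dropped("apps", day - 1)) NULL
              else apps_by[[as.character(day - 1)]]
      has <- !is.null(da) && nrow(da) > 0
      m <- if (has) minutes_of_day(da$timestamp) else numeric(0)
      ua <- c(
        lock_screen_duration = lock,
        n_used_apps = if (has) length(unique(da$app_id)) else 0,
        midnight_app_usage = if (has) {
          length(unique(da$app_id[m < 300]))
        } else 0,
        sleep_time = sleep_minutes_for_day(
          day,
          if (has) da$timestamp else as.POSIXct(character(), tz = "UTC"),
          if (!is.null(prev) && nrow(prev) > 0) prev$timestamp
          else as.POSIXct(character(), tz = "UTC")))
    }
    em <- if (is_dropped("ema", day)) ema_na else {
      de <- ema_by[[key]]
      if (is.null(de) || nrow(de) == 0) ema_na else {
        mh <- mean(de$happy); ma <- mean(de$active)
        mt <- mean(de$tense); ms <- mean(de$sad)
        c(ema_happy = mh, ema_active = ma, ema_tense = mt, ema_sad = ms,
          positive_affect = (mh + ma) / 2, negative_affect = (mt + ms) / 2)
      }
    }
    di <- if (is_dropped("diary", day)) na_named(dn) else {
      dd <- diary_by[[key]]
      if (is.null(dd)) na_named(dn) else {
        stats::setNames(
          as.numeric(dd$value[match(names(DIARY_ITEMS), dd$item_id)]), dn)
      }
    }
    c(g, cm, pu, ua, em, di)
  })
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(mat)
  out$subject_id <- streams$subject_id
  out$sex <- streams$sex
  out$date <- dates
  out[, c("subject_id", "sex", "date", feature_columns())]
}

#' Daily feature table for a whole cohort
#'
#' @param cohort A `moodcast_cohort`.
#' @param clustering Significant-place method.
#' @param ... Further clustering parameters.
#' @return Tibble with one row per subject-day; columns `subject_id`,
#'   `sex`, `date` and [feature_columns()].
#' @export
extract_features <- function(cohort, clustering = "time_based", ...) {
  stopifnot(inherits(cohort, "moodcast_cohort"))
  cfg <- cohort$config
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1L
  out <- dplyr::bind_rows(lapply(cohort$subjects, extract_daily_features,
                                 dates = dates, clustering = clustering,
                                 ...))
  attr(out, "clustering") <- clustering
  out
}
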