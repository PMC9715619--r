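#' Configuration for a synthetic mobile-sensing cohort
#'
#' Defines the generative conditions of a simulated 8-week observation study:
#' per-subject latent depressive-severity trajectories (baseline + linear
#' trend + AR(1) noise) that drive both the daily PHQ-2 / weekly PHQ-9
#' labels and the sensor behaviour (mobility, calling, phone usage, sleep),
#' subject-specific affect-reporting styles, and a controllable missingness
#' process.
#'
#' @param n_subjects Number of subjects.
#' @param n_days Days of observation per subject (default 56, i.e. 8 weeks).
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   cohort.
#' @param sex_ratio Probability that a subject is female.
#' @param baseline_mean,baseline_sd Mean and SD of the subject baseline
#'   latent severity at study entry, expressed on the PHQ-2 scale (0-6).
#'   The default emulates a treatment cohort: subjects enter with elevated
#'   symptoms (an inclusion criterion), so the entry spread is moderate.
#' @param trend_mean,trend_sd Mean and SD of the per-day linear drift of
#'   latent severity. The negative default mean emulates heterogeneous
#'   improvement under an 8-week digital intervention (about 1.4 PHQ-2
#'   points on average over 56 days, with some subjects improving much
#'   more than others).
#' @param ar_coefficient AR(1) persistence of the latent severity noise,
#'   in `[0, 1)`.
#' @param noise_sd Innovation SD of the AR(1) severity noise.
#' @param response_offset_sd,response_scale_sd SD of the subject-specific
#'   additive offset and (log-)multiplicative scale with which subjects map
#'   latent severity onto their EMA/diary ratings. These control the
#'   reporting heterogeneity that makes subject-dependent standardisation
#'   pay off; 0 means all subjects report identically.
#' @param behaviour_offset_sd SD of the subject-specific baseline shifts of
#'   the behavioural rates (daily excursions, calls, phone-usage sessions).
#'   People differ in how mobile or communicative they are independently of
#'   depression, so absolute sensor levels are not comparable across
#'   subjects; only within-subject changes track severity.
#' @param missing_day_rate Probability that a whole subject-day (all streams
#'   and labels) is lost.
#' @param missing_feature_rate Probability that a single stream
#'   (gps/calls/screen/apps/ema/diary) of an observed day is lost.
#' @param sex_effect Additive shift of male subjects' baseline latent
#'   severity; a non-zero value plants a group-level signal for fairness
#'   analyses.
#' @param night_usage_prob Probability of a short after-midnight phone-usage
#'   bout on any given night.
#' @param start_date Calendar date of study day 1.
#'
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20,
                          n_days = 56,
                          seed = 1,
                          sex_ratio = 0.8,
                          baseline_mean = 3.0,
                          baseline_sd = 0.5,
                          trend_mean = -0.02,
                          trend_sd = 0.015,
                          ar_coefficient = 0.7,
                          noise_sd = 1.0,
                          response_offset_sd = 0.7,
                          response_scale_sd = 0.4,
                          behaviour_offset_sd = 1.5,
                          missing_day_rate = 0,
                          missing_feature_rate = 0,
                          sex_effect = 0,
                          night_usage_prob = 0.05,
                          start_date = as.Date("2021-06-01")) {
  cfg <- list(
    n_subjects = n_subjects, n_days = n_days, seed = seed,
    sex_ratio = sex_ratio, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, trend_mean = trend_mean,
    trend_sd = trend_sd,
    ar_coefficient = ar_coefficient, noise_sd = noise_sd,
    response_offset_sd = response_offset_sd,
    response_scale_sd = response_scale_sd,
    behaviour_offset_sd = behaviour_offset_sd,
    missing_day_rate = missing_day_rate,
    missing_feature_rate = missing_feature_rate,
    sex_effect = sex_effect, night_usage_prob = night_usage_prob,
    start_date = as.Date(start_date))
  num <- cfg[!(names(cfg) %in% "start_date")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1)))) {
    stop("all cohort_config values must be finite scalars", call. = FALSE)
  }
  rates <- c(cfg$sex_ratio, cfg$missing_day_rate, cfg$missing_feature_rate,
             cfg$night_usage_prob)
  if (any(rates < 0 | rates > 1)) {
    stop("rates/probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$ar_coefficient < 0 || cfg$ar_coefficient >= 1) {
    stop("ar_coefficient must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$n_days < 8) stop("n_days must be at least 8", call. = FALSE)
  if (cfg$n_subjects < 1) stop("n_subjects must be positive", call. = FALSE)
  if (cfg$baseline_sd < 0 || cfg$trend_sd < 0 || cfg$noise_sd < 0 ||
      cfg$response_offset_sd < 0 || cfg$response_scale_sd < 0 ||
      cfg$behaviour_offset_sd < 0) {
    stop("scale parameters must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# Diary item loadings on reported severity: positive items worsen with
# severity (CES-D depressed mood, PSQI sleep trouble, PDD workload),
# negative items shrink with it (behavioural activation, reward experience).
DIARY_ITEMS <- c(
  cesd_5 = 0.9, cesd_7 = 0.9, cesd_20 = 0.8, psqi_6 = 0.7,
  bads_1 = -0.8, bads_5 = -0.7, bads_7 = -0.8,
  pdd_agentic = -0.6, pdd_communal = -0.6, pdd_workload = 0.4)

APP_POOL <- sprintf("app_%02d", 1:8)

# Anchor excursion targets relative to the home coordinate (degrees).
ANCHOR_OFFSETS <- matrix(c(0.010, 0.004,
                           -0.006, 0.012,
                           0.003, -0.015), ncol = 2, byrow = TRUE)

#' Simulate a synthetic mobile-sensing cohort
#'
#' Generates raw event streams and active assessments for every subject.
#' For subject i, a latent severity `s_i(t) = b_i + m_i t + AR(1) noise`
#' (on the PHQ-2 scale) drives everything: daily PHQ-2 is
#' `round(clamp(s_i(t), 0, 6))`, weekly PHQ-9 maps the weekly mean of
#' `s_i` onto 0-27, EMA and diary ratings are subject-specific affine maps
#' of `s_i` (negative affect increasing, positive affect decreasing), GPS
#' excursions and call rates decrease with severity, and app/screen streams
#' carry a nightly usage gap so sleep can be inferred downstream.
#' Missingness is applied afterwards via [inject_missingness()].
#'
#' @param config A [cohort_config()].
#' @return An object of class `moodcast_cohort`: a list with `subjects`
#'   (one raw-stream list per subject) and `config`. Each subject carries
#'   `gps`, `calls`, `screen`, `apps`, `ema`, `diary`, `phq2`, `phq9`
#'   tibbles, a `dropped` table of lost (date, stream) pairs, and a `truth`
#'   tibble with the latent severity and the simulated nightly sleep gap.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- with_local_seed(config$seed, {
    subjects <- lapply(seq_len(config$n_subjects), function(i) {
      simulate_subject(i, config)
    })
    names(subjects) <- vapply(subjects, `[[`, character(1), "subject_id")
    structure(list(subjects = subjects, config = config),
              class = "moodcast_cohort")
  })
  if (config$missing_day_rate > 0 || config$missing_feature_rate > 0) {
    cohort <- inject_missingness(cohort, config$missing_day_rate,
                                 config$missing_feature_rate,
                                 seed = config$seed + 777L)
  }
  cohort
}

simulate_subject <- function(i, cfg) {
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1L
  sex <- if (stats::runif(1) < cfg$sex_ratio) "female" else "male"
  b <- stats::rnorm(1, cfg$baseline_mean +
                      if (sex == "male") cfg$sex_effect else 0,
                    cfg$baseline_sd)
  m <- stats::rnorm(1, cfg$trend_mean, cfg$trend_sd)
  offset <- stats::rnorm(1, 0, cfg$response_offset_sd)
  scale <- exp(stats::rnorm(1, 0, cfg$response_scale_sd))
  bed_mean <- clamp(stats::rnorm(1, 1410, 15), 1200, 1430)   # ~23:30
  wake_mean <- clamp(stats::rnorm(1, 420, 15), 315, 600)     # ~07:00
  # subject-level behavioural baselines: mobility, calling and phone-usage
  # rates differ between people independently of severity
  exc_base <- stats::rnorm(1, 2.5, cfg$behaviour_offset_sd)
  call_base <- stats::rnorm(1, 2.2, 0.8 * cfg$behaviour_offset_sd)
  sess_base <- max(4, stats::rnorm(1, 18, 5 * cfg$behaviour_offset_sd))

  # latent severity
  e <- numeric(cfg$n_days)
  e[1] <- if (cfg$noise_sd > 0) {
    stats::rnorm(1, 0, cfg$noise_sd / sqrt(1 - cfg$ar_coefficient^2))
  } else 0
  innov <- stats::rnorm(cfg$n_days, 0, cfg$noise_sd)
  for (t in seq_len(cfg$n_days)[-1]) {
    e[t] <- cfg$ar_coefficient * e[t - 1] + innov[t]
  }
  s <- b + m * (seq_len(cfg$n_days) - 1) + e
  s6 <- clamp(s, 0, 6)
  reported <- offset + scale * s

  phq2 <- tibble::tibble(date = dates, value = round(s6))
  wk <- which(seq_len(cfg$n_days) %% 7L == 0L)
  phq9 <- tibble::tibble(
    date = dates[wk],
    value = round(clamp(vapply(wk, function(t) mean(s[(t - 6):t]),
                               numeric(1)) * 4.5 +
                          stats::rnorm(length(wk), 0, 1), 0, 27)))

  bed <- clamp(bed_mean + stats::rnorm(cfg$n_days, 0, 12), 1200, 1435)
  wake <- clamp(wake_mean + stats::rnorm(cfg$n_days, 0, 12), 310, 660)

  home <- c(48 + 0.05 * i, 11.5)
  anchors <- cbind(home[1] + ANCHOR_OFFSETS[, 1],
                   home[2] + ANCHOR_OFFSETS[, 2])
  contact_w <- (1 / seq_len(6)) / sum(1 / seq_len(6))

  gps <- vector("list", cfg$n_days)
  calls <- vector("list", cfg$n_days)
  screen <- vector("list", cfg$n_days)
  apps <- vector("list", cfg$n_days)
  ema <- vector("list", cfg$n_days)
  diary <- vector("list", cfg$n_days)

  for (t in seq_len(cfg$n_days)) {
    day <- dates[t]
    # --- GPS: 5-min fix grid, home by default, Poisson-many anchor visits
    grid <- seq(0, 1435, by = 5)
    lat <- rep(home[1], length(grid))
    lon <- rep(home[2], length(grid))
    n_exc <- stats::rpois(1, max(0.2, exc_base - 0.35 * s6[t]))
    if (n_exc > 0) {
      for (k in seq_len(n_exc)) {
        start <- stats::runif(1, wake[t] + 30, max(wake[t] + 60, bed[t] - 210))
        dur <- min(180, 30 + stats::rexp(1, 1 / 45))
        a <- sample.int(3, 1)
        sel <- grid >= start & grid <= min(start + dur, bed[t] - 10)
        lat[sel] <- anchors[a, 1]
        lon[sel] <- anchors[a, 2]
      }
    }
    gps[[t]] <- tibble::tibble(
      timestamp = make_ts(day, grid),
      lat = lat + stats::rnorm(length(grid), 0, 1e-4),
      lon = lon + stats::rnorm(length(grid), 0, 1e-4))

    # --- calls
    n_call <- stats::rpois(1, max(0.3, call_base - 0.25 * s6[t]))
    if (n_call > 0) {
      at <- sort(stats::runif(n_call, 8 * 60, 22 * 60))
      missed <- stats::runif(n_call) < 0.15
      calls[[t]] <- tibble::tibble(
        timestamp = make_ts(day, at),
        contact_id = sprintf("C%d", sample.int(6, n_call, replace = TRUE,
                                               prob = contact_w)),
        direction = sample(c("incoming", "outgoing"), n_call,
                           replace = TRUE),
        duration_min = ifelse(missed, 0,
                              round(0.5 + stats::rexp(n_call, 1 / 5), 2)),
        missed = missed)
    }

    # --- screen sessions within the wake window
    n_sess <- stats::rpois(1, sess_base)
    if (n_sess > 0) {
      st <- sort(stats::runif(n_sess, wake[t], bed[t] - 2))
      du <- 1 + stats::rexp(n_sess, 1 / 6)
      keep <- logical(n_sess); last_end <- -Inf
      for (k in seq_len(n_sess)) {
        if (st[k] >= last_end) { keep[k] <- TRUE; last_end <- st[k] + du[k] }
      }
      st <- st[keep]
      du <- pmin(du[keep], bed[t] - st)
      if (length(st) > 0) {
        screen[[t]] <- tibble::tibble(
          timestamp = make_ts(day, as.vector(rbind(st, st + du))),
          event = rep(c("unlock", "lock"), length(st)))
        # app events inside sessions
        n_ev <- pmin(3, 1 + stats::rpois(length(st), 0.8))
        ev_t <- unlist(lapply(seq_along(st), function(k) {
          st[k] + stats::runif(n_ev[k], 0, max(du[k] - 0.2, 0.1))
        }))
        apps_t <- ev_t
      } else apps_t <- numeric(0)
    } else apps_t <- numeric(0)

    # anchor app events at wake and bedtime keep the nightly gap well defined
    apps_t <- c(wake[t], apps_t, bed[t])
    if (stats::runif(1) < cfg$night_usage_prob) {
      apps_t <- c(stats::runif(1, 10, 100), apps_t)  # 00:10-01:40 bout
    }
    apps_t <- sort(apps_t)
    apps[[t]] <- tibble::tibble(
      timestamp = make_ts(day, apps_t),
      app_id = sample(APP_POOL, length(apps_t), replace = TRUE))

    # --- EMA (3x/day) and end-of-day diary
    slot <- clamp(c(540, 840, 1200) + stats::runif(3, -30, 30), 0, 1435)
    neg <- function() clamp(reported[t] + stats::rnorm(3, 0, 0.5), 0, 6)
    pos <- function() clamp(6 - reported[t] + stats::rnorm(3, 0, 0.5), 0, 6)
    ema[[t]] <- tibble::tibble(
      timestamp = make_ts(day, slot),
      happy = pos(), active = pos(), tense = neg(), sad = neg())
    diary[[t]] <- tibble::tibble(
      date = day,
      item_id = names(DIARY_ITEMS),
      value = clamp(3 + unname(DIARY_ITEMS) * (reported[t] - 3) +
                      stats::rnorm(length(DIARY_ITEMS), 0, 0.5), 0, 6))
  }

  sleep_truth <- c(NA_real_, wake[-1] + 1440 - bed[-cfg$n_days])
  empty_calls <- tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    contact_id = character(), direction = character(),
    duration_min = numeric(), missed = logical())
  empty_screen <- tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"), event = character())
  list(
    subject_id = sprintf("S%02d", i),
    sex = sex,
    gps = dplyr::bind_rows(gps),
    calls = dplyr::bind_rows(c(list(empty_calls), calls)),
    screen = dplyr::bind_rows(c(list(empty_screen), screen)),
    apps = dplyr::bind_rows(apps),
    ema = dplyr::bind_rows(ema),
    diary = dplyr::bind_rows(diary),
    phq2 = phq2,
    phq9 = phq9,
    dropped = tibble::tibble(date = as.Date(character()),
                             stream = character()),
    truth = tibble::tibble(date = dates, severity = s,
                           sleep_min = sleep_truth))
}

#' Remove subject-days and daily streams at random
#'
#' Emulates the non-response and technical data loss of real mobile-sensing
#' studies. Whole subject-days are dropped with probability
#' `missing_day_rate` (removing all streams *and* the labels of that day);
#' individual streams of surviving days are dropped independently with
#' probability `missing_feature_rate`. Labels are only ever removed by the
#' day-level process. Dropped (date, stream) pairs are recorded in each
#' subject's `dropped` table so that feature extraction can distinguish "no
#' events occurred" from "stream lost".
#'
#' @param cohort A `moodcast_cohort`.
#' @param missing_day_rate,missing_feature_rate Probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return The cohort with events and labels removed.
#' @export
inject_missingness <- function(cohort, missing_day_rate,
                               missing_feature_rate, seed) {
  stopifnot(inherits(cohort, "moodcast_cohort"),
            missing_day_rate >= 0, missing_day_rate <= 1,
            missing_feature_rate >= 0, missing_feature_rate <= 1)
  if (missing_day_rate == 0 && missing_feature_rate == 0) return(cohort)
  streams <- c("gps", "calls", "screen", "apps", "ema", "diary")
  cfg <- cohort$config
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1L
  with_local_seed(seed, {
    cohort$subjects <- lapply(cohort$subjects, function(sub) {
      day_drop <- stats::runif(cfg$n_days) < missing_day_rate
      feat_drop <- matrix(stats::runif(cfg$n_days * length(streams)) <
                            missing_feature_rate,
                          nrow = cfg$n_days)
      dropped <- dplyr::bind_rows(lapply(seq_along(streams), function(j) {
        tibble::tibble(date = dates[day_drop | feat_drop[, j]],
                       stream = streams[j])
      }))
      for (j in seq_along(streams)) {
        st <- streams[j]
        gone <- dates[day_drop | feat_drop[, j]]
        if (nrow(sub[[st]]) > 0) {
          d <- if ("date" %in% names(sub[[st]])) sub[[st]]$date
               else ts_date(sub[[st]]$timestamp)
          sub[[st]] <- sub[[st]][!(d %in% gone), , drop = FALSE]
        }
      }
      sub$phq2 <- sub$phq2[!(sub$phq2$date %in% dates[day_drop]), ]
      sub$phq9 <- sub$phq9[!(sub$phq9$date %in% dates[day_drop]), ]
      sub$dropped <- dplyr::arrange(dplyr::bind_rows(sub$dropped, dropped),
                                    .data$date, .data$stream)
      sub
    })
    cohort
  })
}

#' Daily PHQ-2 and weekly PHQ-9 labels of a cohort
#'
#' @param cohort A `moodcast_cohort`.
#' @return A tibble with one row per (subject, date) carrying a label:
#'   `subject_id`, `sex`, `date`, `phq2`, `phq9` (NA where not scheduled or
#'   lost).
#' @export
cohort_labels <- function(cohort) {
  stopifnot(inherits(cohort, "moodcast_cohort"))
  dplyr::bind_rows(lapply(cohort$subjects, function(sub) {
    p2 <- dplyr::rename(sub$phq2, phq2 = "value")
    p9 <- dplyr::rename(sub$phq9, phq9 = "value")
    out <- dplyr::full_join(p2, p9, by = "date")
    out$subject_id <- sub$subject_id
    out$sex <- sub$sex
    dplyr::arrange(out[, c("subject_id", "sex", "date", "phq2", "phq9")],
                   .data$date)
  }))
}

#' @export
print.moodcast_cohort <- function(x, ...) {
  cfg <- x$config
  sexes <- vapply(x$subjects, `[[`, character(1), "sex")
  cat(sprintf(
    "<moodcast_cohort> %d subjects (%d female / %d male), %d days, seed %d\n",
    cfg$n_subjects, sum(sexes == "female"), sum(sexes == "male"),
    cfg$n_days, cfg$seed))
  invisible(x)
}

iso8601 <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S")

#' Write a cohort to a directory of per-subject CSV files
#'
#' One directory per subject holding `gps.csv`, `calls.csv`, `screen.csv`,
#' `apps.csv`, `ema.csv`, `diary.csv`, `labels.csv` and `dropped.csv`
#' (ISO-8601 timestamps, comma-delimited, header row), plus a cohort-level
#' `manifest.json` with subject ids, sex, and the generating configuration.
#'
#' @param cohort A `moodcast_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "moodcast_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in cohort$subjects) {
    sd <- file.path(dir, sub$subject_id)
    dir.create(sd, showWarnings = FALSE)
    wr <- function(df, name) {
      df <- as.data.frame(df)
      for (cl in names(df)) {
        if (inherits(df[[cl]], "POSIXct")) df[[cl]] <- iso8601(df[[cl]])
        if (inherits(df[[cl]], "Date")) df[[cl]] <- format(df[[cl]])
      }
      utils::write.csv(df, file.path(sd, name), row.names = FALSE)
    }
    wr(sub$gps, "gps.csv"); wr(sub$calls, "calls.csv")
    wr(sub$screen, "screen.csv"); wr(sub$apps, "apps.csv")
    wr(sub$ema, "ema.csv"); wr(sub$diary, "diary.csv")
    labels <- dplyr::full_join(
      dplyr::rename(sub$phq2, phq2 = "value"),
      dplyr::rename(sub$phq9, phq9 = "value"), by = "date")
    wr(dplyr::arrange(labels, .data$date), "labels.csv")
    wr(sub$dropped, "dropped.csv")
  }
  cfg <- cohort$config
  cfg$start_date <- format(cfg$start_date)
  manifest <- list(
    subjects = data.frame(
      subject_id = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
      sex = vapply(cohort$subjects, `[[`, character(1), "sex")),
    config = unclass(cfg),
    seed = cohort$config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json` and per-subject folders.
#' @return A `moodcast_cohort` (without the simulator's `truth` tables).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  cfg$start_date <- as.Date(cfg$start_date)
  config <- do.call(cohort_config, cfg[names(cfg) %in%
                                         names(formals(cohort_config))])
  rd <- function(sd, name, ts_cols = "timestamp", date_cols = character()) {
    df <- utils::read.csv(file.path(sd, name), stringsAsFactors = FALSE)
    for (cl in intersect(ts_cols, names(df))) {
      df[[cl]] <- as.POSIXct(df[[cl]], format = "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
    }
    for (cl in intersect(date_cols, names(df))) df[[cl]] <- as.Date(df[[cl]])
    tibble::as_tibble(df)
  }
  subjects <- lapply(seq_len(nrow(manifest$subjects)), function(i) {
    id <- manifest$subjects$subject_id[i]
    sd <- file.path(dir, id)
    labels <- rd(sd, "labels.csv", date_cols = "date")
    list(
      subject_id = id,
      sex = manifest$subjects$sex[i],
      gps = rd(sd, "gps.csv"),
      calls = rd(sd, "calls.csv"),
      screen = rd(sd, "screen.csv"),
      apps = rd(sd, "apps.csv"),
      ema = rd(sd, "ema.csv"),
      diary = rd(sd, "diary.csv", date_cols = "date"),
      phq2 = stats::setNames(
        labels[!is.na(labels$phq2), c("date", "phq2")], c("date", "value")),
      phq9 = stats::setNames(
        labels[!is.na(labels$phq9), c("date", "phq9")], c("date", "value")),
      dropped = rd(sd, "dropped.csv", ts_cols = character(),
                   date_cols = "date"))
  })
  names(subjects) <- manifest$subjects$subject_id
  structure(list(subjects = subjects, config = config),
            class = "moodcast_cohort")
}
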