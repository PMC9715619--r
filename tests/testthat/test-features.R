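test_that("haversine distance matches closed forms and geosphere", {
  expect_equal(haversine_km(48.1, 11.5, 48.1, 11.5), 0)
  expect_equal(haversine_km(0, 0, 0, 1), pi * 6371 / 180,
               tolerance = 1e-10)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-10)
  skip_if_not_installed("geosphere")
  set.seed(2)
  for (k in 1:20) {
    p1 <- c(runif(1, -180, 180), runif(1, -80, 80))
    p2 <- c(runif(1, -180, 180), runif(1, -80, 80))
    expect_equal(
      haversine_km(p1[2], p1[1], p2[2], p2[1]),
      geosphere::distHaversine(p1, p2, r = 6371000) / 1000,
      tolerance = 1e-9)
  }
})

test_that("a single visited coordinate yields one all-dwell place", {
  ts <- make_ts_test(golden_day2, seq(0, 120, by = 5))
  gps <- tibble::tibble(timestamp = ts, lat = 48, lon = 11)
  for (m in c("time_based", "dbscan", "kmeans")) {
    pl <- detect_significant_places(gps, method = m, min_samples = 3)
    expect_equal(nrow(pl), 1)
    expect_equal(pl$dwell_min, 120)
  }
})

test_that("two distant anchors with equal dwell give two equal places", {
  min1 <- seq(0, 120, by = 5)
  min2 <- seq(300, 420, by = 5)
  gps <- tibble::tibble(
    timestamp = make_ts_test(golden_day2, c(min1, min2)),
    lat = c(rep(48, length(min1)), rep(48 + 5 / 111.13, length(min2))),
    lon = 11)
  for (m in c("time_based", "dbscan", "kmeans")) {
    pl <- detect_significant_places(gps, method = m, min_samples = 3)
    expect_equal(nrow(pl), 2)
    expect_equal(sort(pl$dwell_min), c(120, 120))
  }
})

test_that("continuous transit yields no significant place", {
  # 200 m between consecutive fixes: never 2+ fixes within 100 m
  n <- 50
  gps <- tibble::tibble(
    timestamp = make_ts_test(golden_day2, seq(0, by = 5, length.out = n)),
    lat = 48 + cumsum(rep(0.0018, n)), lon = 11)
  pl <- detect_significant_places(gps, method = "time_based")
  expect_equal(nrow(pl), 0)
})

test_that("home is the maximal-overnight-dwell place with deterministic ties", {
  # A: 00:00-05:00 dwell (300 min overnight); B: 02:40-06:00 next day
  # (200 min overnight); remaining dwell at B makes it larger overall
  minA <- seq(0, 300, by = 30)
  minB1 <- seq(12 * 60, 20 * 60, by = 30)             # daytime at B
  minB2 <- seq(24 * 60 + 160, 24 * 60 + 360, by = 20) # 02:40-06:00 day 2
  gps <- tibble::tibble(
    timestamp = make_ts_test(golden_day1, c(minA, minB1, minB2)),
    lat = c(rep(48, length(minA)), rep(48.05, length(minB1) + length(minB2))),
    lon = 11)
  pl <- detect_significant_places(gps, method = "time_based")
  expect_equal(nrow(pl), 2)
  home <- infer_home(gps, pl)
  # B has more total dwell (place_id 1) but A wins on the 00:00-06:00 window
  expect_equal(pl$lat[pl$place_id == home], 48)
  expect_false(attr(home, "overnight_fallback"))
  # single place: forced
  gps1 <- tibble::tibble(timestamp = make_ts_test(golden_day1, minA),
                         lat = 48, lon = 11)
  pl1 <- detect_significant_places(gps1, method = "time_based")
  expect_equal(as.integer(infer_home(gps1, pl1)), pl1$place_id[1])
})

test_that("GPS day features handle degenerate and uniform days", {
  pl <- tibble::tibble(place_id = 1:2, lat = c(48, 48.05), lon = 11,
                       dwell_min = c(100, 50))
  attr(pl, "distance_threshold_m") <- 100
  one <- gps_daily_features(
    tibble::tibble(timestamp = make_ts_test(golden_day2, 600),
                   lat = 48, lon = 11), pl, home_id = 1)
  expect_equal(one$location_variance, log(1e-10))
  expect_equal(one$total_distance, 0)
  expect_equal(one$location_entropy, 0)
  expect_equal(one$normalised_location_entropy, 0)
  none <- gps_daily_features(tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    lat = numeric(), lon = numeric()), pl, 1)
  expect_true(all(is.na(unlist(none))))
})

test_that("equal dwell across three places gives maximal entropy", {
  mins <- c(seq(0, 60, 10), seq(300, 360, 10), seq(600, 660, 10))
  lat <- c(rep(48, 7), rep(48.05, 7), rep(48.10, 7))
  gps <- tibble::tibble(timestamp = make_ts_test(golden_day2, mins),
                        lat = lat, lon = 11)
  pl <- detect_significant_places(gps, method = "time_based")
  expect_equal(nrow(pl), 3)
  home <- infer_home(gps, pl)
  g <- gps_daily_features(gps, pl, home)
  expect_equal(g$location_entropy, log(3), tolerance = 1e-9)
  expect_equal(g$normalised_location_entropy, 1, tolerance = 1e-9)
  expect_equal(g$time_at_home, 100 / 3, tolerance = 1e-6)
  # all dwell at home
  gh <- gps_daily_features(gps[1:7, ], pl, home_id = home)
  expect_equal(gh$time_at_home, 100)
})

test_that("communication features follow hand counts", {
  empty <- communication_daily_features(NULL)
  expect_true(all(unlist(empty) == 0))
  two_same <- tibble::tibble(
    timestamp = make_ts_test(golden_day2, c(10, 14) * 60),
    contact_id = "C1", direction = c("outgoing", "incoming"),
    duration_min = 10, missed = FALSE)
  f <- communication_daily_features(two_same)
  expect_equal(f$total_calling_frequency, 2)
  expect_equal(f$total_calling_duration, 20)
  expect_equal(f$nonworking_calling_frequency, 0)
  expect_equal(f$nonworking_calling_duration, 0)
  expect_equal(f$n_contacts, 1)
  expect_equal(f$calling_entropy, 0)
  expect_equal(f$normalised_calling_entropy, 0)
  two_contacts <- tibble::tibble(
    timestamp = make_ts_test(golden_day2, c(10, 20) * 60),
    contact_id = c("C1", "C2"), direction = "outgoing",
    duration_min = 10, missed = FALSE)
  g <- communication_daily_features(two_contacts)
  expect_equal(g$nonworking_calling_frequency, 1)
  expect_equal(g$nonworking_calling_duration, 10)
  expect_equal(g$n_contacts, 2)
  expect_equal(g$calling_entropy, log(2), tolerance = 1e-12)
  expect_equal(g$normalised_calling_entropy, 1, tolerance = 1e-12)
})

test_that("phone usage counts sessions and splits them at midnight", {
  expect_equal(nrow(phone_usage_daily_features(NULL)), 0)
  ev <- tibble::tibble(
    timestamp = make_ts_test(golden_day1,
                             c(9 * 60, 9 * 60 + 10, 21 * 60, 21 * 60 + 5)),
    event = c("unlock", "lock", "unlock", "lock"))
  u <- phone_usage_daily_features(ev)
  expect_equal(u$phone_usage_frequency, 2)
  expect_equal(u$phone_usage_duration, 15)
  cross <- tibble::tibble(
    timestamp = make_ts_test(golden_day1, c(23 * 60 + 50, 24 * 60 + 10)),
    event = c("unlock", "lock"))
  v <- phone_usage_daily_features(cross)
  expect_equal(v$date, c(golden_day1, golden_day2))
  expect_equal(v$phone_usage_frequency, c(1, 0))
  expect_equal(v$phone_usage_duration, c(10, 10))
})

test_that("orphan screen events are repaired by dropping", {
  ev <- tibble::tibble(
    timestamp = make_ts_test(golden_day1,
                             c(60, 9 * 60, 9 * 60 + 10, 10 * 60,
                               11 * 60, 11 * 60 + 4)),
    event = c("lock", "unlock", "unlock", "lock", "unlock", "lock"))
  # leading orphan lock dropped; double unlock keeps the later one
  u <- phone_usage_daily_features(ev)
  expect_equal(u$phone_usage_frequency, 2)
  expect_equal(u$phone_usage_duration, 50 + 4)
})

test_that("the app-gap sleep rule covers both onset branches", {
  prev <- tibble::tibble(timestamp = make_ts_test(golden_day1, 23 * 60),
                         app_id = "app_1")
  day <- tibble::tibble(timestamp = make_ts_test(golden_day2, 7 * 60),
                        app_id = "app_1")
  ua <- user_activity_daily_features(day, NULL, prev, date = golden_day2)
  expect_equal(ua$sleep_time, 480)
  # same-day use before 02:00 takes precedence
  day2 <- tibble::tibble(
    timestamp = make_ts_test(golden_day2, c(90, 6 * 60)),
    app_id = "app_1")
  ua2 <- user_activity_daily_features(day2, NULL, prev, date = golden_day2)
  expect_equal(ua2$sleep_time, 270)
  # no app events at all: missing
  ua3 <- user_activity_daily_features(NULL, NULL, NULL, date = golden_day2)
  expect_true(is.na(ua3$sleep_time))
})

test_that("distance is invariant to row order and longitude translation", {
  set.seed(9)
  mins <- seq(0, 200, by = 5)
  gps <- tibble::tibble(
    timestamp = make_ts_test(golden_day2, mins),
    lat = 48 + cumsum(rnorm(length(mins), 0, 1e-4)),
    lon = 11 + cumsum(rnorm(length(mins), 0, 1e-4)))
  pl <- detect_significant_places(gps, method = "time_based")
  home <- if (nrow(pl) > 0) infer_home(gps, pl) else NA_integer_
  d0 <- gps_daily_features(gps, pl, home)$total_distance
  shuffled <- gps[sample(nrow(gps)), ]
  expect_equal(gps_daily_features(shuffled, pl, home)$total_distance, d0,
               tolerance = 1e-9)
  moved <- gps; moved$lon <- moved$lon + 30
  pl2 <- detect_significant_places(moved, method = "time_based")
  home2 <- if (nrow(pl2) > 0) infer_home(moved, pl2) else NA_integer_
  expect_equal(gps_daily_features(moved, pl2, home2)$total_distance, d0,
               tolerance = 1e-6)
})

test_that("entropy invariants hold on simulated days", {
  co <- simulate_cohort(cohort_config(n_subjects = 4, n_days = 14,
                                      seed = 13))
  fe <- extract_features(co)
  expect_true(all(fe$location_entropy >= 0, na.rm = TRUE))
  expect_true(all(fe$normalised_location_entropy >= 0 &
                    fe$normalised_location_entropy <= 1, na.rm = TRUE))
  expect_true(all(fe$calling_entropy >= 0, na.rm = TRUE))
  expect_true(all(fe$normalised_calling_entropy >= 0 &
                    fe$normalised_calling_entropy <= 1 + 1e-12,
                  na.rm = TRUE))
  expect_true(all(fe$time_at_home >= 0 & fe$time_at_home <= 100,
                  na.rm = TRUE))
  expect_true(all(fe$total_distance >= 0, na.rm = TRUE))
})

test_that("sleep inference recovers the generator's nightly gap", {
  co <- simulate_cohort(cohort_config(n_subjects = 3, n_days = 14, seed = 17,
                                      night_usage_prob = 0))
  fe <- extract_features(co)
  for (sub in co$subjects) {
    f <- fe[fe$subject_id == sub$subject_id, ]
    m <- merge(f[, c("date", "sleep_time")], sub$truth)
    m <- m[!is.na(m$sleep_min), ]
    expect_true(all(abs(m$sleep_time - m$sleep_min) <= 1 / 60 + 1e-9))
  }
})

test_that("dropping a stream blanks exactly its features", {
  co <- simulate_cohort(cohort_config(n_subjects = 1, n_days = 10,
                                      seed = 19))
  day <- co$config$start_date + 4
  sub <- co$subjects[[1]]
  sub$gps <- sub$gps[ts_date_test(sub$gps$timestamp) != day, ]
  sub$dropped <- tibble::tibble(date = day, stream = "gps")
  co$subjects[[1]] <- sub
  fe <- extract_features(co)
  row <- fe[fe$date == day, ]
  gps_cols <- c("location_variance", "location_entropy",
                "normalised_location_entropy", "time_at_home",
                "total_distance")
  expect_true(all(is.na(row[, gps_cols])))
  other <- setdiff(feature_columns(), gps_cols)
  expect_true(sum(is.na(row[, other])) == 0)
})
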