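#' Names of the daily feature columns
#'
#' The 19 passive features (GPS, communication, phone usage, user activity)
#' plus the active features derived from EMA affect ratings and the daily
#' diary. This fixed ordering is the feature universe used by the quality
#' criteria and the model input layout.
#'
#' @param which `"all"`, `"passive"` or `"active"`.
#' @return Character vector of column names.
#' @export
feature_columns <- function(which = c("all", "passive", "active")) {
  which <- match.arg(which)
  passive <- c(
    "location_variance", "location_entropy", "normalised_location_entropy",
    "time_at_home", "total_distance",
    "total_calling_frequency", "total_calling_duration",
    "nonworking_calling_frequency", "nonworking_calling_duration",
    "missed_calls", "n_contacts", "calling_entropy",
    "normalised_calling_entropy",
    "phone_usage_frequency", "phone_usage_duration",
    "lock_screen_duration", "n_used_apps", "midnight_app_usage",
    "sleep_time")
  active <- c("ema_happy", "ema_active", "ema_tense", "ema_sad",
              "positive_affect", "negative_affect",
              paste0("diary_", names(DIARY_ITEMS)))
  switch(which, passive = passive, active = active,
         all = c(passive, active))
}

#' Great-circle distance in kilometres
#'
#' Haversine formula with Earth radius 6371 km. Vectorised over all
#' arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(is.finite(c(lat1, lon1, lat2, lon2))))
  d2r <- pi / 180
  dlat <- (lat2 - lat1) * d2r
  dlon <- (lon2 - lon1) * d2r
  a <- sin(dlat / 2)^2 + cos(lat1 * d2r) * cos(lat2 * d2r) * sin(dlon / 2)^2
  2 * 6371 * atan2(sqrt(a), sqrt(1 - a))
}

# local equirectangular projection to metres around the centroid
project_m <- function(lat, lon) {
  lat0 <- mean(lat)
  cbind(x = (lon - mean(lon)) * cos(lat0 * pi / 180) * 111319.49,
        y = (lat - mean(lat)) * 111132.95)
}

# Grid-accelerated DBSCAN on projected points: points are binned into cells
# of side eps; a cell's neighbourhood only needs the 5x5 cell block around
# it. Returns cluster ids (0 = noise).
dbscan_labels <- function(xy, eps, min_samples) {
  n <- nrow(xy)
  cell <- floor(xy / eps)
  key <- paste(cell[, 1], cell[, 2])
  cell_of <- split(seq_len(n), key)
  neighbours <- function(i) {
    cand <- unlist(cell_of[paste(rep(cell[i, 1] + (-2:2), each = 5),
                                 rep(cell[i, 2] + (-2:2), 5))],
                   use.names = FALSE)
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    cand[d2 <= eps^2]
  }
  labels <- integer(n)  # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbours(i)
    if (length(nb) < min_samples) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue) > 0) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == 0L) labels[j] <- cl
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbours(j)
        if (length(nbj) >= min_samples) {
          queue <- c(queue, nbj[!visited[nbj] | labels[nbj] == 0L])
        }
      }
    }
  }
  labels
}

# split [start, end) intervals at midnight; intervals must span < 24 h.
# Returns a data frame (date, minutes).
split_interval_vec <- function(start, end) {
  dur <- as.numeric(end - start, units = "mins")
  d1 <- ts_date(start); d2 <- ts_date(end)
  same <- d1 == d2 | (minutes_of_day(end) == 0 & d2 == d1 + 1)
  first_part <- ifelse(same, dur, 1440 - minutes_of_day(start))
  date <- d1; minutes <- first_part
  cross <- !same
  if (any(cross)) {
    date <- c(date, d2[cross])
    minutes <- c(minutes, minutes_of_day(end[cross]))
  }
  keep <- minutes > 0
  data.frame(date = date[keep], minutes = minutes[keep])
}

# per-(date, place) dwell minutes from a fix assignment; consecutive fixes
# sharing a place contribute their inter-fix interval (capped at 30 min).
dwell_table <- function(ts, place) {
  empty <- data.frame(date = as.Date(character()), place_id = integer(),
                      minutes = numeric())
  n <- length(ts)
  if (n < 2) return(empty)
  i <- seq_len(n - 1)
  same <- !is.na(place[i]) & !is.na(place[i + 1]) &
    place[i] == place[i + 1]
  gap <- as.numeric(ts[i + 1] - ts[i], units = "mins")
  keep <- same & gap > 0 & gap <= 30
  if (!any(keep)) return(empty)
  st <- ts[i][keep]; en <- ts[i + 1][keep]; pl <- place[i][keep]
  # split_interval_vec emits first-day parts for all rows, then the
  # post-midnight spill rows in order; replicate place ids to match
  d1 <- ts_date(st); d2 <- ts_date(en)
  same_day <- d1 == d2 | (minutes_of_day(en) == 0 & d2 == d1 + 1)
  parts <- split_interval_vec(st, en)
  parts$place_id <- c(pl, pl[!same_day])
  agg <- rowsum(parts$minutes,
                paste(as.integer(parts$date), parts$place_id, sep = ":"))
  key <- strsplit(rownames(agg), ":", fixed = TRUE)
  data.frame(
    date = as.Date(vapply(key, function(k) as.integer(k[1]), integer(1)),
                   origin = "1970-01-01"),
    place_id = vapply(key, function(k) as.integer(k[2]), integer(1)),
    minutes = as.numeric(agg))
}

#' Detect significant places from GPS fixes
#'
#' Clusters a subject's GPS fixes over the whole observation period and
#' keeps clusters whose cumulative dwell time reaches `dwell_threshold_min`.
#' Three approaches are available: `time_based` stay-point detection (the
#' default; deterministic), grid-accelerated `dbscan`, and `kmeans` with the
#' number of clusters chosen by mean silhouette width.
#'
#' @param gps_fixes Tibble with `timestamp`, `lat`, `lon`, sorted by time.
#' @param method Clustering approach.
#' @param dwell_threshold_min Minimum cumulative dwell (minutes) for a
#'   cluster to count as a significant place.
#' @param distance_threshold_m Stay-point / place-merge radius (time_based)
#'   and fix-to-place assignment radius.
#' @param time_threshold_min Minimum stay duration for a stay point.
#' @param eps_m,min_samples DBSCAN neighbourhood radius and core-point size.
#' @param k_range Candidate cluster counts for k-means.
#' @param seed Seed for k-means initialisation.
#' @return Tibble of places (`place_id`, `lat`, `lon`, `dwell_min`), ordered
#'   by decreasing dwell, with the per-fix place assignment in
#'   `attr(, "assignment")` (NA = transit / not significant).
#' @export
detect_significant_places <- function(gps_fixes,
                                      method = c("time_based", "dbscan",
                                                 "kmeans"),
                                      dwell_threshold_min = 10,
                                      distance_threshold_m = 100,
                                      time_threshold_min = 10,
                                      eps_m = 50, min_samples = 5,
                                      k_range = 2:8, seed = 1) {
  method <- match.arg(method)
  empty <- tibble::tibble(place_id = integer(), lat = numeric(),
                          lon = numeric(), dwell_min = numeric())
  attr(empty, "assignment") <- integer(0)
  attr(empty, "distance_threshold_m") <- distance_threshold_m
  if (is.null(gps_fixes) || nrow(gps_fixes) == 0) return(empty)
  if (is.unsorted(gps_fixes$timestamp)) {
    gps_fixes <- gps_fixes[order(gps_fixes$timestamp), ]
  }
  ts <- gps_fixes$timestamp
  lat <- gps_fixes$lat; lon <- gps_fixes$lon
  n <- length(lat)

  cl <- switch(method,
    time_based = {
      sp <- cpp_staypoint_scan(lat, lon, as.numeric(ts) / 60,
                               distance_threshold_m, time_threshold_min)
      merge_staypoints(lat, lon, sp, distance_threshold_m)
    },
    dbscan = {
      xy <- project_m(lat, lon)
      # cluster unique ~10 m cells, carrying their fix multiplicity
      cell <- round(xy / 10)
      key <- paste(cell[, 1], cell[, 2])
      uk <- !duplicated(key)
      counts <- as.vector(table(factor(key, levels = key[uk])))
      lab_u <- dbscan_weighted(xy[uk, , drop = FALSE], counts, eps_m,
                               min_samples)
      lab_u[match(key, key[uk])]
    },
    kmeans = {
      xy <- project_m(lat, lon)
      cell <- round(xy / 25)
      key <- paste(cell[, 1], cell[, 2])
      uxy <- xy[!duplicated(key), , drop = FALSE]
      k_range <- k_range[k_range < nrow(uxy)]
      if (nrow(uxy) < 3 || length(k_range) == 0) {
        # too few distinct locations to score silhouettes: one cluster per
        # distinct ~25 m cell
        match(key, key[!duplicated(key)])
      } else {
        dmat <- stats::dist(uxy)
        fits <- with_local_seed(seed, lapply(k_range, function(k) {
          stats::kmeans(uxy, centers = k, nstart = 5, iter.max = 50)
        }))
        sil <- vapply(fits, function(f) {
          mean(cluster::silhouette(f$cluster, dmat)[, 3])
        }, numeric(1))
        centers <- fits[[which.max(sil)]]$centers
        d2 <- outer(xy[, 1], centers[, 1], "-")^2 +
          outer(xy[, 2], centers[, 2], "-")^2
        max.col(-d2)
      }
    })

  dw <- dwell_table(ts, ifelse(cl == 0L, NA_integer_, cl))
  tot <- dplyr::summarise(dplyr::group_by(dw, .data$place_id),
                          dwell_min = sum(.data$minutes), .groups = "drop")
  tot <- tot[tot$dwell_min >= dwell_threshold_min, ]
  if (nrow(tot) == 0) return(empty)
  tot <- tot[order(-tot$dwell_min, tot$place_id), ]
  relabel <- stats::setNames(seq_len(nrow(tot)), tot$place_id)
  assignment <- unname(relabel[as.character(cl)])
  places <- tibble::tibble(
    place_id = seq_len(nrow(tot)),
    lat = vapply(tot$place_id, function(p) mean(lat[cl == p]), numeric(1)),
    lon = vapply(tot$place_id, function(p) mean(lon[cl == p]), numeric(1)),
    dwell_min = tot$dwell_min)
  attr(places, "assignment") <- assignment
  attr(places, "distance_threshold_m") <- distance_threshold_m
  places
}

# greedy merge of stay points into places by centroid distance
merge_staypoints <- function(lat, lon, sp_id, dist_m) {
  cl <- integer(length(lat))
  if (all(sp_id == 0L)) return(cl)
  ids <- sort(unique(sp_id[sp_id > 0L]))
  cen <- t(vapply(ids, function(p) c(mean(lat[sp_id == p]),
                                     mean(lon[sp_id == p])), numeric(2)))
  place_of <- integer(length(ids))
  plat <- numeric(0); plon <- numeric(0); pn <- integer(0)
  for (k in seq_along(ids)) {
    if (length(plat) > 0) {
      d <- haversine_km(cen[k, 1], cen[k, 2], plat, plon) * 1000
      j <- which.min(d)
    }
    if (length(plat) > 0 && d[j] <= dist_m) {
      place_of[k] <- j
      plat[j] <- (plat[j] * pn[j] + cen[k, 1]) / (pn[j] + 1)
      plon[j] <- (plon[j] * pn[j] + cen[k, 2]) / (pn[j] + 1)
      pn[j] <- pn[j] + 1L
    } else {
      plat <- c(plat, cen[k, 1]); plon <- c(plon, cen[k, 2])
      pn <- c(pn, 1L)
      place_of[k] <- length(plat)
    }
  }
  cl[sp_id > 0L] <- place_of[match(sp_id[sp_id > 0L], ids)]
  cl
}

# DBSCAN over unique cells with point multiplicities as weights
dbscan_weighted <- function(xy, w, eps, min_samples) {
  n <- nrow(xy)
  cell <- floor(xy / eps)
  key <- paste(cell[, 1], cell[, 2])
  cell_of <- split(seq_len(n), key)
  neighbours <- function(i) {
    cand <- unlist(cell_of[paste(rep(cell[i, 1] + (-2:2), each = 5),
                                 rep(cell[i, 2] + (-2:2), 5))],
                   use.names = FALSE)
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    cand[d2 <= eps^2]
  }
  labels <- integer(n); visited <- logical(n); cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbours(i)
    if (sum(w[nb]) < min_samples) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue) > 0) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == 0L) labels[j] <- cl
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbours(j)
        if (sum(w[nbj]) >= min_samples) {
          queue <- c(queue, nbj[!visited[nbj] | labels[nbj] == 0L])
        }
      }
    }
  }
  labels
}

#' Infer the home place
#'
#' Home is the significant place with the largest cumulative dwell between
#' 00:00 and 06:00 across the whole study; ties break towards the smallest
#' `place_id`. If no overnight dwell exists at any place, the place with the
#' largest overall dwell is returned and flagged via
#' `attr(, "overnight_fallback")`.
#'
#' @param gps_fixes All of a subject's fixes (tibble with `timestamp`,
#'   `lat`, `lon`).
#' @param places Output of [detect_significant_places()].
#' @return The home `place_id` (integer).
#' @export
infer_home <- function(gps_fixes, places) {
  if (nrow(places) == 0) stop("no significant places", call. = FALSE)
  assignment <- place_assignment(gps_fixes, places)
  dw <- dwell_overlap_night(gps_fixes$timestamp, assignment)
  if (nrow(dw) > 0 && any(dw$minutes > 0)) {
    agg <- dplyr::summarise(dplyr::group_by(dw, .data$place_id),
                            minutes = sum(.data$minutes), .groups = "drop")
    agg <- agg[order(-agg$minutes, agg$place_id), ]
    home <- agg$place_id[1]
    attr(home, "overnight_fallback") <- FALSE
    return(home)
  }
  home <- places$place_id[which.max(places$dwell_min)]
  attr(home, "overnight_fallback") <- TRUE
  home
}

place_assignment <- function(gps_fixes, places) {
  a <- attr(places, "assignment")
  if (!is.null(a) && length(a) == nrow(gps_fixes)) return(a)
  if (nrow(places) == 0) return(rep(NA_integer_, nrow(gps_fixes)))
  thr <- attr(places, "distance_threshold_m") %||% 100
  d <- vapply(seq_len(nrow(places)), function(j) {
    haversine_km(gps_fixes$lat, gps_fixes$lon,
                 places$lat[j], places$lon[j]) * 1000
  }, numeric(nrow(gps_fixes)))
  d <- matrix(d, nrow = nrow(gps_fixes))
  best <- max.col(-d)
  ifelse(d[cbind(seq_len(nrow(d)), best)] <= thr,
         places$place_id[best], NA_integer_)
}

# dwell minutes per place restricted to the 00:00-06:00 window
dwell_overlap_night <- function(ts, place) {
  n <- length(ts)
  if (n < 2) {
    return(tibble::tibble(place_id = integer(), minutes = numeric()))
  }
  i <- seq_len(n - 1)
  same <- !is.na(place[i]) & !is.na(place[i + 1]) & place[i] == place[i + 1]
  gap <- as.numeric(ts[i + 1] - ts[i], units = "mins")
  keep <- same & gap <= 30
  if (!any(keep)) {
    return(tibble::tibble(place_id = integer(), minutes = numeric()))
  }
  st <- minutes_of_day(ts[i][keep])
  dur <- gap[keep]
  en <- st + dur  # may exceed 1440 (cross midnight)
  overlap <- pmax(0, pmin(en, 360) - pmax(st, 0)) +
    pmax(0, pmin(en, 1440 + 360) - pmax(st, 1440))
  tibble::tibble(place_id = place[i][keep], minutes = overlap)
}

#' Daily GPS mobility features
#'
#' Computes the five GPS features for one day of fixes: `location_variance`
#' (natural log of `var(lat) + var(lon) + 1e-10`), `location_entropy` (nats,
#' over the day's dwell shares across significant places),
#' `normalised_location_entropy` (entropy / log of the number of places
#' visited that day, 0 when at most one), `time_at_home` (% of significant
#' dwell at the home place), and `total_distance` (km, summed over
#' consecutive fixes after dropping segments implying > `speed_limit_kmh`).
#'
#' @param day_fixes One day of GPS fixes.
#' @param places,home_id Study-level significant places and home id.
#' @param speed_limit_kmh Speed filter for distance segments.
#' @return One-row tibble with the five features (all NA when the day has
#'   no fixes).
#' @export
gps_daily_features <- function(day_fixes, places, home_id,
                               speed_limit_kmh = 200) {
  tibble::as_tibble_row(gps_daily_vec(day_fixes, places, home_id,
                                      speed_limit_kmh))
}

gps_daily_vec <- function(day_fixes, places, home_id,
                          speed_limit_kmh = 200) {
  out <- c(location_variance = NA_real_, location_entropy = NA_real_,
           normalised_location_entropy = NA_real_, time_at_home = NA_real_,
           total_distance = NA_real_)
  if (is.null(day_fixes) || nrow(day_fixes) == 0) return(out)
  if (is.unsorted(day_fixes$timestamp)) {
    day_fixes <- day_fixes[order(day_fixes$timestamp), ]
  }
  lat <- day_fixes$lat; lon <- day_fixes$lon; ts <- day_fixes$timestamp
  v <- if (length(lat) < 2) 0 else stats::var(lat) + stats::var(lon)
  out["location_variance"] <- log(v + 1e-10)
  n <- length(lat)
  dist <- 0
  if (n >= 2) {
    seg <- haversine_km(lat[-n], lon[-n], lat[-1], lon[-1])
    dt_h <- as.numeric(ts[-1] - ts[-n], units = "hours")
    ok <- dt_h > 0 & seg / dt_h <= speed_limit_kmh
    dist <- sum(seg[ok])
  }
  out["total_distance"] <- dist
  assignment <- if (".place" %in% names(day_fixes)) day_fixes$.place
                else place_assignment(day_fixes, places)
  dw <- dwell_table(ts, assignment)
  if (nrow(dw) == 0) {
    ent <- 0; nent <- 0; tah <- NA_real_
  } else {
    shares <- dw$minutes[dw$minutes > 0]
    pl <- dw$place_id[dw$minutes > 0]
    ent <- shannon_entropy(shares)
    nent <- if (length(shares) <= 1) 0 else ent / log(length(shares))
    tot <- sum(shares)
    tah <- if (tot > 0) 100 * sum(shares[pl == home_id]) / tot else NA_real_
  }
  out["location_entropy"] <- ent
  out["normalised_location_entropy"] <- nent
  out["time_at_home"] <- tah
  out
}

#' Daily communication features
#'
#' Eight features over one day's call log: frequency and duration of
#' answered + made (non-missed) calls, the same restricted to non-working
#' hours (outside 08:00-18:00), the number of missed calls, the number of
#' distinct contacts, and the entropy (nats) of per-contact call-duration
#' shares with its normalised variant (entropy / log n_contacts, 0 when at
#' most one contact). An empty log yields all zeros.
#'
#' @param day_calls One day of call records (`timestamp`, `contact_id`,
#'   `direction`, `duration_min`, `missed`).
#' @return One-row tibble with the eight features.
#' @export
communication_daily_features <- function(day_calls) {
  tibble::as_tibble_row(communication_daily_vec(day_calls))
}

communication_daily_vec <- function(day_calls) {
  if (is.null(day_calls) || nrow(day_calls) == 0) {
    return(c(total_calling_frequency = 0, total_calling_duration = 0,
             nonworking_calling_frequency = 0,
             nonworking_calling_duration = 0, missed_calls = 0,
             n_contacts = 0, calling_entropy = 0,
             normalised_calling_entropy = 0))
  }
  ok <- !day_calls$missed
  mins <- minutes_of_day(day_calls$timestamp)
  nonwork <- mins < 8 * 60 | mins >= 18 * 60
  dur_by_contact <- tapply(day_calls$duration_min[ok],
                           day_calls$contact_id[ok], sum)
  dur_by_contact <- dur_by_contact[!is.na(dur_by_contact) &
                                     dur_by_contact > 0]
  ent <- shannon_entropy(as.numeric(dur_by_contact))
  c(total_calling_frequency = sum(ok),
    total_calling_duration = sum(day_calls$duration_min[ok]),
    nonworking_calling_frequency = sum(ok & nonwork),
    nonworking_calling_duration = sum(day_calls$duration_min[ok & nonwork]),
    missed_calls = sum(day_calls$missed),
    n_contacts = length(unique(day_calls$contact_id[ok])),
    calling_entropy = ent,
    normalised_calling_entropy = if (length(dur_by_contact) <= 1) 0
                                 else ent / log(length(dur_by_contact)))
}

# unlock->lock sessions with orphan repair
screen_sessions <- function(screen_events) {
  if (is.null(screen_events) || nrow(screen_events) == 0) {
    return(tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC")))
  }
  ev <- screen_events[order(screen_events$timestamp), ]
  starts <- as.POSIXct(character(), tz = "UTC")
  ends <- as.POSIXct(character(), tz = "UTC")
  open <- NULL
  for (k in seq_len(nrow(ev))) {
    if (ev$event[k] == "unlock") {
      open <- ev$timestamp[k]            # an earlier unpaired unlock is dropped
    } else if (!is.null(open)) {
      starts <- c(starts, open); ends <- c(ends, ev$timestamp[k])
      open <- NULL
    }                                     # orphan lock dropped
  }
  tibble::tibble(start = starts, end = ends)
}

#' Daily phone-usage features
#'
#' `phone_usage_frequency` counts unlock-to-lock sessions starting on each
#' day; `phone_usage_duration` sums session minutes, with sessions crossing
#' midnight split at midnight (the post-midnight part counts towards the
#' next day's duration but not its frequency). Alternation violations in
#' the event stream are repaired by dropping orphan events.
#'
#' @param screen_events Tibble with `timestamp` and `event`
#'   (`"lock"`/`"unlock"`).
#' @return Tibble with `date`, `phone_usage_frequency`,
#'   `phone_usage_duration` for each day that has any usage.
#' @export
phone_usage_daily_features <- function(screen_events) {
  ses <- screen_sessions(screen_events)
  if (nrow(ses) == 0) {
    return(tibble::tibble(date = as.Date(character()),
                          phone_usage_frequency = numeric(),
                          phone_usage_duration = numeric()))
  }
  parts <- split_interval_vec(ses$start, ses$end)
  dur <- dplyr::summarise(dplyr::group_by(parts, .data$date),
                          phone_usage_duration = sum(.data$minutes),
                          .groups = "drop")
  freq <- dplyr::count(tibble::tibble(date = ts_date(ses$start)), .data$date,
                       name = "phone_usage_frequency")
  out <- dplyr::full_join(freq, dur, by = "date")
  out$phone_usage_frequency[is.na(out$phone_usage_frequency)] <- 0
  out$phone_usage_duration[is.na(out$phone_usage_duration)] <- 0
  dplyr::arrange(out[, c("date", "phone_usage_frequency",
                         "phone_usage_duration")], .data$date)
}

# sleep rule: onset = last app use of the previous day, unless the same day
# has app use before 02:00 (then the last such use); end = first app use
# after 05:00 on the day. NA when either endpoint is missing.
sleep_minutes_for_day <- function(day, day_apps_ts, prev_apps_ts) {
  m <- minutes_of_day(day_apps_ts)
  wake_cand <- day_apps_ts[m >= 300]
  if (length(wake_cand) == 0) return(NA_real_)
  wake <- min(wake_cand)
  early <- day_apps_ts[m < 120]
  onset <- if (length(early) > 0) max(early)
           else if (length(prev_apps_ts) > 0) max(prev_apps_ts)
           else as.POSIXct(NA)
  if (is.na(onset)) return(NA_real_)
  sl <- as.numeric(wake - onset, units = "mins")
  if (sl <= 0 || sl > 1440) NA_real_ else sl
}

#' Daily user-activity features
#'
#' `lock_screen_duration` is the complement of the day's phone-usage
#' duration within 24 h; `n_used_apps` counts distinct apps used during the
#' day; `midnight_app_usage` counts distinct apps used between 00:00 and
#' 05:00; `sleep_time` applies the app-gap rule: from the last app use of
#' the previous day (or of the same day before 02:00, if any) to the first
#' app use after 05:00.
#'
#' @param app_events The day's app events (`timestamp`, `app_id`).
#' @param screen_events The day's screen events (for usage duration).
#' @param prev_day_app_events The previous day's app events.
#' @param date The day (defaults to the modal date of `app_events`).
#' @return One-row tibble with the four features.
#' @export
user_activity_daily_features <- function(app_events, screen_events,
                                         prev_day_app_events,
                                         date = NULL) {
  if (is.null(date)) {
    date <- if (!is.null(app_events) && nrow(app_events) > 0) {
      ts_date(app_events$timestamp[1])
    } else if (!is.null(screen_events) && nrow(screen_events) > 0) {
      ts_date(screen_events$timestamp[1])
    } else as.Date(NA)
  }
  usage <- phone_usage_daily_features(screen_events)
  usage_min <- if (nrow(usage) > 0 && !is.na(date) && date %in% usage$date) {
    usage$phone_usage_duration[usage$date == date]
  } else 0
  has_apps <- !is.null(app_events) && nrow(app_events) > 0
  apps_ts <- if (has_apps) app_events$timestamp
             else as.POSIXct(character(), tz = "UTC")
  prev_ts <- if (!is.null(prev_day_app_events) &&
                 nrow(prev_day_app_events) > 0) {
    prev_day_app_events$timestamp
  } else as.POSIXct(character(), tz = "UTC")
  m <- minutes_of_day(apps_ts)
  tibble::tibble(
    lock_screen_duration = 1440 - usage_min,
    n_used_apps = if (has_apps) length(unique(app_events$app_id)) else 0,
    midnight_app_usage = if (has_apps) {
      length(unique(app_events$app_id[m < 300]))
    } else 0,
    sleep_time = sleep_minutes_for_day(date, apps_ts, prev_ts))
}
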