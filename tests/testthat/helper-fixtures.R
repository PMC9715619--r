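# Hand-constructed two-day event fixture with feature values that can be
# recomputed by hand. Day 2 (2021-06-02) is the day under test; day 1
# provides the previous-day app events for the sleep rule.
#
# Geography: home H = (48, 11), place B = (48, 11.02) (~1.49 km east).
# Day-2 GPS: at H every 30 min 00:00-06:00 (13 fixes), at B 10:00-11:00
# (3 fixes), back at H at 12:00 (1 fix). Dwell: H 360 min, B 60 min.
golden_day1 <- as.Date("2021-06-01")
golden_day2 <- as.Date("2021-06-02")

golden_streams <- function() {
  ts2 <- function(min) make_ts_test(golden_day2, min)
  ts1 <- function(min) make_ts_test(golden_day1, min)
  gps <- tibble::tibble(
    timestamp = c(ts2(seq(0, 360, by = 30)), ts2(c(600, 630, 660)),
                  ts2(720)),
    lat = rep(48, 17),
    lon = c(rep(11, 13), rep(11.02, 3), 11))
  calls <- tibble::tibble(
    timestamp = ts2(c(7.5 * 60, 12 * 60, 13 * 60, 20 * 60)),
    contact_id = c("C1", "C2", "C3", "C2"),
    direction = c("incoming", "outgoing", "incoming", "outgoing"),
    duration_min = c(5, 15, 0, 10),
    missed = c(FALSE, FALSE, TRUE, FALSE))
  screen <- tibble::tibble(
    timestamp = c(ts1(23 * 60 + 50), ts2(10), ts2(9 * 60), ts2(9 * 60 + 10),
                  ts2(21 * 60), ts2(21 * 60 + 5)),
    event = c("unlock", "lock", "unlock", "lock", "unlock", "lock"))
  apps <- tibble::tibble(
    timestamp = c(ts1(13 * 60), ts1(23 * 60),
                  ts2(7 * 60), ts2(10 * 60 + 5), ts2(21 * 60 + 1)),
    app_id = c("app_1", "app_2", "app_1", "app_3", "app_1"))
  ema <- tibble::tibble(
    timestamp = ts2(c(9 * 60, 14 * 60, 20 * 60)),
    happy = c(4, 5, 3), active = c(2, 2, 2),
    tense = c(1, 2, 3), sad = c(0, 1, 2))
  items <- c("cesd_5", "cesd_7", "cesd_20", "psqi_6", "bads_1", "bads_5",
             "bads_7", "pdd_agentic", "pdd_communal", "pdd_workload")
  diary <- tibble::tibble(date = golden_day2, item_id = items,
                          value = seq(0.5, 5, by = 0.5))
  list(subject_id = "G01", sex = "female",
       gps = gps, calls = calls, screen = screen, apps = apps, ema = ema,
       diary = diary,
       phq2 = tibble::tibble(date = golden_day2, value = 2),
       phq9 = tibble::tibble(date = as.Date(character()), value = numeric()),
       dropped = tibble::tibble(date = as.Date(character()),
                                stream = character()))
}

make_ts_test <- function(date, minutes) {
  as.POSIXct(as.numeric(date) * 86400 + minutes * 60,
             origin = "1970-01-01", tz = "UTC")
}

ts_date_test <- function(ts) {
  as.Date(floor(as.numeric(ts) / 86400), origin = "1970-01-01")
}
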