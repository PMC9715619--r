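#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @useDynLib moodcast, .registration = TRUE
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shannon entropy (nats) of a positive share vector; zero-shares dropped.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  p <- p / sum(p)
  -sum(p * log(p))
}

# all timestamps are naive local time stored as UTC, so day arithmetic is
# plain integer arithmetic on the epoch seconds
minutes_of_day <- function(ts) (as.numeric(ts) %% 86400) / 60

ts_date <- function(ts) {
  as.Date(floor(as.numeric(ts) / 86400), origin = "1970-01-01")
}

make_ts <- function(date, minutes) {
  # whole-second resolution, as device event logs have
  as.POSIXct(round(as.numeric(date) * 86400 + minutes * 60),
             origin = "1970-01-01", tz = "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
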