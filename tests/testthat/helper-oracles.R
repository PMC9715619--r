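# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

oracle_rank <- function(x) {
  # average ranks, by explicit counting
  sapply(seq_along(x), function(i) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    less + (eq + 1) / 2
  })
}

oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

oracle_spearman <- function(y, yhat) {
  oracle_pearson(oracle_rank(y), oracle_rank(yhat))
}

oracle_spearman_local <- function(subject, y, yhat) {
  vals <- c()
  for (s in unique(subject)) {
    ys <- y[subject == s]; ps <- yhat[subject == s]
    if (length(ys) < 2 || length(unique(ys)) == 1 ||
        length(unique(ps)) == 1) next
    vals <- c(vals, oracle_spearman(ys, ps))
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

oracle_mae <- function(y, yhat) {
  tot <- 0
  for (i in seq_along(y)) tot <- tot + abs(yhat[i] - y[i])
  tot / length(y)
}

oracle_sex_score <- function(sex, y, yhat) {
  oracle_mae(y[sex == "female"], yhat[sex == "female"]) -
    oracle_mae(y[sex == "male"], yhat[sex == "male"])
}

oracle_sex_bias <- function(sex, y, yhat) {
  mean(yhat[sex == "female"] - y[sex == "female"]) -
    mean(yhat[sex == "male"] - y[sex == "male"])
}

oracle_gini <- function(x) {
  if (mean(x) == 0) return(0)
  tot <- 0
  for (i in seq_along(x)) {
    for (j in seq_along(x)) tot <- tot + abs(x[i] - x[j])
  }
  tot / (2 * length(x)^2 * mean(x))
}

oracle_dm <- function(x) {
  med <- stats::median(x)
  lower <- 0; upper <- 0
  for (v in x) {
    if (v < med) lower <- lower + (med - v)
    if (v > med) upper <- upper + (v - med)
  }
  c(dmli = lower, dmui = upper)
}

# windows built directly (bypassing extraction) for model/CV tests:
# target = affine function of feature 1 on the last day + optional
# per-subject offset, plus noise
make_synthetic_windows <- function(n_subjects = 3, n_per_subject = 12,
                                   d = 4, seed = 1, offsets = NULL,
                                   noise_sd = 0, sexes = NULL) {
  set.seed(seed)
  offsets <- offsets %||% rep(0, n_subjects)
  sexes <- sexes %||% rep(c("female", "male"), length.out = n_subjects)
  rows <- list()
  wid <- 0
  for (i in seq_len(n_subjects)) {
    for (k in seq_len(n_per_subject)) {
      wid <- wid + 1
      seq_mat <- matrix(rnorm(7 * d), nrow = 7,
                        dimnames = list(NULL, paste0("f", seq_len(d))))
      target <- 2 * seq_mat[7, 1] + 1 + offsets[i] + rnorm(1, 0, noise_sd)
      rows[[wid]] <- tibble::tibble(
        window_id = wid, subject_id = sprintf("S%02d", i),
        sex = sexes[i], label_date = as.Date("2021-06-01") + k,
        task = "prediction", target = target,
        sequence = list(seq_mat),
        imputed = list(matrix(FALSE, 7, d)))
    }
  }
  w <- dplyr::bind_rows(rows)
  attr(w, "feature_order") <- paste0("f", seq_len(d))
  attr(w, "standardised_scope") <- "population"
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
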