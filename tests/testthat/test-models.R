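test_that("analytic gradients match finite differences", {
  set.seed(1)
  d <- 4
  X <- array(rnorm(d * 7 * 6), dim = c(d, 7, 6))
  y <- rnorm(6)
  p <- moodcast:::cpp_gru_init(d, 5, 5, 42)
  lg <- moodcast:::cpp_gru_loss_grad(X, y, p)
  eps <- 1e-6
  worst <- 0
  for (nm in names(p)) {
    for (k in seq_len(min(4, length(p[[nm]])))) {
      pp <- p; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- p; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (moodcast:::cpp_gru_loss_grad(X, y, pp)$loss -
                moodcast:::cpp_gru_loss_grad(X, y, pm)$loss) / (2 * eps)
      worst <- max(worst, abs(num - lg$grads[[nm]][k]))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("the parameter count matches the closed form", {
  d <- length(feature_columns())
  w <- make_synthetic_windows(n_subjects = 2, n_per_subject = 4,
                              d = d, seed = 3)
  m <- train_baseline(w, w, config = train_config(epochs = 0))
  h <- 30; f <- 30
  expect_equal(n_parameters(m),
               3 * (d * h + h^2 + 2 * h) + 3 * (h * h + h^2 + 2 * h) +
                 (h * f + f) + (f + 1))
})

test_that("training is bit-reproducible under a fixed seed", {
  w <- make_synthetic_windows(n_subjects = 2, n_per_subject = 10, seed = 5)
  tr <- w[w$window_id <= 14, ]; dv <- w[w$window_id > 14, ]
  attr(tr, "feature_order") <- attr(dv, "feature_order") <-
    attr(w, "feature_order")
  cfg <- train_config(epochs = 20, seed = 9)
  m1 <- train_baseline(tr, dv, config = cfg)
  m2 <- train_baseline(tr, dv, config = cfg)
  expect_identical(serialize(m1$params, NULL), serialize(m2$params, NULL))
  expect_identical(predict(m1, dv), predict(m2, dv))
  expect_length(predict(m1, dv), nrow(dv))
})

test_that("the network fits a noiseless affine target", {
  w <- make_synthetic_windows(n_subjects = 2, n_per_subject = 10, d = 3,
                              seed = 7, noise_sd = 0)
  m <- train_baseline(w, w, config = train_config(epochs = 500, seed = 1))
  expect_lt(mean(abs(predict(m, w) - w$target)), 0.1)
})

test_that("transfer learning freezes the backbone and adapts per subject", {
  # subject S03's targets sit a constant +2 above the shared relation
  w <- make_synthetic_windows(n_subjects = 3, n_per_subject = 12, seed = 11,
                              offsets = c(0, 0, 2), noise_sd = 0.1)
  tr <- w[as.integer(w$label_date - as.Date("2021-06-01")) <= 9, ]
  dv <- w[as.integer(w$label_date - as.Date("2021-06-01")) > 9, ]
  attr(tr, "feature_order") <- attr(dv, "feature_order") <-
    attr(w, "feature_order")
  base <- train_baseline(tr, dv, config = train_config(epochs = 60,
                                                       seed = 2))
  tl <- personalise_transfer(base, tr, dv)
  expect_length(tl$models, 3)
  for (m in tl$models) {
    for (nm in c("Wi1", "Wh1", "bi1", "bh1", "Wi2", "Wh2", "bi2", "bh2")) {
      expect_identical(m$params[[nm]], base$params[[nm]])
    }
  }
  s3_tr <- tr[tr$subject_id == "S03", ]
  attr(s3_tr, "feature_order") <- attr(w, "feature_order")
  bias_base <- mean(predict(base, s3_tr) - s3_tr$target)
  bias_tl <- mean(predict(tl$models[["S03"]], s3_tr) - s3_tr$target)
  expect_lt(abs(bias_tl), abs(bias_base))
})

test_that("subgroup models are trained and routed per sex", {
  w <- make_synthetic_windows(n_subjects = 4, n_per_subject = 10, seed = 13,
                              sexes = c("female", "female", "male", "male"))
  tr <- w[w$window_id %% 5 != 0, ]; dv <- w[w$window_id %% 5 == 0, ]
  attr(tr, "feature_order") <- attr(dv, "feature_order") <-
    attr(w, "feature_order")
  sg <- train_subgroup(tr, dv, config = train_config(epochs = 10, seed = 3))
  expect_length(sg$models, 2)
  expect_setequal(names(sg$models), c("female", "male"))
  fem <- dv[dv$sex == "female", ]
  attr(fem, "feature_order") <- attr(w, "feature_order")
  expect_identical(predict(sg, fem), predict(sg$models[["female"]], fem))
  # single-sex cohort: the complement group is empty
  solo <- w[w$sex == "female", ]
  attr(solo, "feature_order") <- attr(w, "feature_order")
  expect_error(train_subgroup(solo, solo,
                              config = train_config(epochs = 1)),
               "single-sex")
})

test_that("SDS requires per-subject scope and equals baseline for one subject", {
  w <- make_synthetic_windows(n_subjects = 1, n_per_subject = 12, seed = 17)
  tr <- w[w$window_id <= 9, ]; dv <- w[w$window_id > 9, ]
  attr(tr, "feature_order") <- attr(dv, "feature_order") <-
    attr(w, "feature_order")
  expect_error(train_sds(tr, dv), "per_subject")
  pop <- fit_standardiser(tr, "population")
  per <- fit_standardiser(tr, "per_subject")
  cfg <- train_config(epochs = 15, seed = 4)
  base <- train_baseline(apply_standardiser(pop, tr),
                         apply_standardiser(pop, dv), config = cfg)
  sds <- train_sds(apply_standardiser(per, tr),
                   apply_standardiser(per, dv), config = cfg)
  expect_equal(predict(sds, apply_standardiser(per, dv)),
               predict(base, apply_standardiser(pop, dv)))
})

test_that("prediction respects clipping and window order", {
  w <- make_synthetic_windows(n_subjects = 2, n_per_subject = 8, seed = 19,
                              offsets = c(-30, 30))
  m <- train_baseline(w, w, config = train_config(epochs = 30, seed = 5))
  unclipped <- predict(m, w)
  expect_true(any(unclipped < 0 | unclipped > 6))
  clipped <- predict(m, w, clip = TRUE)
  expect_true(all(clipped >= 0 & clipped <= 6))
  perm <- sample(nrow(w))
  wp <- w[perm, ]
  attr(wp, "feature_order") <- attr(w, "feature_order")
  expect_identical(predict(m, wp), unclipped[perm])
})
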