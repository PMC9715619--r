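#' Architecture of the recurrent regressor
#'
#' Two GRU layers (hidden size 30), a fully connected ReLU layer with 30
#' neurons and 20% dropout after it, and a single linear output neuron.
#'
#' @param input_dim Number of input features per day.
#' @param hidden_size GRU hidden size.
#' @param fc_size Fully connected layer width.
#' @param dropout Dropout rate after the FC layer, in `[0, 1)`.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(input_dim, hidden_size = 30, fc_size = 30,
                       dropout = 0.2) {
  stopifnot(input_dim >= 1, hidden_size >= 1, fc_size >= 1,
            dropout >= 0, dropout < 1)
  structure(list(input_dim = as.integer(input_dim),
                 gru_layers = 2L,
                 hidden_size = as.integer(hidden_size),
                 fc_size = as.integer(fc_size),
                 dropout = dropout, output_dim = 1L),
            class = "model_spec")
}

#' Training protocol
#'
#' @param epochs Training epochs (default 100).
#' @param batch_size Minibatch size (default 8).
#' @param learning_rate Adam learning rate (default 0.01).
#' @param seed Integer seed controlling initialisation, batch shuffling and
#'   dropout; fixed seed + fixed data gives bit-identical models.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 8,
                         learning_rate = 0.01, seed = 1) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "train_config")
}

# windows -> (d x 7 x n) array in the recorded feature order, oldest day
# first
windows_to_array <- function(windows, feature_order) {
  n <- nrow(windows)
  if (n == 0) stop("no windows", call. = FALSE)
  t_len <- nrow(windows$sequence[[1]])
  d <- length(feature_order)
  X <- array(0, dim = c(d, t_len, n))
  for (k in seq_len(n)) {
    X[, , k] <- t(windows$sequence[[k]][, feature_order, drop = FALSE])
  }
  X
}

#' Number of trainable parameters
#'
#' @param x A `moodcast_model` or parameter list.
#' @return Integer count.
#' @export
n_parameters <- function(x) {
  p <- if (inherits(x, "moodcast_model")) x$params else x
  sum(vapply(p, length, integer(1)))
}

new_model <- function(params, spec, strategy, owner, fit, config,
                      feature_order, std_scope) {
  structure(list(params = params, spec = spec, strategy = strategy,
                 owner = owner, selected_epoch = fit$selected_epoch,
                 dev_mae = fit$dev_mae, config = config,
                 feature_order = feature_order,
                 standardised_scope = std_scope),
            class = "moodcast_model")
}

check_windows <- function(train_windows, dev_windows) {
  if (nrow(train_windows) == 0) stop("empty training set", call. = FALSE)
  if (nrow(dev_windows) == 0) stop("empty development set", call. = FALSE)
}

#' Train the population baseline model
#'
#' Fits the recurrent regressor on all subjects' (population-standardised)
#' training windows with MAE loss and Adam; the returned parameter state is
#' the epoch with the best development-set MAE.
#'
#' @param train_windows,dev_windows Standardised windows.
#' @param spec A [model_spec()]; defaults to the standard architecture for
#'   the windows' feature dimension.
#' @param config A [train_config()].
#' @return A `moodcast_model`.
#' @export
train_baseline <- function(train_windows, dev_windows, spec = NULL,
                           config = train_config()) {
  check_windows(train_windows, dev_windows)
  fcols <- attr(train_windows, "feature_order") %||% feature_columns()
  spec <- spec %||% model_spec(length(fcols))
  X <- windows_to_array(train_windows, fcols)
  Xd <- windows_to_array(dev_windows, fcols)
  p0 <- cpp_gru_init(spec$input_dim, spec$hidden_size, spec$fc_size,
                     config$seed)
  fit <- cpp_gru_train(X, train_windows$target, Xd, dev_windows$target, p0,
                       config$epochs, config$batch_size,
                       config$learning_rate, spec$dropout,
                       config$seed + 1, FALSE)
  new_model(fit$params, spec, "baseline", "population", fit, config, fcols,
            attr(train_windows, "standardised_scope"))
}

#' Train one common model over subject-wise standardised inputs
#'
#' Identical architecture and protocol to [train_baseline()]; the
#' personalisation lives entirely in the subject-dependent standardisation
#' of the windows, which must have been applied with `per_subject` scope.
#'
#' @inheritParams train_baseline
#' @return A `moodcast_model` with strategy `"sds"`.
#' @export
train_sds <- function(train_windows, dev_windows, spec = NULL,
                      config = train_config()) {
  scope <- attr(train_windows, "standardised_scope")
  if (!identical(scope, "per_subject")) {
    stop("train_sds requires windows standardised with per_subject scope",
         call. = FALSE)
  }
  m <- train_baseline(train_windows, dev_windows, spec, config)
  m$strategy <- "sds"
  m
}

#' Fine-tune personalised heads on a shared frozen backbone
#'
#' Takes a trained baseline, freezes its two GRU layers, and re-trains the
#' fully connected + output layers separately on every subject's training
#' windows (epoch selected on that subject's development windows),
#' yielding one personalised model per subject. Head weights start from the
#' pretrained baseline head.
#'
#' @param baseline A `moodcast_model` trained on the same feature space.
#' @param train_windows,dev_windows Standardised windows for all subjects.
#' @param config A [train_config()]; defaults to the baseline's.
#' @return A `moodcast_model_set` keyed by subject id.
#' @export
personalise_transfer <- function(baseline, train_windows, dev_windows,
                                 config = NULL) {
  stopifnot(inherits(baseline, "moodcast_model"))
  config <- config %||% baseline$config
  check_windows(train_windows, dev_windows)
  subjects <- sort(unique(train_windows$subject_id))
  models <- lapply(seq_along(subjects), function(k) {
    s <- subjects[k]
    tr <- train_windows[train_windows$subject_id == s, ]
    dv <- dev_windows[dev_windows$subject_id == s, ]
    attr(tr, "feature_order") <- baseline$feature_order
    attr(dv, "feature_order") <- baseline$feature_order
    if (nrow(dv) == 0) {
      stop("subject ", s, " has no development windows", call. = FALSE)
    }
    X <- windows_to_array(tr, baseline$feature_order)
    Xd <- windows_to_array(dv, baseline$feature_order)
    fit <- cpp_gru_train(X, tr$target, Xd, dv$target, baseline$params,
                         config$epochs, config$batch_size,
                         config$learning_rate, baseline$spec$dropout,
                         config$seed + 100 + k, TRUE)
    new_model(fit$params, baseline$spec, "transfer_learning", s, fit,
              config, baseline$feature_order, baseline$standardised_scope)
  })
  names(models) <- subjects
  structure(list(models = models, strategy = "transfer_learning",
                 routing = "subject_id", spec = baseline$spec,
                 feature_order = baseline$feature_order),
            class = "moodcast_model_set")
}

#' Train per-sex subgroup models
#'
#' One model with the baseline architecture per group; inference routes
#' each window to its subject's group model.
#'
#' @param train_windows,dev_windows Standardised windows.
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @param group_key Grouping column (default `"sex"`).
#' @return A `moodcast_model_set` keyed by group.
#' @export
train_subgroup <- function(train_windows, dev_windows, spec = NULL,
                           config = train_config(), group_key = "sex") {
  check_windows(train_windows, dev_windows)
  fcols <- attr(train_windows, "feature_order") %||% feature_columns()
  groups <- sort(unique(c(train_windows[[group_key]],
                          dev_windows[[group_key]])))
  if (group_key == "sex" && length(groups) < 2) {
    stop("single-", group_key, " cohort: the complement subgroup is empty",
         call. = FALSE)
  }
  models <- lapply(seq_along(groups), function(k) {
    g <- groups[k]
    tr <- train_windows[train_windows[[group_key]] == g, ]
    dv <- dev_windows[dev_windows[[group_key]] == g, ]
    if (nrow(tr) == 0) stop("group ", g, " has no training windows",
                            call. = FALSE)
    if (nrow(dv) == 0) stop("group ", g, " has no development windows",
                            call. = FALSE)
    attr(tr, "feature_order") <- fcols
    attr(dv, "feature_order") <- fcols
    attr(tr, "standardised_scope") <- attr(train_windows,
                                           "standardised_scope")
    cfg <- config; cfg$seed <- config$seed + 10 * k
    m <- train_baseline(tr, dv, spec, cfg)
    m$strategy <- "subgroup"; m$owner <- g
    m
  })
  names(models) <- groups
  structure(list(models = models, strategy = "subgroup",
                 routing = group_key, spec = models[[1]]$spec,
                 feature_order = fcols),
            class = "moodcast_model_set")
}

#' Predict PHQ-2 for windows
#'
#' @param object A `moodcast_model`.
#' @param windows Standardised windows.
#' @param clip Clamp predictions to the PHQ-2 range `[0, 6]` (off by
#'   default, matching how metrics are computed).
#' @param ... Unused.
#' @return Numeric vector, one prediction per window.
#' @export
predict.moodcast_model <- function(object, windows, clip = FALSE, ...) {
  X <- windows_to_array(windows, object$feature_order)
  yhat <- as.numeric(cpp_gru_predict(X, object$params))
  if (clip) yhat <- clamp(yhat, 0, 6)
  yhat
}

#' @describeIn predict.moodcast_model Routes each window to its owner model
#'   (by subject for transfer learning, by group for subgroup models).
#' @export
predict.moodcast_model_set <- function(object, windows, clip = FALSE, ...) {
  key <- windows[[object$routing]]
  if (any(is.na(key)) || !all(key %in% names(object$models))) {
    missing_keys <- unique(key[is.na(key) | !(key %in%
                                                names(object$models))])
    stop("no model for ", object$routing, ": ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  yhat <- numeric(nrow(windows))
  for (g in unique(key)) {
    sel <- key == g
    yhat[sel] <- predict.moodcast_model(object$models[[g]],
                                        windows[sel, ], clip = clip)
  }
  yhat
}

#' @export
print.moodcast_model <- function(x, ...) {
  cat(sprintf(
    "<moodcast_model> %s (owner: %s), %d parameters, epoch %d, dev MAE %.3f\n",
    x$strategy, x$owner, n_parameters(x), x$selected_epoch, x$dev_mae))
  invisible(x)
}

#' @export
print.moodcast_model_set <- function(x, ...) {
  cat(sprintf("<moodcast_model_set> %s: %d models routed by %s\n",
              x$strategy, length(x$models), x$routing))
  invisible(x)
}
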