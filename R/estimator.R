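#' GRU model configuration
#'
#' Hyperparameters of the valence and arousal regressors. The per-target
#' defaults are the published optima of the hyperparameter search: the
#' valence model uses a ReLU candidate activation, dropout 0.530, recurrent
#' dropout 0.266, learning rate 1.23e-5 and batch size 48; the arousal model
#' uses a linear ("none") candidate activation, dropout 0.680, recurrent
#' dropout 0.301, learning rate 1.01e-5 and batch size 32; both train for
#' 100 epochs under a mean-absolute-error loss. The recurrent layer width is
#' not part of the published table; the default here is a single GRU layer
#' of 32 units.
#'
#' @param target `"valence"` or `"arousal"`; selects which rating is the
#'   training label and which defaults apply.
#' @param hidden_units GRU layer width (positive integer).
#' @param activation Candidate-transformation activation, `"relu"` or
#'   `"none"` (linear). Gate activations are always sigmoid.
#' @param dropout,recurrent_dropout Dropout rates in `[0, 1)` on the gate
#'   inputs and the recurrent state respectively.
#' @param learning_rate Positive Adam step size.
#' @param batch_size,epochs Positive integers.
#' @param loss Only `"mean_absolute_error"` is supported.
#' @param seed Integer seed used when a training call does not supply one.
#' @return A `model_config` list.
#' @export
model_config <- function(target = c("valence", "arousal"),
                         hidden_units = 32L,
                         activation = NULL,
                         dropout = NULL,
                         recurrent_dropout = NULL,
                         learning_rate = NULL,
                         batch_size = NULL,
                         epochs = 100L,
                         loss = "mean_absolute_error",
                         seed = 0L) {
  target <- match.arg(target)
  def <- if (target == "valence") {
    list(activation = "relu", dropout = 0.530, recurrent_dropout = 0.266,
         learning_rate = 1.23e-5, batch_size = 48L)
  } else {
    list(activation = "none", dropout = 0.680, recurrent_dropout = 0.301,
         learning_rate = 1.01e-5, batch_size = 32L)
  }
  cfg <- list(target = target,
              hidden_units = as.integer(hidden_units),
              activation = activation %||% def$activation,
              dropout = dropout %||% def$dropout,
              recurrent_dropout = recurrent_dropout %||% def$recurrent_dropout,
              learning_rate = learning_rate %||% def$learning_rate,
              batch_size = as.integer(batch_size %||% def$batch_size),
              epochs = as.integer(epochs),
              loss = loss,
              seed = as.integer(seed))
  validate_model_config(cfg)
  structure(cfg, class = "model_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_model_config <- function(cfg) {
  if (!cfg$target %in% c("valence", "arousal"))
    abort_config("target must be 'valence' or 'arousal'")
  if (!is.finite(cfg$hidden_units) || cfg$hidden_units < 1L)
    abort_config("hidden_units must be a positive integer")
  if (!cfg$activation %in% c("relu", "none"))
    abort_config("activation must be 'relu' or 'none'")
  for (nm in c("dropout", "recurrent_dropout")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v >= 1)
      abort_config(sprintf("%s must lie in [0, 1)", nm))
  }
  if (!is.numeric(cfg$learning_rate) || cfg$learning_rate <= 0)
    abort_config("learning_rate must be positive")
  if (cfg$batch_size < 1L) abort_config("batch_size must be positive")
  if (cfg$epochs < 0L) abort_config("epochs must be non-negative")
  if (cfg$loss != "mean_absolute_error")
    abort_config("loss must be 'mean_absolute_error'")
  invisible(cfg)
}

#' Build an affect estimator
#'
#' Constructs an unfitted GRU regressor: one recurrent GRU layer
#' (`hidden_units` wide, activation/dropout per the config) over the
#' 5-frame x 17-AU input window, followed by a single linear output unit.
#' Predictions are clipped to the bounds of `output_scale` after inference.
#'
#' @param config A [model_config()].
#' @param output_scale Scale of the predictions: `"five"` (1-5) or `"nine"`
#'   (1-9). Training labels are converted to this scale before fitting.
#' @param n_features Input width; 17 for the full AU set, smaller when
#'   columns are dropped for importance analysis.
#' @return An unfitted `affect_estimator`.
#' @export
build_estimator <- function(config, output_scale = c("five", "nine"),
                            n_features = length(au_ids())) {
  validate_model_config(config)
  output_scale <- match.arg(output_scale)
  structure(list(config = config, weights = NULL, fitted = FALSE,
                 output_scale = output_scale,
                 n_features = as.integer(n_features)),
            class = "affect_estimator")
}

#' @export
print.affect_estimator <- function(x, ...) {
  cat(sprintf("<affect_estimator> target = %s, %s, %d hidden units, %d parameters\n",
              x$config$target, if (x$fitted) "fitted" else "unfitted",
              x$config$hidden_units, n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Closed form for a single classic GRU layer plus a linear unit:
#' `3 * (d * h + h^2 + h) + h + 1` for `d` input features and `h` hidden
#' units.
#'
#' @param est An `affect_estimator`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(est) {
  stopifnot(inherits(est, "affect_estimator"))
  gru_param_count(est$n_features, est$config$hidden_units)
}

episode_label <- function(ep, target, output_scale) {
  r <- ep[[target]]
  if (r$scale == "five" && output_scale == "nine") r <- convert_rating(r)
  if (r$scale == "nine" && output_scale == "five") r <- revert_rating(r)
  r$value
}

episodes_to_xy <- function(episodes, target, output_scale, n_features) {
  if (length(episodes) == 0L) abort_data("no episodes to train on")
  scales <- vapply(episodes, function(e) e$valence$scale, character(1))
  if (length(unique(scales)) > 1L)
    abort_data("episodes mix rating scales; convert before training")
  d <- ncol(episodes[[1]]$window)
  if (d != n_features)
    abort_format(sprintf("window width %d does not match estimator input width %d",
                         d, n_features))
  n <- length(episodes)
  X <- array(0, dim = c(n, 5L, d))
  for (i in seq_len(n)) X[i, , ] <- unclass(episodes[[i]]$window)
  y <- vapply(episodes, episode_label, numeric(1),
              target = target, output_scale = output_scale)
  list(X = X, y = y)
}

#' Train an affect estimator
#'
#' Fits the GRU regressor on rated episodes. The label is the rating named
#' by `config$target`; labels are converted to the estimator's output scale
#' (via the I' = 2I - 1 rule) before fitting. Training is deterministic
#' given `seed`: weight initialisation, minibatch shuffling and dropout
#' masks are all drawn from it.
#'
#' @param est An `affect_estimator` from [build_estimator()].
#' @param episodes List of [rated_episode()]s sharing one rating scale.
#' @param seed Integer seed; defaults to the config's seed.
#' @return The fitted estimator.
#' @export
train_estimator <- function(est, episodes, seed = NULL) {
  stopifnot(inherits(est, "affect_estimator"))
  cfg <- est$config
  seed <- as.integer(seed %||% cfg$seed)
  xy <- episodes_to_xy(episodes, cfg$target, est$output_scale, est$n_features)
  est$weights <- gru_fit(xy$X, xy$y,
                         hidden_units = cfg$hidden_units,
                         activation = cfg$activation,
                         dropout = cfg$dropout,
                         recurrent_dropout = cfg$recurrent_dropout,
                         learning_rate = cfg$learning_rate,
                         batch_size = cfg$batch_size,
                         epochs = cfg$epochs,
                         seed = seed,
                         init_params = est$weights)
  est$fitted <- TRUE
  est
}

window_to_array <- function(window, n_features) {
  m <- unclass(window)
  if (!is.matrix(m) || nrow(m) != 5L || ncol(m) != n_features)
    abort_format(sprintf("expected a 5 x %d window", n_features))
  X <- array(0, dim = c(1L, 5L, n_features))
  X[1, , ] <- m
  X
}

#' Predict a rating from one AU window
#'
#' Runs the fitted GRU over a single 5-frame window and returns a real
#' rating clipped to the estimator's output-scale bounds. Inference is
#' deterministic (dropout is inactive).
#'
#' @param est A fitted `affect_estimator`.
#' @param window An `au_window` (or 5 x d matrix) matching the estimator's
#'   input width.
#' @return A single finite rating value.
#' @export
predict_rating <- function(est, window) {
  stopifnot(inherits(est, "affect_estimator"))
  if (!est$fitted) abort_state("estimator is not fitted; train it first")
  X <- window_to_array(window, est$n_features)
  raw <- gru_infer(est$weights, X, est$config$activation)
  lim <- scale_bounds(est$output_scale)
  min(max(raw, lim[1]), lim[2])
}

#' Predict per-second ratings for a continuous session
#'
#' Applies [predict_rating()] independently to every per-second window; no
#' temporal state is carried across seconds at inference time.
#'
#' @param est A fitted `affect_estimator`.
#' @param session A [continuous_session()].
#' @return Numeric vector, one prediction per window.
#' @export
predict_session <- function(est, session) {
  stopifnot(inherits(session, "continuous_session"))
  if (!est$fitted) abort_state("estimator is not fitted; train it first")
  n <- length(session$windows)
  d <- est$n_features
  X <- array(0, dim = c(n, 5L, d))
  for (i in seq_len(n)) X[i, , ] <- window_to_array(session$windows[[i]], d)[1, , ]
  raw <- gru_infer(est$weights, X, est$config$activation)
  lim <- scale_bounds(est$output_scale)
  pmin(pmax(raw, lim[1]), lim[2])
}

#' Save and load a fitted estimator
#'
#' Persists the configuration as JSON alongside a JSON weights file
#' (`<stem>_config.json`, `<stem>_weights.json`). Loading re-validates the
#' configuration invariants.
#'
#' @param est A fitted `affect_estimator`.
#' @param stem File path stem (without suffix).
#' @return `save_estimator()` returns `stem` invisibly; `load_estimator()`
#'   returns the estimator.
#' @export
save_estimator <- function(est, stem) {
  stopifnot(inherits(est, "affect_estimator"))
  cfg_path <- paste0(stem, "_config.json")
  w_path <- paste0(stem, "_weights.json")
  meta <- c(unclass(est$config),
            list(output_scale = est$output_scale, n_features = est$n_features,
                 fitted = est$fitted))
  jsonlite::write_json(meta, cfg_path, auto_unbox = TRUE, digits = NA)
  weights <- lapply(est$weights, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
    else list(dim = length(p), data = as.numeric(p))
  })
  jsonlite::write_json(weights, w_path, digits = NA)
  invisible(stem)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(stem) {
  cfg_path <- paste0(stem, "_config.json")
  w_path <- paste0(stem, "_weights.json")
  if (!file.exists(cfg_path) || !file.exists(w_path))
    abort_data(sprintf("no estimator files at stem '%s'", stem))
  meta <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  cfg <- model_config(target = meta$target, hidden_units = meta$hidden_units,
                      activation = meta$activation, dropout = meta$dropout,
                      recurrent_dropout = meta$recurrent_dropout,
                      learning_rate = meta$learning_rate,
                      batch_size = meta$batch_size, epochs = meta$epochs,
                      loss = meta$loss, seed = meta$seed)
  est <- build_estimator(cfg, output_scale = meta$output_scale,
                         n_features = meta$n_features)
  raw <- jsonlite::read_json(w_path, simplifyVector = TRUE)
  est$weights <- lapply(raw, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2])
    else if (identical(as.integer(p$dim), 1L) && length(p$data) == 1L) p$data
    else as.numeric(p$data)
  })
  # scalar bias round-trips as length-1 numeric
  est$weights$b <- as.numeric(est$weights$b)
  est$fitted <- isTRUE(meta$fitted)
  est
}
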