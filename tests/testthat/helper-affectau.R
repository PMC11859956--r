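# Shared fixtures and the scaled-down training configuration used by the
# recovery experiments.

# Training configuration for desk-scale recovery experiments: published
# architecture and dropout rates, but a step size sized for the small
# number of optimiser updates these experiments take (an Adam-family
# update moves parameters by at most ~lr per step, so the published
# full-scale learning rates cannot move a freshly initialised network
# measurably within tens of epochs on a few hundred episodes).
recovery_config <- function(target, epochs = 30L, seed = 0L) {
  model_config(target, epochs = epochs, learning_rate = 1e-2, seed = seed)
}

# Minimal OpenFace-dialect AU table as a data frame.
make_au_df <- function(n = 5, fps = 30, success = rep(1L, n),
                       confidence = rep(0.98, n), intensity = NULL) {
  au_cols <- au_columns()
  m <- if (is.null(intensity)) {
    matrix(stats::runif(n * length(au_cols), 0, 2), n, length(au_cols))
  } else {
    matrix(intensity, n, length(au_cols))
  }
  colnames(m) <- au_cols
  cbind(data.frame(frame = seq_len(n), timestamp = (seq_len(n) - 1) / fps,
                   confidence = confidence, success = success),
        as.data.frame(m))
}

write_au_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A constant-activation series for the dimensional baseline.
constant_activation_series <- function(value, duration = 120, fps = 2) {
  ts <- seq(0, duration, by = 1 / fps)
  m <- matrix(value, length(ts), length(baseline_au_set()))
  colnames(m) <- baseline_au_set()
  data.frame(timestamp = ts, m)
}

# Tiny rated-episode set where one AU column linearly encodes the label and
# everything else is silent; learnable to r ~ 1.
identity_episodes <- function(n_participants = 3, target = "valence",
                              au = "12", seed = 1) {
  E <- matrix(0, 17, 2,
              dimnames = list(as.character(au_ids()), c("valence", "arousal")))
  E[au, target] <- 0.5
  other <- setdiff(c("valence", "arousal"), target)
  E["17", other] <- 0.5
  spec <- generator_spec(n_participants = n_participants, effect_matrix = E,
                         noise_sd = 0, participant_sd = 0, seed = seed)
  windowed_episodes(generate_rated_episodes(spec))
}
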