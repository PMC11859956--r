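# Seeded generators for rated-episode and continuous-session data with a
# known linear AU-to-affect ground truth, so the whole pipeline is testable
# without any external recordings.

#' Default AU effect matrix
#'
#' Ground-truth linear coefficients mapping affect deviations to AU
#' responses. The default plants coefficients of magnitude 0.4 on four AUs
#' per target, mirroring the qualitative importance pattern recovered from
#' real data: valence loads positively on AU 12 (lip corner puller), AU 1
#' (inner brow raiser) and AU 6 (cheek raiser) and negatively on AU 4 (brow
#' lowerer); arousal loads positively on AUs 4, 6, 7 and 17.
#'
#' @return 17 x 2 numeric matrix, rows named by AU id, columns
#'   `valence`/`arousal`.
#' @export
default_effect_matrix <- function() {
  E <- matrix(0, nrow = length(au_ids()), ncol = 2,
              dimnames = list(as.character(au_ids()), c("valence", "arousal")))
  E["12", "valence"] <- 0.4
  E["1", "valence"] <- 0.4
  E["6", "valence"] <- 0.4
  E["4", "valence"] <- -0.4
  E["4", "arousal"] <- 0.4
  E["6", "arousal"] <- 0.4
  E["7", "arousal"] <- 0.4
  E["17", "arousal"] <- 0.4
  E
}

#' Synthetic-data generator specification
#'
#' Parameters of the ground-truth emission model. Each AU's intensity is
#' `baseline + gain(t) * (E %*% affect_deviation + participant_effect) +
#' noise`, truncated at zero, where `E` is the effect matrix,
#' `affect_deviation` is the centred affect state (on the 1-5 scale:
#' `(valence - 3, arousal - 3)`), `participant_effect` is a per-participant
#' per-AU normal offset with sd `participant_sd`, and `noise` is i.i.d.
#' normal with sd `noise_sd`.
#'
#' @param n_participants Number of participants.
#' @param effect_matrix 17 x 2 coefficient matrix (rows = AU ids, columns =
#'   valence, arousal); at least one nonzero coefficient per target.
#' @param baseline_au Neutral AU intensities; single value recycled or a
#'   17-vector.
#' @param noise_sd Frame-level Gaussian noise sd on AU intensities.
#' @param participant_sd Sd of the per-participant AU offsets.
#' @param rating_noise_sd Sd of the Gaussian noise added to stored session
#'   ratings (episode ratings are exact grid labels).
#' @param frame_rate Video frame rate in Hz.
#' @param seed Integer seed; every generated dataset is a pure function of
#'   the spec.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_participants = 24L,
                           effect_matrix = default_effect_matrix(),
                           baseline_au = 0.5,
                           noise_sd = 0.3,
                           participant_sd = 0.2,
                           rating_noise_sd = 0.2,
                           frame_rate = 30,
                           seed = 1L) {
  n_au <- length(au_ids())
  if (length(baseline_au) == 1L) baseline_au <- rep(baseline_au, n_au)
  if (length(baseline_au) != n_au)
    abort_config(sprintf("baseline_au must have length 1 or %d", n_au))
  if (!is.matrix(effect_matrix) || nrow(effect_matrix) != n_au ||
      ncol(effect_matrix) != 2L)
    abort_config(sprintf("effect_matrix must be %d x 2", n_au))
  if (all(effect_matrix[, 1] == 0) || all(effect_matrix[, 2] == 0))
    abort_config("effect_matrix needs at least one nonzero coefficient per target")
  for (nm in c("noise_sd", "participant_sd", "rating_noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || !is.finite(v) || v < 0)
      abort_config(sprintf("%s must be a finite non-negative number", nm))
  }
  if (frame_rate <= 0) abort_config("frame_rate must be positive")
  structure(list(n_participants = as.integer(n_participants),
                 effect_matrix = effect_matrix,
                 baseline_au = as.numeric(baseline_au),
                 noise_sd = noise_sd, participant_sd = participant_sd,
                 rating_noise_sd = rating_noise_sd,
                 frame_rate = frame_rate, seed = as.integer(seed)),
            class = "generator_spec")
}

# Onset-hold-offset gain: 0 -> 1 over [0, 1] s, 1 over [1, 3] s, 1 -> 0
# over [3, 4] s.
episode_ramp <- function(t) {
  pmin(1, pmax(0, pmin(t, 4 - t)))
}

emit_au_frames <- function(ts, gain, dev, p_eff, spec, noise) {
  n_au <- length(au_ids())
  drive <- as.numeric(spec$effect_matrix %*% dev) + p_eff
  m <- outer(gain, drive) + matrix(spec$baseline_au, length(ts), n_au,
                                   byrow = TRUE) + noise
  m <- pmax(m, 0)
  colnames(m) <- au_columns()
  df <- data.frame(timestamp = ts, confidence = 1, success = 1L)
  new_au_frames(cbind(df, as.data.frame(m)))
}

#' Generate rated episodes on the 5 x 5 affect grid
#'
#' Emulates a rated-episode database: per participant, exactly 25 four-second
#' episodes covering every combination of valence and arousal levels 1-5.
#' Each episode's AU trajectory ramps from neutral to the target expression
#' over 1 s, holds it for 2 s and returns over 1 s, following the linear
#' emission model of the [generator_spec()].
#'
#' @param spec A [generator_spec()].
#' @return A `episode_dataset`: list of episode records, each with
#'   `participant_id`, `episode_id`, `frames` (an `au_frames` table),
#'   `valence` and `arousal` (`au_rating`s on the five scale).
#' @export
generate_rated_episodes <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  grid <- expand.grid(valence = 1:5, arousal = 1:5)
  n_au <- length(au_ids())
  ts <- seq(0, 4, by = 1 / spec$frame_rate)
  episodes <- with_seed(spec$seed, {
    out <- vector("list", spec$n_participants * nrow(grid))
    k <- 0L
    for (p in seq_len(spec$n_participants)) {
      pid <- sprintf("P%02d", p)
      p_eff <- stats::rnorm(n_au, 0, spec$participant_sd)
      for (g in seq_len(nrow(grid))) {
        dev <- c(grid$valence[g] - 3, grid$arousal[g] - 3)
        noise <- matrix(stats::rnorm(length(ts) * n_au, 0, spec$noise_sd),
                        length(ts), n_au)
        frames <- emit_au_frames(ts, episode_ramp(ts), dev, p_eff, spec, noise)
        k <- k + 1L
        out[[k]] <- list(participant_id = pid,
                         episode_id = sprintf("E%02d", g),
                         frames = frames,
                         valence = rating(grid$valence[g], "five"),
                         arousal = rating(grid$arousal[g], "five"))
      }
    }
    out
  })
  structure(episodes, class = "episode_dataset")
}

#' @export
print.episode_dataset <- function(x, ...) {
  pids <- unique(vapply(x, function(e) e$participant_id, character(1)))
  cat(sprintf("<episode_dataset> %d episodes, %d participants\n",
              length(x), length(pids)))
  invisible(x)
}

#' Window a rated-episode dataset for training
#'
#' Applies the standard preprocessing to every generated episode: locate
#' the most prominently expressed one-second segment
#' ([select_peak_segment()]) and sample the five-frame window
#' ([extract_window()]).
#'
#' @param dataset A `episode_dataset` from [generate_rated_episodes()].
#' @return List of [rated_episode()]s.
#' @export
windowed_episodes <- function(dataset) {
  lapply(dataset, function(e) {
    start <- select_peak_segment(e$frames)
    rated_episode(e$participant_id, extract_window(e$frames, start),
                  e$valence, e$arousal)
  })
}

#' Generate a continuous session with per-second ratings
#'
#' Emulates a continuously rated viewing session: smooth latent valence and
#' arousal trajectories on the 1-9 scale (sums of three low-frequency
#' sinusoids with seeded random frequencies and phases around a midpoint of
#' 5), AU frames emitted by the same linear model (with the latent state
#' mapped back to 1-5-scale deviations), one five-frame window per second,
#' and stored per-second ratings equal to the latent value at the window
#' centre plus Gaussian rating noise, clipped to `[1, 9]`.
#'
#' @param spec A [generator_spec()].
#' @param duration Session length in seconds (>= 3).
#' @param participant_id Identifier stored on the session.
#' @return A [continuous_session()] with attributes `latent_valence`,
#'   `latent_arousal` (per-second latent values) and `frames` (the full
#'   `au_frames` table).
#' @export
generate_session_like <- function(spec, duration, participant_id = "S01") {
  stopifnot(inherits(spec, "generator_spec"))
  if (duration < 3) abort_config("duration must be at least 3 s")
  duration <- as.integer(duration)
  n_au <- length(au_ids())
  with_seed(spec$seed, {
    latent_fun <- function() {
      freq <- stats::runif(3, 0.005, 0.05)
      phase <- stats::runif(3, 0, 2 * pi)
      amp <- c(1.5, 1.0, 0.5)
      function(t) {
        5 + colSums(amp * sin(outer(2 * pi * freq, t) + phase))
      }
    }
    val_fun <- latent_fun()
    aro_fun <- latent_fun()
    ts <- seq(0, duration, by = 1 / spec$frame_rate)
    dev_v <- (val_fun(ts) + 1) / 2 - 3   # back to 1-5-scale deviations
    dev_a <- (aro_fun(ts) + 1) / 2 - 3
    drive <- spec$effect_matrix %*% rbind(dev_v, dev_a)   # n_au x n_frames
    noise <- matrix(stats::rnorm(length(ts) * n_au, 0, spec$noise_sd),
                    length(ts), n_au)
    p_eff <- stats::rnorm(n_au, 0, spec$participant_sd)
    m <- t(drive + p_eff) + matrix(spec$baseline_au, length(ts), n_au,
                                   byrow = TRUE) + noise
    m <- pmax(m, 0)
    colnames(m) <- au_columns()
    frames <- new_au_frames(cbind(
      data.frame(timestamp = ts, confidence = 1, success = 1L),
      as.data.frame(m)))
    secs <- 0:(duration - 1L)
    windows <- lapply(secs, function(s) extract_window(frames, s))
    lat_v <- val_fun(secs + 0.5)
    lat_a <- aro_fun(secs + 0.5)
    clip9 <- function(x) pmin(pmax(x, 1), 9)
    rat_v <- clip9(lat_v + stats::rnorm(length(secs), 0, spec$rating_noise_sd))
    rat_a <- clip9(lat_a + stats::rnorm(length(secs), 0, spec$rating_noise_sd))
    session <- continuous_session(participant_id, windows,
                                  clip9(rat_v), clip9(rat_a))
    attr(session, "latent_valence") <- clip9(lat_v)
    attr(session, "latent_arousal") <- clip9(lat_a)
    attr(session, "frames") <- frames
    session
  })
}

#' Generate category and activation series for the dimensional baseline
#'
#' Seeded smooth series of the seven emotion-category intensities and the
#' 19 baseline AU activations, all in `[0, 1]`, with an optional step event
#' for window-correction tests.
#'
#' @param spec A [generator_spec()] (only `seed` is used).
#' @param duration Series length in seconds.
#' @param frame_rate Sampling rate in Hz (default 5).
#' @param constant If non-`NULL`, a single value in `[0, 1]`: every
#'   category and activation is held constant at it.
#' @param step Optional `list(time =, column =, delta =)`: at `time`
#'   seconds, `delta` is added to activation `column` for the rest of the
#'   series (clipped to `[0, 1]`).
#' @return List with data frames `categories` (`timestamp` + 7 columns) and
#'   `activations` (`timestamp` + 19 columns).
#' @export
generate_category_series <- function(spec, duration, frame_rate = 5,
                                     constant = NULL, step = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  ts <- seq(0, duration, by = 1 / frame_rate)
  smooth01 <- function(n_cols) {
    vapply(seq_len(n_cols), function(j) {
      freq <- stats::runif(2, 0.005, 0.05)
      phase <- stats::runif(2, 0, 2 * pi)
      base <- stats::runif(1, 0.2, 0.8)
      x <- base + 0.3 * sin(2 * pi * freq[1] * ts + phase[1]) +
        0.15 * sin(2 * pi * freq[2] * ts + phase[2])
      pmin(pmax(x, 0), 1)
    }, numeric(length(ts)))
  }
  with_seed(spec$seed, {
    if (!is.null(constant)) {
      cat_m <- matrix(constant, length(ts), 7)
      act_m <- matrix(constant, length(ts), length(baseline_au_set()))
    } else {
      cat_m <- smooth01(7)
      act_m <- smooth01(length(baseline_au_set()))
    }
    colnames(cat_m) <- baseline_categories()
    colnames(act_m) <- baseline_au_set()
    if (!is.null(step)) {
      act_m[ts >= step$time, step$column] <-
        pmin(pmax(act_m[ts >= step$time, step$column] + step$delta, 0), 1)
    }
    list(categories = data.frame(timestamp = ts, cat_m),
         activations = data.frame(timestamp = ts, act_m))
  })
}

#' Write and read a rated-episode dataset on disk
#'
#' `write_dataset()` emits one OpenFace-dialect AU CSV per episode under
#' `dir/au/`, a `ratings.csv` (`participant_id, episode_id, valence,
#' arousal, scale`) and a `spec.json`; `read_dataset()` loads such a
#' directory back into a `episode_dataset`, so generated data round-trips
#' through the same readers used for real recordings.
#'
#' @param dataset A `episode_dataset`.
#' @param dir Dataset directory.
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()` a
#'   `episode_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "au"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset, function(e) {
    write_au_table(e$frames, file.path(dir, "au",
                                       sprintf("%s_%s.csv", e$participant_id,
                                               e$episode_id)))
    data.frame(participant_id = e$participant_id, episode_id = e$episode_id,
               valence = e$valence$value, arousal = e$arousal$value,
               scale = e$valence$scale)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "ratings.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  ratings_path <- file.path(dir, "ratings.csv")
  if (!file.exists(ratings_path))
    abort_data(sprintf("no ratings.csv under %s", dir))
  ratings <- utils::read.csv(ratings_path, strip.white = TRUE)
  need <- c("participant_id", "episode_id", "valence", "arousal", "scale")
  miss <- setdiff(need, names(ratings))
  if (length(miss) > 0L)
    abort_format(sprintf("ratings.csv missing column(s): %s",
                         paste(miss, collapse = ", ")))
  episodes <- lapply(seq_len(nrow(ratings)), function(i) {
    row <- ratings[i, ]
    path <- file.path(dir, "au", sprintf("%s_%s.csv", row$participant_id,
                                         row$episode_id))
    list(participant_id = as.character(row$participant_id),
         episode_id = as.character(row$episode_id),
         frames = read_au_table(path),
         valence = rating(row$valence, row$scale),
         arousal = rating(row$arousal, row$scale))
  })
  structure(episodes, class = "episode_dataset")
}
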