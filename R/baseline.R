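# Category/AU-based dimensional baseline: valence from emotion-category
# intensities, arousal from rolling-mean-corrected AU activations.

#' Emotion categories and the baseline AU activation set
#'
#' The baseline consumes two kinds of per-frame input: intensities of the
#' seven emotion categories (six basic plus neutral), and activations of a
#' 19-item AU set — AUs 1, 2, 4, 5, 6, 7, 9, 10, 12, 14, 15, 17, 20, 23,
#' 24, 25, 26, 27, and the inverse of AU 43 (one minus the eye-closure
#' activation), all on `[0, 1]`.
#'
#' @return Character vectors of the category / activation column names.
#' @export
baseline_categories <- function() {
  c("happy", "sad", "angry", "scared", "disgusted", "surprised", "neutral")
}

#' @rdname baseline_categories
#' @export
baseline_au_set <- function() {
  c(sprintf("AU%02d", c(1L, 2L, 4L, 5L, 6L, 7L, 9L, 10L, 12L, 14L, 15L,
                        17L, 20L, 23L, 24L, 25L, 26L, 27L)), "invAU43")
}

negative_categories <- function() c("sad", "angry", "scared", "disgusted")

check_unit_interval <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    abort_format(sprintf("%s must lie in [0, 1]", what))
}

#' Baseline dimensional valence from category intensities
#'
#' Valence is the intensity of `happy` minus the intensity of the strongest
#' negative category among `sad`, `angry`, `scared` and `disgusted`
#' (`surprised` and `neutral` are treated as valence-neutral). For example,
#' happy 0.8 against negatives 0.2, 0.0, 0.3, 0.2 gives 0.8 - 0.3 = 0.5.
#'
#' @param intensities Named numeric vector (or single-row data frame)
#'   containing all seven category intensities in `[0, 1]`.
#' @return Valence in `[-1, 1]`.
#' @export
baseline_valence <- function(intensities) {
  if (is.data.frame(intensities)) intensities <- unlist(intensities[1, ])
  miss <- setdiff(baseline_categories(), names(intensities))
  if (length(miss) > 0L)
    abort_format(sprintf("missing category intensit%s: %s",
                         if (length(miss) > 1L) "ies" else "y",
                         paste(miss, collapse = ", ")))
  vals <- as.numeric(intensities[baseline_categories()])
  check_unit_interval(vals, "category intensities")
  unname(intensities[["happy"]] -
           max(as.numeric(intensities[negative_categories()])))
}

validate_activation_series <- function(series) {
  need <- c("timestamp", baseline_au_set())
  miss <- setdiff(need, names(series))
  if (length(miss) > 0L)
    abort_format(sprintf("activation series missing column(s): %s",
                         paste(miss, collapse = ", ")))
  check_unit_interval(as.matrix(series[, baseline_au_set(), drop = FALSE]),
                      "AU activations")
  if (is.unsorted(series$timestamp))
    abort_format("activation series must be ordered by timestamp")
  invisible(series)
}

#' Rolling-mean-corrected AU activations
#'
#' For each baseline AU, subtracts from the activation at time `t` the mean
#' activation over the trailing 60 seconds (frames with timestamps in
#' `(t - 60, t]`). During the first 60 seconds the mean is taken over all
#' frames observed up to `t`.
#'
#' @param series Data frame with a `timestamp` column (seconds) plus the 19
#'   [baseline_au_set()] activation columns, ordered by timestamp.
#' @param t Time in seconds; a frame must exist at or before `t`.
#' @param window Trailing window length in seconds (default 60).
#' @return Named numeric vector of corrected activations over the 19 AUs.
#' @export
corrected_activations <- function(series, t, window = 60) {
  validate_activation_series(series)
  ts <- series$timestamp
  upto <- which(ts <= t + 1e-9)
  if (length(upto) == 0L)
    abort_data(sprintf("no activation frames at or before t = %.3f s", t))
  cur_idx <- max(upto)
  lo <- t - window
  in_win <- which(ts > lo + 1e-9 & ts <= t + 1e-9)
  if (length(in_win) == 0L) in_win <- cur_idx
  m <- as.matrix(series[, baseline_au_set(), drop = FALSE])
  colMeans2 <- if (length(in_win) == 1L) m[in_win, ] else colMeans(m[in_win, , drop = FALSE])
  out <- m[cur_idx, ] - colMeans2
  names(out) <- baseline_au_set()
  out
}

#' Baseline arousal from corrected activations
#'
#' Arousal at time `t` is the mean of the five highest corrected activation
#' values (values are ranked, not AU identities; duplicates are all
#' eligible). No clamping is applied.
#'
#' @inheritParams corrected_activations
#' @return Arousal value (unbounded; typically small).
#' @export
baseline_arousal <- function(series, t, window = 60) {
  ca <- corrected_activations(series, t, window)
  mean(sort(ca, decreasing = TRUE)[1:5])
}

#' Score a session with the dimensional baseline
#'
#' Computes per-timestamp baseline valence (from the category series) and
#' arousal (from the activation series). The two series must share their
#' timestamps.
#'
#' @param categories Data frame with `timestamp` plus the seven category
#'   columns.
#' @param activations Data frame with `timestamp` plus the 19 activation
#'   columns.
#' @return Data frame `timestamp, valence, arousal`.
#' @export
baseline_series <- function(categories, activations) {
  validate_activation_series(activations)
  miss <- setdiff(c("timestamp", baseline_categories()), names(categories))
  if (length(miss) > 0L)
    abort_format(sprintf("category series missing column(s): %s",
                         paste(miss, collapse = ", ")))
  if (nrow(categories) != nrow(activations) ||
      any(abs(categories$timestamp - activations$timestamp) > 1e-9))
    abort_data("category and activation series must share timestamps")
  ts <- activations$timestamp
  val <- vapply(seq_len(nrow(categories)), function(i) {
    baseline_valence(unlist(categories[i, baseline_categories()]))
  }, numeric(1))
  aro <- vapply(ts, function(t) baseline_arousal(activations, t), numeric(1))
  data.frame(timestamp = ts, valence = val, arousal = aro)
}
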