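#' Action units used by the estimation model
#'
#' The model consumes the intensities of 17 facial action units (FACS AUs)
#' as tracked by OpenFace: AUs 1, 2, 4, 5, 6, 7, 9, 10, 12, 14, 15, 17, 20,
#' 23, 25, 26 and 45.
#'
#' @return `au_ids()` returns the integer AU identifiers in ascending order;
#'   `au_columns()` returns the corresponding OpenFace intensity column names
#'   (`"AU01_r"`, ..., `"AU45_r"`).
#' @export
au_ids <- function() {
  c(1L, 2L, 4L, 5L, 6L, 7L, 9L, 10L, 12L, 14L, 15L, 17L, 20L, 23L, 25L, 26L, 45L)
}

#' @rdname au_ids
#' @export
au_columns <- function() {
  sprintf("AU%02d_r", au_ids())
}

meta_columns <- function() c("frame", "timestamp", "confidence", "success")

new_au_frames <- function(df) {
  structure(df, class = c("au_frames", "data.frame"))
}

validate_au_frames <- function(frames) {
  need <- c("timestamp", "confidence", "success", au_columns())
  miss <- setdiff(need, names(frames))
  if (length(miss) > 0L)
    abort_format(sprintf("AU frame table is missing column(s): %s",
                         paste(miss, collapse = ", ")))
  vals <- as.matrix(frames[, au_columns(), drop = FALSE])
  if (any(!is.finite(vals)))
    abort_format("AU intensities must be finite")
  if (any(vals < 0))
    abort_format("AU intensities must be non-negative")
  if (is.unsorted(frames$timestamp))
    abort_format("AU frames must be ordered by timestamp")
  invisible(frames)
}

#' Read an OpenFace-style AU intensity table
#'
#' Reads a per-frame CSV in the OpenFace 2.x dialect (header row with
#' `frame, timestamp, confidence, success` plus `AUxx_r` intensity columns;
#' whitespace after commas is tolerated, extra columns are ignored) and keeps
#' only the 17 model AU columns.
#'
#' Rows are ordered by timestamp. Rows with `success == 0` are dropped when
#' `require_success` is `TRUE`, and rows below `min_confidence` are dropped.
#'
#' @param path Path to the CSV file.
#' @param min_confidence Minimum tracker confidence in `[0, 1]`; rows below
#'   it are discarded. Default `0` (filter off).
#' @param require_success Drop rows whose `success` flag is 0? Default `TRUE`.
#' @return An `au_frames` data frame with columns `timestamp`, `confidence`,
#'   `success` and the 17 `AUxx_r` intensity columns.
#' @export
read_au_table <- function(path, min_confidence = 0, require_success = TRUE) {
  if (!file.exists(path))
    abort_data(sprintf("AU table not found: %s", path))
  df <- utils::read.csv(path, strip.white = TRUE, check.names = TRUE)
  need <- c("timestamp", "confidence", "success", au_columns())
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    abort_format(sprintf("%s: missing required column(s): %s",
                         path, paste(miss, collapse = ", ")))
  df <- df[order(df$timestamp), c("timestamp", "confidence", "success", au_columns())]
  if (require_success) df <- df[df$success != 0, , drop = FALSE]
  df <- df[df$confidence >= min_confidence, , drop = FALSE]
  if (nrow(df) == 0L)
    abort_data(sprintf("%s: no frames left after success/confidence filtering", path))
  rownames(df) <- NULL
  validate_au_frames(new_au_frames(df))
}

#' Write an AU frame table in the OpenFace CSV dialect
#'
#' Inverse of [read_au_table()]: emits `frame, timestamp, confidence, success`
#' plus the 17 `AUxx_r` columns, so generated data round-trips through the
#' reader losslessly.
#'
#' @param frames An `au_frames` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_au_table <- function(frames, path) {
  validate_au_frames(frames)
  out <- data.frame(frame = seq_len(nrow(frames)),
                    timestamp = frames$timestamp,
                    confidence = frames$confidence,
                    success = as.integer(frames$success))
  out <- cbind(out, as.data.frame(frames)[, au_columns(), drop = FALSE])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract a one-second five-frame AU window
#'
#' Samples five frames at equal intervals over one second — target times
#' `start_time + {0, 0.25, 0.5, 0.75, 1}` s — taking for each target the
#' nearest available frame (no interpolation; ties resolved to the earlier
#' frame). The result is the model's input unit: a 5 x 17 matrix of AU
#' intensities in ascending AU-id column order.
#'
#' @param frames An `au_frames` data frame covering
#'   `[start_time, start_time + 1]`.
#' @param start_time Window start in seconds.
#' @return An `au_window`: 5 x 17 numeric matrix with attribute `start_time`.
#' @export
extract_window <- function(frames, start_time) {
  validate_au_frames(frames)
  ts <- frames$timestamp
  targets <- start_time + 0.25 * (0:4)
  if (length(ts) < 2L) {
    gap_tol <- Inf
  } else {
    gap_tol <- stats::median(diff(ts))
  }
  idx <- vapply(targets, function(tt) {
    d <- abs(ts - tt)
    which.min(d) # ties: which.min takes the first (earlier) frame
  }, integer(1))
  off <- abs(ts[idx] - targets)
  if (any(off > gap_tol + 1e-9))
    abort_data(sprintf(
      "insufficient coverage: no frame within one inter-frame interval of t = %.3f s",
      targets[which.max(off)]))
  m <- as.matrix(as.data.frame(frames)[idx, au_columns(), drop = FALSE])
  dimnames(m) <- list(NULL, au_columns())
  new_au_window(m, start_time)
}

new_au_window <- function(m, start_time, cols = au_columns()) {
  if (!is.matrix(m) || nrow(m) != 5L || ncol(m) != length(cols))
    abort_format(sprintf("AU window must be a 5 x %d matrix", length(cols)))
  if (any(!is.finite(m)))
    abort_format("AU window entries must be finite")
  structure(m, start_time = start_time, class = "au_window")
}

#' @export
print.au_window <- function(x, ...) {
  cat(sprintf("<au_window> start_time = %.3f s, 5 frames x %d AUs\n",
              attr(x, "start_time"), ncol(x)))
  print(unclass(x)[, seq_len(min(6L, ncol(x)))])
  if (ncol(x) > 6L) cat(sprintf("... %d more AU columns\n", ncol(x) - 6L))
  invisible(x)
}

#' Locate the most prominently expressed one-second segment
#'
#' Scans sliding one-second windows (candidate starts at frame resolution)
#' and returns the start time maximising the mean total AU intensity — the
#' sum over the 17 AUs averaged over the frames inside the window. Ties are
#' broken in favour of the earliest start.
#'
#' @param frames An `au_frames` data frame spanning at least one second.
#' @return Start time of the peak segment, in seconds.
#' @export
select_peak_segment <- function(frames) {
  validate_au_frames(frames)
  ts <- frames$timestamp
  if (max(ts) - min(ts) < 1 - 1e-9)
    abort_data("insufficient coverage: need at least 1 s of frames")
  total <- rowSums(as.data.frame(frames)[, au_columns(), drop = FALSE])
  starts <- ts[ts <= max(ts) - 1 + 1e-9]
  score <- vapply(starts, function(s) {
    inw <- ts >= s - 1e-9 & ts <= s + 1 + 1e-9
    mean(total[inw])
  }, numeric(1))
  starts[which.max(score)] # which.max: earliest index on ties
}

#' Affect ratings and the five-to-nine scale conversion
#'
#' Ratings live on one of two scales: the ordinal 1-5 scale used for rated
#' episodes, or the continuous 1-9 scale used for per-second session ratings.
#' `convert_rating()` maps a 1-5 rating I to the 1-9 scale via the affine rule
#' I' = 2I - 1; `revert_rating()` is its exact inverse I = (I' + 1) / 2.
#'
#' @param value Numeric rating value.
#' @param scale `"five"` (1-5) or `"nine"` (1-9).
#' @return `rating()` returns an `au_rating` object; `convert_rating()` an
#'   `au_rating` on the nine scale; `revert_rating()` one on the five scale.
#' @examples
#' convert_rating(rating(5, "five"))  # value 9
#' revert_rating(rating(5, "nine"))   # value 3
#' @export
rating <- function(value, scale = c("five", "nine")) {
  scale <- match.arg(scale)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    abort_domain("rating value must be a single finite number")
  lim <- scale_bounds(scale)
  if (value < lim[1] || value > lim[2])
    abort_domain(sprintf("rating %.3f outside the %s scale [%d, %d]",
                         value, scale, lim[1], lim[2]))
  structure(list(value = value, scale = scale), class = "au_rating")
}

scale_bounds <- function(scale) {
  switch(scale, five = c(1, 5), nine = c(1, 9),
         abort_domain(sprintf("unknown rating scale '%s'", scale)))
}

#' @rdname rating
#' @param r An `au_rating`.
#' @export
convert_rating <- function(r) {
  stopifnot(inherits(r, "au_rating"))
  if (r$scale != "five")
    abort_domain("convert_rating expects a rating on the five scale")
  rating(2 * r$value - 1, "nine")
}

#' @rdname rating
#' @export
revert_rating <- function(r) {
  stopifnot(inherits(r, "au_rating"))
  if (r$scale != "nine")
    abort_domain("revert_rating expects a rating on the nine scale")
  rating((r$value + 1) / 2, "five")
}

#' @export
print.au_rating <- function(x, ...) {
  cat(sprintf("<au_rating> %.3f on the %s scale\n", x$value, x$scale))
  invisible(x)
}

#' Rated episodes and continuous sessions
#'
#' A `rated_episode` pairs one AU window with a single valence and arousal
#' rating (both on the same scale); a `continuous_session` pairs an ordered
#' list of per-second AU windows with per-second valence/arousal rating
#' series on the 1-9 scale.
#'
#' @param participant_id Participant identifier.
#' @param window An `au_window`.
#' @param valence,arousal `au_rating`s sharing the same scale.
#' @return A `rated_episode` or `continuous_session` object.
#' @export
rated_episode <- function(participant_id, window, valence, arousal) {
  stopifnot(inherits(window, "au_window"),
            inherits(valence, "au_rating"), inherits(arousal, "au_rating"))
  if (valence$scale != arousal$scale)
    abort_domain("valence and arousal ratings must share one scale")
  structure(list(participant_id = participant_id, window = window,
                 valence = valence, arousal = arousal),
            class = "rated_episode")
}

#' @rdname rated_episode
#' @param windows List of `au_window`s, one per second.
#' @param valence_series,arousal_series Numeric per-second ratings on the
#'   1-9 scale, same length as `windows`.
#' @export
continuous_session <- function(participant_id, windows, valence_series,
                               arousal_series) {
  if (!all(vapply(windows, inherits, logical(1), "au_window")))
    abort_format("windows must be a list of au_window objects")
  n <- length(windows)
  if (length(valence_series) != n || length(arousal_series) != n)
    abort_format("windows, valence_series and arousal_series must have equal length")
  if (any(valence_series < 1 | valence_series > 9) ||
      any(arousal_series < 1 | arousal_series > 9))
    abort_domain("session ratings must lie on the 1-9 scale")
  structure(list(participant_id = participant_id, windows = windows,
                 valence_series = as.numeric(valence_series),
                 arousal_series = as.numeric(arousal_series)),
            class = "continuous_session")
}

#' @export
print.continuous_session <- function(x, ...) {
  cat(sprintf("<continuous_session> participant %s, %d seconds\n",
              as.character(x$participant_id), length(x$windows)))
  invisible(x)
}
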