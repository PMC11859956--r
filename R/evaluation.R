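#' Pearson correlation between actual and predicted ratings
#'
#' Standard product-moment coefficient; refuses degenerate inputs rather
#' than silently returning 0 or NA.
#'
#' @param actual,predicted Equal-length numeric vectors (length >= 3), each
#'   with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    abort_data("actual and predicted must have equal length")
  if (length(actual) < 3L)
    abort_data("need at least 3 pairs for a correlation")
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0)
    abort_data("correlation undefined: a series has zero variance")
  stats::cor(actual, predicted)
}

#' Fisher z-transformation
#'
#' Variance-stabilising transform `z = atanh(r)` applied to correlations
#' before t-testing.
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1))
    abort_domain("fisher_z requires |r| < 1")
  atanh(r)
}

new_group_inference <- function(mean_r, mean_z, t_stat, df, p, d) {
  structure(list(mean_r = mean_r, mean_z = mean_z, t_stat = t_stat,
                 df = as.integer(df), p_two_sided = p, cohens_d = d),
            class = "group_inference")
}

#' @export
print.group_inference <- function(x, ...) {
  cat(sprintf("<group_inference> mean r = %.3f, t(%d) = %.3f, p = %.4g, d = %.3f\n",
              x$mean_r, x$df, x$t_stat, x$p_two_sided, x$cohens_d))
  invisible(x)
}

#' One-sample t-test of Fisher-z values against zero
#'
#' `t = mean(z) / (sd(z) / sqrt(n))` with `df = n - 1`, two-sided p from the
#' t distribution, and Cohen's d = mean / sd. `mean_r` back-transforms the
#' mean z through tanh.
#'
#' @param zs Numeric vector of Fisher-z transformed correlations, length >= 2.
#' @return A `group_inference` with fields `mean_r`, `mean_z`, `t_stat`,
#'   `df`, `p_two_sided`, `cohens_d`.
#' @export
one_sample_t <- function(zs) {
  n <- length(zs)
  if (n < 2L) abort_data("need at least 2 values for a t-test")
  s <- stats::sd(zs)
  if (s == 0) abort_data("degenerate sample: zero standard deviation")
  m <- mean(zs)
  t_stat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  new_group_inference(tanh(m), m, t_stat, n - 1L, p, m / s)
}

#' Paired t-test on two sets of Fisher-z values
#'
#' Reduces to [one_sample_t()] on the element-wise differences
#' `zs_a - zs_b`.
#'
#' @param zs_a,zs_b Equal-length numeric vectors (length >= 2).
#' @return A `group_inference` on the differences.
#' @export
paired_t <- function(zs_a, zs_b) {
  if (length(zs_a) != length(zs_b))
    abort_data("paired t-test requires equal-length vectors")
  one_sample_t(zs_a - zs_b)
}

#' Leave-one-participant-out cross-validation
#'
#' For each participant, trains fresh valence and arousal estimators on all
#' other participants' episodes (seeded per fold as `seed + fold_index`),
#' predicts the held-out participant's episodes, and computes that
#' participant's Pearson correlation between actual and predicted ratings
#' for each target. Correlations are Fisher-z transformed and tested
#' against zero with a one-sample t-test per target. Participants whose
#' actual ratings have zero variance are flagged with a warning and
#' excluded from inference.
#'
#' @param episodes List of [rated_episode()]s covering >= 3 participants,
#'   each with >= 3 episodes.
#' @param config_valence,config_arousal [model_config()]s for the two
#'   targets.
#' @param seed Integer base seed.
#' @param output_scale Scale predictions and labels are placed on.
#' @return A `loocv_result`: `$results` (data frame with one row per
#'   participant: `participant_id`, `r_valence`, `r_arousal`, `n_pairs`),
#'   `$inference` (list with `group_inference` per target), and
#'   `$predictions` (long data frame `participant_id, unit_id, actual,
#'   predicted, target`).
#' @export
run_loocv <- function(episodes,
                      config_valence = model_config("valence"),
                      config_arousal = model_config("arousal"),
                      seed = 0L,
                      output_scale = c("five", "nine")) {
  output_scale <- match.arg(output_scale)
  pids <- vapply(episodes, function(e) as.character(e$participant_id), character(1))
  upid <- unique(pids)
  if (length(upid) < 3L) abort_data("LOOCV needs at least 3 participants")
  counts <- table(pids)
  if (any(counts < 3L))
    abort_data("every participant needs at least 3 episodes")
  configs <- list(valence = config_valence, arousal = config_arousal)

  rows <- vector("list", length(upid))
  preds <- vector("list", length(upid))
  for (fold in seq_along(upid)) {
    p <- upid[fold]
    test_idx <- which(pids == p)
    train_eps <- episodes[pids != p]
    test_eps <- episodes[test_idx]
    fold_seed <- as.integer(seed + fold)
    r <- list()
    pred_rows <- list()
    for (target in c("valence", "arousal")) {
      est <- build_estimator(configs[[target]], output_scale = output_scale,
                             n_features = ncol(episodes[[1]]$window))
      est <- train_estimator(est, train_eps, seed = fold_seed)
      actual <- vapply(test_eps, episode_label, numeric(1),
                       target = target, output_scale = output_scale)
      predicted <- vapply(test_eps, function(e) predict_rating(est, e$window),
                          numeric(1))
      r[[target]] <- if (stats::sd(actual) == 0 || stats::sd(predicted) == 0) {
        NA_real_
      } else {
        pearson_r(actual, predicted)
      }
      pred_rows[[target]] <- data.frame(
        participant_id = p, unit_id = seq_along(test_idx),
        actual = actual, predicted = predicted, target = target)
    }
    rows[[fold]] <- data.frame(participant_id = p,
                               r_valence = r$valence, r_arousal = r$arousal,
                               n_pairs = length(test_idx))
    preds[[fold]] <- do.call(rbind, pred_rows)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  inference <- list()
  for (target in c("valence", "arousal")) {
    col <- paste0("r_", target)
    rs <- results[[col]]
    if (anyNA(rs)) {
      warning(sprintf(
        "%d participant(s) with undefined %s correlation excluded from inference",
        sum(is.na(rs)), target))
      rs <- rs[!is.na(rs)]
    }
    inference[[target]] <- one_sample_t(fisher_z(rs))
  }
  structure(list(results = results, inference = inference,
                 predictions = do.call(rbind, preds)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %d participants\n", nrow(x$results)))
  for (target in names(x$inference)) {
    gi <- x$inference[[target]]
    cat(sprintf("  %s: mean r = %.3f, t(%d) = %.2f, p = %.3g, d = %.2f\n",
                target, gi$mean_r, gi$df, gi$t_stat, gi$p_two_sided,
                gi$cohens_d))
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' Emits the per-participant correlations as CSV, the group inference as
#' JSON, and the prediction dump as CSV
#' (`participant_id, unit_id, actual, predicted, target`).
#'
#' @param res A `loocv_result`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(res, dir) {
  stopifnot(inherits(res, "loocv_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$results, file.path(dir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(res$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(lapply(res$inference, unclass),
                       file.path(dir, "inference.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
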