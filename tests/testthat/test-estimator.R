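test_that("model configurations carry the published per-target defaults and validate", {
  v <- model_config("valence")
  expect_identical(v$activation, "relu")
  expect_equal(c(v$dropout, v$recurrent_dropout), c(0.530, 0.266))
  expect_equal(v$learning_rate, 1.23e-5)
  expect_identical(c(v$batch_size, v$epochs), c(48L, 100L))
  a <- model_config("arousal")
  expect_identical(a$activation, "none")
  expect_equal(c(a$dropout, a$recurrent_dropout), c(0.680, 0.301))
  expect_equal(a$learning_rate, 1.01e-5)
  expect_identical(c(a$batch_size, a$epochs), c(32L, 100L))
  expect_identical(a$loss, "mean_absolute_error")

  expect_error(model_config("valence", dropout = 1.0),
               class = "affectau_config_error")
  expect_error(model_config("valence", learning_rate = 0),
               class = "affectau_config_error")
  expect_error(model_config("valence", hidden_units = 0),
               class = "affectau_config_error")
})

test_that("prediction refuses unfitted models and clips to the output scale", {
  eps <- identity_episodes(3, seed = 2)
  est <- build_estimator(recovery_config("valence"), output_scale = "nine")
  expect_error(predict_rating(est, eps[[1]]$window),
               class = "affectau_state_error")

  est <- train_estimator(est, eps[1:30], seed = 4)
  p <- predict_rating(est, eps[[1]]$window)
  expect_true(is.finite(p) && p >= 1 && p <= 9)
  expect_identical(p, predict_rating(est, eps[[1]]$window))

  # wrong input shape
  expect_error(predict_rating(est, matrix(0, 4, 17)),
               class = "affectau_format_error")
})

test_that("labels are converted to the output scale before fitting", {
  # constant five-scale label 5 trained on the nine scale must approach 9
  eps <- identity_episodes(3, seed = 6)
  const <- lapply(eps[1:40], function(e) {
    rated_episode(e$participant_id, e$window, rating(5, "five"), rating(5, "five"))
  })
  cfg <- model_config("valence", epochs = 150, learning_rate = 2e-2,
                      dropout = 0, recurrent_dropout = 0, batch_size = 20)
  est <- train_estimator(build_estimator(cfg, output_scale = "nine"),
                         const, seed = 3)
  preds <- vapply(const, function(e) predict_rating(est, e$window), numeric(1))
  expect_equal(mean(preds), 9, tolerance = 0.1 / 9 * 3)
  expect_true(all(abs(preds - 9) < 0.5))
})

test_that("training rejects empty and mixed-scale episode lists", {
  eps <- identity_episodes(3, seed = 2)
  est <- build_estimator(recovery_config("valence"))
  expect_error(train_estimator(est, list(), seed = 1),
               class = "affectau_data_error")
  mixed <- eps[1:4]
  mixed[[2]] <- rated_episode(mixed[[2]]$participant_id, mixed[[2]]$window,
                              rating(5, "nine"), rating(5, "nine"))
  expect_error(train_estimator(est, mixed, seed = 1),
               class = "affectau_data_error")
})

test_that("session prediction is an element-wise map over windows", {
  spec <- generator_spec(n_participants = 2, seed = 31)
  sess <- generate_session_like(spec, duration = 12)
  eps <- identity_episodes(3, seed = 2)
  est <- train_estimator(build_estimator(recovery_config("valence", epochs = 5),
                                         output_scale = "nine"),
                         lapply(eps[1:30], function(e) {
                           rated_episode(e$participant_id, e$window,
                                         convert_rating(e$valence),
                                         convert_rating(e$arousal))
                         }), seed = 2)
  series <- predict_session(est, sess)
  expect_length(series, length(sess$windows))

  single <- continuous_session("S1", sess$windows[1],
                               sess$valence_series[1], sess$arousal_series[1])
  expect_equal(predict_session(est, single), predict_rating(est, sess$windows[[1]]))

  # shuffling windows permutes the output identically (no temporal state)
  set.seed(99)
  perm <- sample(length(sess$windows))
  shuffled <- continuous_session("S1", sess$windows[perm],
                                 sess$valence_series[perm],
                                 sess$arousal_series[perm])
  expect_equal(predict_session(est, shuffled), series[perm], tolerance = 1e-12)
})

test_that("estimators round-trip through save and load", {
  eps <- identity_episodes(3, seed = 12)
  est <- train_estimator(build_estimator(recovery_config("valence", epochs = 5)),
                         eps[1:30], seed = 8)
  stem <- file.path(tempfile("model"), "valence")
  dir.create(dirname(stem))
  save_estimator(est, stem)
  back <- load_estimator(stem)
  expect_identical(back$config$target, "valence")
  expect_true(back$fitted)
  for (e in eps[1:5])
    expect_equal(predict_rating(back, e$window), predict_rating(est, e$window),
                 tolerance = 1e-12)
  expect_error(load_estimator(tempfile()), class = "affectau_data_error")
})
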