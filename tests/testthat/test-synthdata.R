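test_that("episode generator covers the full 5 x 5 grid per participant", {
  spec <- generator_spec(n_participants = 3, seed = 44)
  ds <- generate_rated_episodes(spec)
  expect_length(ds, 75)
  pids <- vapply(ds, function(e) e$participant_id, character(1))
  expect_identical(unname(table(pids)), rep(25L, 3), ignore_attr = TRUE)
  for (p in unique(pids)) {
    labs <- t(vapply(ds[pids == p],
                     function(e) c(e$valence$value, e$arousal$value),
                     numeric(2)))
    grid <- expand.grid(v = 1:5, a = 1:5)
    expect_equal(labs[order(labs[, 2], labs[, 1]), ],
                 unname(as.matrix(grid[order(grid$a, grid$v), ])) * 1.0,
                 ignore_attr = TRUE)
  }
  # intensities are truncated at zero
  expect_true(all(vapply(ds, function(e) {
    all(as.matrix(as.data.frame(e$frames)[, au_columns()]) >= 0)
  }, logical(1))))
})

test_that("noiseless episodes follow the stated emission formula", {
  spec <- generator_spec(n_participants = 1, noise_sd = 0, participant_sd = 0,
                         seed = 3)
  ds <- generate_rated_episodes(spec)
  labs <- vapply(ds, function(e) c(e$valence$value, e$arousal$value), numeric(2))

  # neutral episode (v = 3, a = 3): AU(t) = baseline for every frame
  neutral <- ds[[which(labs[1, ] == 3 & labs[2, ] == 3)]]
  m <- as.matrix(as.data.frame(neutral$frames)[, au_columns()])
  expect_equal(m, matrix(0.5, nrow(m), 17), ignore_attr = TRUE)

  # (v = 5, a = 3): during the hold phase AU12 = baseline + 2 * coef
  ep <- ds[[which(labs[1, ] == 5 & labs[2, ] == 3)]]
  fr <- as.data.frame(ep$frames)
  hold <- fr$timestamp >= 1 & fr$timestamp <= 3
  coef12 <- default_effect_matrix()["12", "valence"]
  expect_equal(fr$AU12_r[hold], rep(0.5 + 2 * coef12, sum(hold)))
  # and the ramp is linear on the onset
  onset <- fr$timestamp <= 1
  expect_equal(fr$AU12_r[onset], 0.5 + fr$timestamp[onset] * 2 * coef12)
})

test_that("generation is a pure function of the spec seed", {
  spec <- generator_spec(n_participants = 2, seed = 10)
  expect_identical(generate_rated_episodes(spec), generate_rated_episodes(spec))
  spec2 <- generator_spec(n_participants = 2, seed = 11)
  expect_false(identical(generate_rated_episodes(spec), generate_rated_episodes(spec2)))

  s1 <- generate_category_series(spec, duration = 20)
  s2 <- generate_category_series(spec, duration = 20)
  expect_identical(s1, s2)
})

test_that("generator spec validates its fields", {
  expect_error(generator_spec(noise_sd = -1), class = "affectau_config_error")
  E <- default_effect_matrix(); E[, "arousal"] <- 0
  expect_error(generator_spec(effect_matrix = E),
               class = "affectau_config_error")
  expect_error(generator_spec(baseline_au = c(1, 2)),
               class = "affectau_config_error")
})

test_that("sessions pair one window per second with latent-driven ratings", {
  spec <- generator_spec(n_participants = 1, seed = 77)
  sess <- generate_session_like(spec, duration = 100)
  expect_length(sess$windows, 100)
  expect_length(sess$valence_series, 100)
  expect_length(sess$arousal_series, 100)
  expect_true(all(sess$valence_series >= 1 & sess$valence_series <= 9))

  # zero rating noise: stored ratings equal the latent trajectory samples
  quiet <- generator_spec(n_participants = 1, rating_noise_sd = 0, seed = 77)
  s2 <- generate_session_like(quiet, duration = 50)
  expect_equal(s2$valence_series, attr(s2, "latent_valence"))
  expect_equal(s2$arousal_series, attr(s2, "latent_arousal"))

  expect_error(generate_session_like(spec, duration = 2),
               class = "affectau_config_error")
})

test_that("noise-free AU emission tracks the latent valence trajectory", {
  E <- matrix(0, 17, 2,
              dimnames = list(as.character(au_ids()), c("valence", "arousal")))
  E["12", "valence"] <- 0.5
  E["17", "arousal"] <- 0.5
  spec <- generator_spec(n_participants = 1, effect_matrix = E, noise_sd = 0,
                         participant_sd = 0, rating_noise_sd = 0, seed = 13)
  sess <- generate_session_like(spec, duration = 120)
  frames <- attr(sess, "frames")
  sec <- floor(frames$timestamp)
  persec <- tapply(frames$AU12_r, sec, mean)[1:120]
  expect_gt(stats::cor(as.numeric(persec), attr(sess, "latent_valence")), 0.999)
})

test_that("category series honours constants and step events", {
  spec <- generator_spec(seed = 19)
  const <- generate_category_series(spec, duration = 10, constant = 0.4)
  expect_true(all(as.matrix(const$categories[baseline_categories()]) == 0.4))
  expect_true(all(as.matrix(const$activations[baseline_au_set()]) == 0.4))

  stepped <- generate_category_series(spec, duration = 200, constant = 0.2,
                                      step = list(time = 100, column = "AU04",
                                                  delta = 0.5))
  a <- stepped$activations
  expect_true(all(a$AU04[a$timestamp < 100] == 0.2))
  expect_true(all(a$AU04[a$timestamp >= 100] == 0.7))
  # the step occurs within exactly one frame interval
  jumps <- which(diff(a$AU04) != 0)
  expect_length(jumps, 1)

  # values stay in [0, 1]
  rnd <- generate_category_series(spec, duration = 100)
  expect_true(all(as.matrix(rnd$activations[baseline_au_set()]) >= 0))
  expect_true(all(as.matrix(rnd$activations[baseline_au_set()]) <= 1))
})

test_that("datasets round-trip through the OpenFace-dialect writers", {
  spec <- generator_spec(n_participants = 2, seed = 55)
  ds <- generate_rated_episodes(spec)
  dir <- tempfile("dataset")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_length(back, length(ds))
  ids <- function(x) paste(vapply(x, `[[`, character(1), "participant_id"),
                           vapply(x, `[[`, character(1), "episode_id"))
  expect_setequal(ids(back), ids(ds))
  ord <- match(ids(ds), ids(back))
  for (i in c(1, 20, 50)) {
    a <- as.data.frame(ds[[i]]$frames)
    b <- as.data.frame(back[[ord[i]]]$frames)
    for (col in au_columns())
      expect_equal(b[[col]], a[[col]], tolerance = 1e-10)
    expect_identical(back[[ord[i]]]$valence$value, ds[[i]]$valence$value)
  }
})
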