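test_that("reader returns ordered frames with exactly the 17 model AU features", {
  df <- make_au_df(n = 5)
  frames <- read_au_table(write_au_csv(df))
  expect_s3_class(frames, "au_frames")
  expect_equal(nrow(frames), 5)
  expect_identical(setdiff(names(frames), c("timestamp", "confidence", "success")),
                   au_columns())
  expect_length(au_columns(), 17)
  expect_false(is.unsorted(frames$timestamp))

  # shuffled rows come back in timestamp order
  path <- write_au_csv(df[c(3, 1, 5, 2, 4), ])
  expect_equal(read_au_table(path)$timestamp, df$timestamp)

  # extra columns are ignored, whitespace after commas tolerated
  lines <- readLines(write_au_csv(cbind(df, extra = 1)))
  lines <- gsub(",", ", ", lines)
  p <- tempfile(fileext = ".csv")
  writeLines(lines, p)
  frames2 <- read_au_table(p)
  expect_identical(names(frames2), c("timestamp", "confidence", "success", au_columns()))
})

test_that("reader applies success and confidence filters and reports errors", {
  df <- make_au_df(n = 5, success = c(1L, 0L, 1L, 1L, 1L))
  expect_equal(nrow(read_au_table(write_au_csv(df))), 4)
  expect_equal(nrow(read_au_table(write_au_csv(df), require_success = FALSE)), 5)

  df$confidence <- c(0.9, 0.9, 0.4, 0.9, 0.9)
  expect_equal(nrow(read_au_table(write_au_csv(df), min_confidence = 0.5)), 3)

  # missing column named in the error
  bad <- df[, setdiff(names(df), "AU06_r")]
  expect_error(read_au_table(write_au_csv(bad)), "AU06_r",
               class = "affectau_format_error")

  # empty after filtering
  none <- make_au_df(n = 3, success = rep(0L, 3))
  expect_error(read_au_table(write_au_csv(none)), "no frames",
               class = "affectau_data_error")
})

test_that("AU tables round-trip losslessly through write and read", {
  df <- make_au_df(n = 12)
  frames <- read_au_table(write_au_csv(df))
  p <- tempfile(fileext = ".csv")
  write_au_table(frames, p)
  back <- read_au_table(p)
  for (col in au_columns())
    expect_equal(back[[col]], frames[[col]], tolerance = 1e-12)
  expect_equal(back$timestamp, frames$timestamp, tolerance = 1e-12)
})

test_that("window extraction samples the nearest frame at five equal intervals", {
  # frames exactly at the 5 target times: identity
  df <- make_au_df(n = 5)
  df$timestamp <- c(0, 0.25, 0.5, 0.75, 1)
  frames <- read_au_table(write_au_csv(df))
  w <- extract_window(frames, 0)
  expect_identical(dim(unclass(w)), c(5L, 17L))
  expect_equal(unclass(w), as.matrix(as.data.frame(frames)[, au_columns()]),
               ignore_attr = TRUE)

  # 30 fps: nearest frames to 0, .25, .5, .75, 1
  df30 <- make_au_df(n = 40, fps = 30)
  f30 <- read_au_table(write_au_csv(df30))
  w30 <- extract_window(f30, 0)
  targets <- 0.25 * (0:4)
  expected_idx <- vapply(targets, function(tt) which.min(abs(f30$timestamp - tt)),
                         integer(1))
  expect_equal(unclass(w30),
               as.matrix(as.data.frame(f30)[expected_idx, au_columns()]),
               ignore_attr = TRUE)

  # 10 fps fixture against an exhaustive nearest-neighbour search
  df10 <- make_au_df(n = 25, fps = 10)
  f10 <- read_au_table(write_au_csv(df10))
  for (start in c(0, 0.3, 1.1)) {
    w10 <- extract_window(f10, start)
    brute_idx <- vapply(start + 0.25 * (0:4), function(tt) {
      d <- abs(f10$timestamp - tt)
      which(d == min(d))[1]
    }, integer(1))
    expect_equal(unclass(w10),
                 as.matrix(as.data.frame(f10)[brute_idx, au_columns()]),
                 ignore_attr = TRUE)
  }
})

test_that("window extraction never interpolates and rejects coverage gaps", {
  df <- make_au_df(n = 31, fps = 30)
  frames <- read_au_table(write_au_csv(df))
  w <- extract_window(frames, 0)
  pool <- as.matrix(as.data.frame(frames)[, au_columns()])
  for (i in 1:5)
    expect_true(any(apply(pool, 1, function(row) all(row == unclass(w)[i, ]))))

  # a hole bigger than one inter-frame interval around a target time
  gap <- df[df$timestamp < 0.4 | df$timestamp > 0.65, ]
  expect_error(extract_window(read_au_table(write_au_csv(gap)), 0),
               "coverage", class = "affectau_data_error")
})

test_that("peak-segment selection maximises mean total AU intensity", {
  # plateau in [1 s, 3 s] dominates: start must fall in [1, 2]
  n <- 121
  df <- make_au_df(n = n, fps = 30, intensity = 0.1)
  ts <- df$timestamp
  bump <- ifelse(ts >= 1 & ts <= 3, 2, 0)
  for (col in au_columns()) df[[col]] <- 0.1 + bump
  s <- select_peak_segment(read_au_table(write_au_csv(df)))
  expect_gte(s, 1)
  expect_lte(s, 2)

  # constant intensity: earliest start wins the tie
  flat <- make_au_df(n = n, fps = 30, intensity = 0.7)
  expect_equal(select_peak_segment(read_au_table(write_au_csv(flat))), 0)

  # random fixture equals an exhaustive scan at frame resolution
  set.seed(4)
  rnd <- make_au_df(n = 61, fps = 15)
  frames <- read_au_table(write_au_csv(rnd))
  total <- rowSums(as.data.frame(frames)[, au_columns()])
  starts <- frames$timestamp[frames$timestamp <= max(frames$timestamp) - 1 + 1e-9]
  score <- vapply(starts, function(s) {
    mean(total[frames$timestamp >= s - 1e-9 & frames$timestamp <= s + 1 + 1e-9])
  }, numeric(1))
  expect_equal(select_peak_segment(frames), starts[which.max(score)])

  short <- make_au_df(n = 5, fps = 30)
  expect_error(select_peak_segment(read_au_table(write_au_csv(short))),
               "1 s", class = "affectau_data_error")
})

test_that("rating conversion is the affine map I' = 2I - 1 with exact inverse", {
  expect_equal(convert_rating(rating(1, "five"))$value, 1)
  expect_equal(convert_rating(rating(3, "five"))$value, 5)
  expect_equal(convert_rating(rating(5, "five"))$value, 9)
  expect_identical(convert_rating(rating(2, "five"))$scale, "nine")

  # strictly increasing and affine; inverse round-trips to machine precision
  vals <- seq(1, 5, by = 0.25)
  conv <- vapply(vals, function(v) convert_rating(rating(v, "five"))$value,
                 numeric(1))
  expect_true(all(diff(conv) > 0))
  expect_equal(diff(conv), rep(0.5, length(vals) - 1))
  for (v in vals)
    expect_equal(revert_rating(convert_rating(rating(v, "five")))$value, v)

  expect_error(rating(0.5, "five"), class = "affectau_domain_error")
  expect_error(rating(9.5, "nine"), class = "affectau_domain_error")
  expect_error(convert_rating(rating(7, "nine")), class = "affectau_domain_error")
})

test_that("episode and session containers enforce their invariants", {
  eps <- identity_episodes(3, seed = 8)
  expect_error(rated_episode("P01", eps[[1]]$window,
                             rating(3, "five"), rating(7, "nine")),
               class = "affectau_domain_error")
  w <- eps[[1]]$window
  expect_error(continuous_session("S1", list(w, w), c(5, 5), c(5)),
               class = "affectau_format_error")
  s <- continuous_session("S1", list(w, w), c(5, 5), c(4, 6))
  expect_length(s$windows, 2)
})
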