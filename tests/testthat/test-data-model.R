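make_wide_csv <- function(path) {
  writeLines(c("time,mood,energy,hunger",
               "0,1,4,2",
               "1,2,5,2",
               "2,3,,3",
               "3,2,6,3",
               "4,1,7,2"), path)
  path
}

make_long_csv <- function(path) {
  rows <- c("time,item,value")
  vals <- list(mood = c(1, 2, 3, 2, 1), energy = c(4, 5, NA, 6, 7),
               hunger = c(2, 2, 3, 3, 2))
  for (it in names(vals)) {
    for (t in 0:4) {
      v <- vals[[it]][t + 1]
      rows <- c(rows, paste0(t, ",", it, ",", ifelse(is.na(v), "", v)))
    }
  }
  writeLines(rows, path)
  path
}

test_that("wide CSV parses with missing cells flagged and items in input order", {
  d <- read_ema_table(make_wide_csv(withr::local_tempfile(fileext = ".csv")),
                      layout = "wide")
  expect_s3_class(d, "ema_df")
  expect_equal(n_timepoints(d), 5)
  expect_equal(ema_items(d), c("mood", "energy", "hunger"))
  expect_equal(sum(d$missing), 1)
  expect_true(is.na(series_values(d, "energy")[3]))
})

test_that("long and wide layouts of the same table parse identically", {
  dw <- read_ema_table(make_wide_csv(withr::local_tempfile(fileext = ".csv")),
                       layout = "wide")
  dl <- read_ema_table(make_long_csv(withr::local_tempfile(fileext = ".csv")),
                       layout = "long")
  expect_equal(tibble::as_tibble(dw), tibble::as_tibble(dl))
  expect_equal(scale_spec(dw), scale_spec(dl))
})

test_that("reader rejects bad input with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,a", "0,1", "1,oops"), f)
  expect_error(read_ema_table(f, "wide"), class = "ema_parse_error")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,item,value", "0,a,1", "0,a,2"), f2)
  expect_error(read_ema_table(f2, "long"), class = "ema_data_error")

  f3 <- make_wide_csv(withr::local_tempfile(fileext = ".csv"))
  spec <- tibble::tibble(item = c("mood", "energy", "hunger", "ghost"),
                         scale_min = 1, scale_max = 7)
  expect_error(read_ema_table(f3, "wide", scale_spec = spec),
               class = "ema_config_error")
  expect_error(read_ema_table(f3, "wide",
                              scale_spec = spec[1:2, ]),
               class = "ema_config_error")
})

test_that("write/read round trip preserves values, masks and labels", {
  d <- generate_study_like_dataset(n_items = 4, n_timepoints = 60, seed = 9,
                                   baseline_end = 20, missing_rate = 0.05)
  for (layout in c("wide", "long")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_ema_table(d, f, layout)
    d2 <- read_ema_table(f, layout,
                         scale_spec = scale_spec(d),
                         baseline_end = baseline_end(d))
    expect_equal(ema_items(d2), ema_items(d))
    expect_equal(d2$missing, d$missing)
    # masked originals are not recoverable from CSV; compare observed cells
    expect_equal(d2$value[!d2$missing], d$value[!d$missing])
  }
})

test_that("rescaling maps endpoints, midpoints, and is invertible", {
  d <- as_ema_df(data.frame(time = 0:2, item = "bip", value = c(-3, 0, 3)),
                 scale_spec = data.frame(item = "bip", scale_min = -3,
                                         scale_max = 3))
  r <- rescale_items(d, 1, 7)
  expect_equal(series_values(r), c(1, 4, 7))

  d7 <- as_ema_df(data.frame(time = 0:2, item = "lik", value = c(1, 4, 7)),
                  scale_spec = data.frame(item = "lik", scale_min = 1,
                                          scale_max = 7))
  expect_equal(series_values(rescale_items(d7, 1, 7)), c(1, 4, 7))

  # order preservation + inverse map on random data
  set.seed(1)
  x <- runif(50, -3, 3)
  dr <- as_ema_df(data.frame(time = 0:49, item = "u", value = x),
                  scale_spec = data.frame(item = "u", scale_min = -3,
                                          scale_max = 3))
  fwd <- series_values(rescale_items(dr, 1, 7))
  expect_equal(order(fwd), order(x))
  back <- series_values(rescale_items(rescale_items(dr, 1, 7), -3, 3))
  expect_lt(max(abs(back - x) / pmax(abs(x), 1e-6)), 1e-12)

  dz <- as_ema_df(data.frame(time = 0:1, item = "z", value = c(2, 2)),
                  scale_spec = data.frame(item = "z", scale_min = 2,
                                          scale_max = 2))
  expect_error(rescale_items(dz), class = "ema_degenerate_scale")
})

test_that("baseline split slices exactly and handles boundaries", {
  d <- generate_study_like_dataset(n_items = 2, n_timepoints = 20, seed = 3,
                                   baseline_end = 10, missing_rate = 0)
  parts <- split_baseline(d)
  expect_equal(n_timepoints(parts$baseline), 10)
  expect_identical(parts$full, d)
  for (it in ema_items(d)) {
    expect_equal(series_values(parts$baseline, it),
                 series_values(d, it)[1:10])
  }

  d_all <- as_ema_df(tibble::as_tibble(d), scale_spec = scale_spec(d),
                     baseline_end = 20)
  expect_equal(n_timepoints(split_baseline(d_all)$baseline), 20)

  d_bad <- as_ema_df(tibble::as_tibble(d), scale_spec = scale_spec(d),
                     baseline_end = 1)
  expect_error(split_baseline(d_bad), class = "ema_window_error")
  expect_error(as_ema_df(tibble::as_tibble(d), baseline_end = 25),
               class = "ema_window_error")
})

test_that("zero-variance items are excluded and reported", {
  base <- data.frame(time = rep(0:9, 3),
                     item = rep(c("a", "const", "b"), each = 10),
                     value = c(rnorm(10), rep(1, 10), rnorm(10)))
  d <- as_ema_df(base)
  kept <- drop_zero_variance(d)
  expect_equal(ema_items(kept), c("a", "b"))
  expect_equal(excluded_items(kept), "const")

  d_ok <- as_ema_df(base[base$item != "const", ])
  kept2 <- drop_zero_variance(d_ok)
  expect_equal(ema_items(kept2), c("a", "b"))
  expect_length(excluded_items(kept2), 0)

  d_const <- as_ema_df(data.frame(time = 0:9, item = "c", value = rep(2, 10)))
  expect_error(drop_zero_variance(d_const), class = "ema_empty_dataset")
})

test_that("study-shaped generation yields the study dimensions", {
  d <- generate_study_like_dataset(n_items = 29, n_timepoints = 1476, seed = 5)
  expect_length(ema_items(d), 29)
  expect_equal(n_timepoints(d), 1476)
  expect_equal(baseline_end(d), 292)
  expect_equal(nrow(d), 29 * 1476)
})
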