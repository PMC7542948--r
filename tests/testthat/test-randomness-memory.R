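test_that("Bartels statistic is exact on a monotone series", {
  d <- ema_from_vector(as.numeric(1:100))
  res <- bartels_test(d)
  expect_equal(res$rvn, 12 * 99 / (100 * (100^2 - 1)))
  expect_lt(res$p_value, 0.001)
  expect_lt(res$statistic, 0) # positive dependence: RVN below its mean of 2
})

test_that("Bartels normal approximation agrees with a permutation oracle", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3) # fixed 10-value series with a tie
  p_norm <- bartels_test(ema_from_vector(x))$p_value
  p_perm <- oracle_bartels_perm_p(x, n_perm = 1e5)
  expect_lt(abs(p_norm - p_perm), 0.03)
})

test_that("Bartels rejects degenerate input", {
  expect_error(bartels_test(ema_from_vector(rep(1, 50))),
               class = "ema_zero_variance")
  expect_error(bartels_test(ema_from_vector(c(1, 2, 3, 4, 5))),
               class = "ema_too_short")
})

test_that("Bartels keeps near-nominal type-I error on Likert-discretized noise", {
  # heavy ties from a 7-level scale must not inflate rejections beyond 1.5x
  p <- vapply(1:1000, function(s) {
    x <- withr::with_seed(2000 + s,
                          pmin(pmax(floor(4 + 1.2 * rnorm(292) + 0.5), 1), 7))
    bartels_test(ema_from_vector(x))$p_value
  }, numeric(1))
  expect_lte(mean(p < 0.05), 1.5 * 0.05)
})

test_that("ACF is exact for a perfectly alternating series", {
  x <- rep(c(1, -1), 50)
  prof <- acf_profile(ema_from_vector(x), max_lag = 2)
  expect_equal(prof$acf[1], -1, tolerance = 0.02)
  expect_equal(prof$acf[2], 1, tolerance = 0.03)
})

test_that("PACF matches an independent Durbin-Levinson recursion", {
  x <- generate_series("ar1", 500, phi = 0.6, seed = 5)$value
  prof <- acf_profile(ema_from_vector(x), max_lag = 10)
  rho <- acf(x, lag.max = 10, plot = FALSE)$acf[-1]
  expect_equal(prof$pacf, oracle_pacf_from_acf(rho, 10), tolerance = 1e-8)
})

test_that("PACF of simulated AR(1) concentrates at lag 1", {
  x <- generate_series("ar1", 2000, phi = 0.6, seed = 77)$value
  prof <- acf_profile(ema_from_vector(x), max_lag = 20)
  expect_lt(abs(prof$pacf[1] - 0.6), 0.05)
  expect_gte(sum(!prof$pacf_significant[2:20]), 17)
})

test_that("PACF flags exactly the true lags of AR(p) in most replicates", {
  # scanning the first 4 lags: each extra lag carries its own 5% false-alarm
  # rate, so "exactly the true lags" can only be demanded over a short scan
  for (p_order in 1:2) {
    hits <- vapply(1:40, function(s) {
      x <- withr::with_seed(3000 + 100 * p_order + s, {
        as.numeric(arima.sim(list(ar = rep(0.4 / p_order, p_order) +
                                    c(0.25, rep(0, p_order - 1))), 2000))
      })
      prof <- acf_profile(ema_from_vector(x), max_lag = 4)
      all(prof$pacf_significant[seq_len(p_order)]) &&
        sum(prof$pacf_significant) == p_order
    }, logical(1))
    expect_gte(mean(hits), 0.8)
  }
})

test_that("significant-lag summary counts what it claims to count", {
  x <- generate_series("ar1", 800, phi = 0.5, seed = 6)$value
  prof <- acf_profile(ema_from_vector(x), max_lag = 50)
  s <- summarise_acf_profile(prof)
  expect_equal(s$n_sig_pacf, sum(abs(prof$pacf) > prof$sig_threshold[1]))
  expect_equal(s$max_sig_pacf_lag,
               max(prof$lag[abs(prof$pacf) > prof$sig_threshold[1]]))
  expect_equal(s$sig_threshold, qnorm(0.975) / sqrt(800))
})

test_that("moving-window counts follow floor((N - w)/step) + 1", {
  x <- generate_series("ar1", 1476, phi = 0.5, seed = 4)$value
  d <- ema_from_vector(x)
  w1 <- moving_window_acf(d, 492, step = 1, max_lag = 5)
  expect_equal(max(w1$window), 985)
  w2 <- moving_window_acf(d, 492, step = 492, max_lag = 5)
  expect_equal(max(w2$window), 3)
})

test_that("stationary series give stable windowed ACFs; constants are flagged", {
  x <- generate_series("ar1", 1476, phi = 0.5, seed = 14)$value
  d <- ema_from_vector(x)
  w <- moving_window_acf(d, 492, step = 20, max_lag = 3)
  s <- summarise_window_acf(w)
  expect_lt(s$q75[s$lag == 1] - s$q25[s$lag == 1], 0.15)

  xc <- c(rep(1, 30), rnorm(70))
  wc <- moving_window_acf(ema_from_vector(xc), 20, step = 10, max_lag = 3)
  expect_true(any(wc$degenerate))
  expect_true(all(is.na(wc$acf[wc$degenerate])))
  expect_false(all(wc$degenerate))
})

test_that("TV-AR keeps EDF near 2 for a constant coefficient", {
  d <- generate_series("ar1", 1476, phi = 0.5, seed = 7)
  f <- tvar_fit(d)
  expect_lte(f$edf, 2.3)
  expect_equal(mean(tidy(f$fit[[1]])$phi), 0.5, tolerance = 0.1)
})

test_that("TV-AR detects and tracks a time-varying coefficient", {
  n <- 1476
  t <- seq_len(n)
  phi_t <- 0.1 + 0.7 * (t - 1) / (n - 1) + 0.15 * sin(4 * pi * (t - 1) / n)
  y <- withr::with_seed(42, {
    y <- numeric(n)
    for (i in 2:n) y[i] <- phi_t[i] * y[i - 1] + rnorm(1)
    y
  })
  f <- tvar_fit(ema_from_vector(y))
  expect_gt(f$edf, 2)
  cc <- tidy(f$fit[[1]])
  expect_lt(mean(abs(cc$phi - phi_t[cc$t + 1])), 0.15)
  g <- glance(f$fit[[1]])
  expect_equal(g$edf, f$edf)
})

test_that("TV-AR rejects unusable designs", {
  expect_error(tvar_fit(ema_from_vector(rnorm(50))), class = "ema_too_short")
  expect_error(tvar_fit(ema_from_vector(rep(1, 300))),
               class = "ema_fit_error")
})

test_that("missing values are dropped pairwise/listwise, not fatal", {
  x <- generate_series("ar1", 1200, phi = 0.5, seed = 9)$value
  x[c(5, 100, 600)] <- NA
  d <- ema_from_vector(x)
  expect_equal(bartels_test(d)$n_used, 1197)
  f <- tvar_fit(d)
  expect_equal(f$n_pairs, 1199 - 6) # each NA kills two pairs
  prof <- acf_profile(d, max_lag = 5)
  expect_false(anyNA(prof$acf))
})
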