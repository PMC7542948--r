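test_that("delay embedding enumerates lagged coordinates correctly", {
  d <- ema_from_vector(as.numeric(1:10))
  emb <- delay_embed(d, E = 3, tau = 2)
  expect_equal(nrow(emb), 6) # 10 - (3-1)*2
  expect_equal(emb$t[1], 4)
  expect_equal(unlist(emb[1, c("y_lag0", "y_lag2", "y_lag4")],
                      use.names = FALSE), c(5, 3, 1))

  e1 <- delay_embed(d, E = 1, tau = 3)
  expect_equal(e1$y_lag0, as.numeric(1:10))

  long <- ema_from_vector(rnorm(1476))
  expect_equal(nrow(delay_embed(long, E = 13, tau = 4)), 1428)

  expect_error(delay_embed(ema_from_vector(rnorm(5)), E = 4, tau = 2),
               class = "ema_embedding_error")
})

test_that("embedding flags vectors that touch missing cells", {
  x <- as.numeric(1:20)
  x[7] <- NA
  emb <- delay_embed(ema_from_vector(x), E = 2, tau = 3)
  # y_t or y_{t-3} equal to the missing index 6 (0-based)
  expect_equal(emb$t[!emb$complete], c(6, 9))
})

test_that("a sine wave is fully predictable at every horizon", {
  d <- generate_series("sine", 1476, period = 40)
  sk <- simplex_forecast(d, E = 2, tau = 10, library_length = 700,
                         horizons = 1:10)
  expect_true(all(sk$skill >= 0.99))
})

test_that("the logistic map is predictable short-term and decays with horizon", {
  # weak chaos (r = 3.9): decay is visible but slow, since a 652-vector
  # library resolves the attractor finely
  d <- generate_series("logistic_map", 1476, r = 3.9, x0 = 0.21)
  sk <- simplex_forecast(d, E = 2, tau = 1, library_length = 700,
                         horizons = 1:10)
  expect_gt(sk$skill[sk$horizon == 1], 0.95)
  expect_lt(sk$skill[sk$horizon == 10], sk$skill[sk$horizon == 1] - 0.2)
  expect_true(all(diff(sk$skill[sk$horizon >= 4]) < 0))

  # full chaos (r = 4): strong decay already by horizon 8
  d4 <- generate_series("logistic_map", 1476, r = 4, x0 = 0.2)
  sk4 <- simplex_forecast(d4, E = 2, tau = 1, library_length = 700,
                          horizons = 1:8)
  expect_gt(sk4$skill[sk4$horizon == 1], 0.95)
  expect_lt(sk4$skill[sk4$horizon == 8], sk4$skill[sk4$horizon == 1] - 0.3)
})

test_that("simplex forecasts equal the brute-force oracle", {
  for (case in list(
    list(y = generate_series("logistic_map", 300, r = 3.9, x0 = 0.3)$value,
         E = 2, tau = 1, lib = 150),
    list(y = generate_series("ar1", 250, phi = 0.6, seed = 91)$value,
         E = 3, tau = 2, lib = 120))) {
    for (tp in c(1, 3)) {
      want <- oracle_simplex(case$y, case$E, case$tau, case$lib, tp)
      got <- emacomplexity:::simplex_core(case$y, case$E, case$tau, case$lib,
                                          tp, details = TRUE)
      fc <- got$forecasts[[as.character(tp)]]
      expect_equal(fc$t, want$pred_t)
      expect_lt(max(abs(fc$forecast - want$forecast)), 1e-10)
      expect_equal(got$curve$skill, cor(want$forecast, want$obs),
                   tolerance = 1e-10)
    }
  }
})

test_that("forecast skill is invariant under affine rescaling", {
  y <- generate_series("ar1", 900, phi = 0.6, seed = 92)$value
  s1 <- simplex_forecast(ema_from_vector(y), E = 3, tau = 1,
                         library_length = 450, horizons = 1:5)
  s2 <- simplex_forecast(ema_from_vector(2.5 * y - 7), E = 3, tau = 1,
                         library_length = 450, horizons = 1:5)
  expect_equal(s1$skill, s2$skill, tolerance = 1e-10)
})

test_that("missing observations are imputed inside the analysis", {
  y <- generate_series("sine", 1000, period = 40)$value
  y[c(100, 450, 820)] <- NA
  sk <- simplex_forecast(ema_from_vector(y), E = 2, tau = 10,
                         library_length = 500, horizons = 1:3)
  expect_true(all(sk$skill > 0.98))
  expect_true(all(sk$n_predictions > 400))
})

test_that("decay slope reduces to exact OLS on clean curves", {
  flat <- tibble::tibble(item = "f", horizon = 1:5, skill = rep(0.7, 5),
                         n_predictions = 100L)
  expect_equal(decay_slope(flat)$decay_slope, 0)

  lin <- tibble::tibble(item = "l", horizon = 1:5,
                        skill = c(0.8, 0.7, 0.6, 0.5, 0.4),
                        n_predictions = 100L)
  expect_equal(decay_slope(lin)$decay_slope, -0.1)

  short <- tibble::tibble(item = "s", horizon = 1:5,
                          skill = c(0.5, rep(NA_real_, 4)),
                          n_predictions = 100L)
  expect_warning(out <- decay_slope(short))
  expect_true(is.na(out$decay_slope))
})

test_that("system classes order as sine ~ flat < noise wobble < chaotic decay", {
  # a coarse 100-vector library so chaotic divergence is visible within 5
  # steps; x0 chosen off the map's exact periodic orbits
  slopes <- purrr::map_dfr(1:10, function(s) {
    noise <- generate_series("white", 400, dist = "uniform",
                             seed = 400 + s)
    chaos <- generate_series("logistic_map", 400, r = 4,
                             x0 = 0.1234 + 0.0617 * s)
    sine <- generate_series("sine", 400, period = 40)
    cfg <- list(E = 2, tau = 1, lib = 100)
    sk <- function(d) simplex_forecast(d, E = cfg$E, tau = cfg$tau,
                                       library_length = cfg$lib,
                                       horizons = 1:5)
    sk_sine <- sk(sine)
    sk_noise <- sk(noise)
    sk_chaos <- sk(chaos)
    tibble::tibble(
      seed = s,
      sine = decay_slope(sk_sine)$decay_slope,
      noise = decay_slope(sk_noise)$decay_slope,
      chaos = decay_slope(sk_chaos)$decay_slope,
      sine_end = dplyr::last(sk_sine$skill),
      noise_end = dplyr::last(sk_noise$skill),
      chaos_end = dplyr::last(sk_chaos$skill))
  })
  expect_lt(abs(mean(slopes$sine)), 0.005)
  expect_lt(mean(abs(slopes$noise)), abs(mean(slopes$chaos)))
  expect_lt(mean(slopes$chaos), -0.02)
  expect_lt(abs(mean(slopes$noise)), 0.02)
  # terminal skill: deterministic > chaotic > random
  expect_gt(mean(slopes$sine_end), mean(slopes$chaos_end))
  expect_gt(mean(slopes$chaos_end), mean(slopes$noise_end))
})
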