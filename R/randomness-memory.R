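#' Bartels rank test of randomness
#'
#' The rank analog of the von Neumann ratio test. For each item, the
#' non-missing values are midranked in time order (ties get average ranks) and
#' the ratio
#' \deqn{RVN = \sum_{t<n} (R_t - R_{t+1})^2 / \sum_t (R_t - \bar R)^2}
#' is compared with its null expectation 2 using the exact null variance
#' \deqn{Var_0 = 4(n-2)(5n^2-2n-9) / (5n(n+1)(n-1)^2),}
#' giving a two-sided normal z test. Non-randomness in either direction
#' (positive dependence: RVN < 2; alternation: RVN > 2) counts against the
#' null of exchangeability, i.e. of a memoryless series.
#'
#' @param data An `ema_df`.
#' @param items Items to test (default all).
#' @return Tibble with one row per item: `item`, `n_used`, `rvn`, `statistic`
#'   (the z value), `p_value`.
#' @examples
#' d <- generate_series("white", 200, seed = 1)
#' bartels_test(d)
#' @export
bartels_test <- function(data, items = NULL) {
  items <- resolve_items(data, items)
  purrr::map_dfr(items, function(it) {
    x <- series_values(data, it)
    x <- x[!is.na(x)]
    res <- bartels_core(x)
    tibble::tibble(item = it, n_used = res$n, rvn = res$rvn,
                   statistic = res$z, p_value = res$p)
  })
}

bartels_core <- function(x) {
  n <- length(x)
  if (n < 10) {
    abort("Bartels rank test needs at least 10 non-missing values.",
          class = "ema_too_short")
  }
  r <- rank(x, ties.method = "average")
  denom <- sum((r - mean(r))^2)
  if (denom == 0) {
    abort("Constant series: rank variance is zero.",
          class = "ema_zero_variance")
  }
  rvn <- sum(diff(r)^2) / denom
  v0 <- 4 * (n - 2) * (5 * n^2 - 2 * n - 9) / (5 * n * (n + 1) * (n - 1)^2)
  z <- (rvn - 2) / sqrt(v0)
  list(n = n, rvn = rvn, z = z, p = 2 * pnorm(-abs(z)))
}

#' Autocorrelation and partial autocorrelation profile
#'
#' Sample ACF (overall-mean centering, lag-0 variance normalization; products
#' involving missing cells are skipped) and PACF (Durbin–Levinson) per item,
#' with the two-tailed z significance threshold
#' `qnorm(1 - alpha/2) / sqrt(n_used)` using the series length as the number
#' of observations at every lag.
#'
#' @param data An `ema_df`.
#' @param max_lag Largest lag to profile; default `floor(10 * log10(n))`. To
#'   count significant partial autocorrelations at high lags (the battery scans
#'   up to `n/3`), raise this.
#' @param alpha Two-sided significance level for the threshold (default .05).
#' @param items Items to profile (default all).
#' @return A tibble of class `ema_acf_profile`: `item`, `lag`, `acf`, `pacf`,
#'   `sig_threshold`, `pacf_significant`. Summarize with
#'   [summarise_acf_profile()].
#' @export
acf_profile <- function(data, max_lag = NULL, alpha = 0.05, items = NULL) {
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).", class = "ema_parameter_error")
  }
  items <- resolve_items(data, items)
  out <- purrr::map_dfr(items, function(it) {
    x <- series_values(data, it)
    n_used <- sum(!is.na(x))
    if (length(unique(x[!is.na(x)])) < 2) {
      abort(paste0("Item '", it, "' is constant; ACF undefined."),
            class = "ema_zero_variance")
    }
    ml <- max_lag %||% floor(10 * log10(n_used))
    if (ml >= n_used) {
      abort("`max_lag` must be smaller than the number of usable values.",
            class = "ema_parameter_error")
    }
    ac <- as.numeric(stats::acf(x, lag.max = ml, plot = FALSE,
                                demean = TRUE, na.action = na.pass)$acf)[-1]
    pc <- as.numeric(stats::pacf(x, lag.max = ml, plot = FALSE,
                                 na.action = na.pass)$acf)
    thr <- qnorm(1 - alpha / 2) / sqrt(n_used)
    tibble::tibble(item = it, lag = seq_len(ml), acf = ac, pacf = pc,
                   sig_threshold = thr,
                   pacf_significant = abs(pc) > thr)
  })
  structure(out, alpha = alpha,
            class = c("ema_acf_profile", class(out)))
}

#' Summarize significant partial autocorrelations
#'
#' @param profile An [acf_profile()] result.
#' @return Tibble with `item`, `n_sig_pacf` (count of lags whose |PACF|
#'   exceeds the threshold), `max_sig_pacf_lag` (largest such lag, `NA` if
#'   none) and `sig_threshold`.
#' @export
summarise_acf_profile <- function(profile) {
  profile |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(
      n_sig_pacf = sum(.data$pacf_significant, na.rm = TRUE),
      max_sig_pacf_lag = if (any(.data$pacf_significant, na.rm = TRUE)) {
        max(.data$lag[.data$pacf_significant])
      } else NA_integer_,
      sig_threshold = .data$sig_threshold[1],
      .groups = "drop")
}

#' Moving-window autocorrelation functions
#'
#' Computes the ACF in (possibly overlapping) windows to expose
#' non-stationarity of the correlation structure at all lags. The number of
#' windows is `floor((n - window_length) / step) + 1`. Windows whose
#' non-missing values are constant are flagged degenerate (ACF `NA`), not
#' fatal.
#'
#' @param data An `ema_df`.
#' @param window_length Window size in assessments (e.g. 492, a third of a
#'   1476-point record).
#' @param step Offset between consecutive window starts (1 = maximally
#'   overlapping).
#' @param max_lag Largest lag per window (default `floor(10 * log10(w))`,
#'   must be `< window_length`).
#' @param items Items to analyze (default all).
#' @return A tibble of class `ema_window_acf`: `item`, `window` (1-based),
#'   `start` (0-based window start), `lag`, `acf`, `degenerate`. Summarize
#'   with [summarise_window_acf()].
#' @export
moving_window_acf <- function(data, window_length, step = 1, max_lag = NULL,
                              items = NULL) {
  items <- resolve_items(data, items)
  n <- n_timepoints(data)
  window_length <- as.integer(window_length)
  step <- as.integer(step)
  if (window_length > n) {
    abort("`window_length` must not exceed the series length.",
          class = "ema_parameter_error")
  }
  ml <- max_lag %||% floor(10 * log10(window_length))
  if (ml >= window_length) {
    abort("`max_lag` must be smaller than `window_length`.",
          class = "ema_parameter_error")
  }
  starts <- seq(0L, n - window_length, by = step)
  out <- purrr::map_dfr(items, function(it) {
    x <- series_values(data, it)
    purrr::map_dfr(seq_along(starts), function(w) {
      xs <- x[(starts[w] + 1):(starts[w] + window_length)]
      ok <- length(unique(xs[!is.na(xs)])) >= 2
      a <- if (ok) {
        as.numeric(stats::acf(xs, lag.max = ml, plot = FALSE, demean = TRUE,
                              na.action = na.pass)$acf)[-1]
      } else rep(NA_real_, ml)
      tibble::tibble(item = it, window = w, start = starts[w],
                     lag = seq_len(ml), acf = a, degenerate = !ok)
    })
  })
  structure(out, window_length = window_length, step = step,
            class = c("ema_window_acf", class(out)))
}

#' Per-lag quantile summary of windowed ACFs
#'
#' @param x A [moving_window_acf()] result.
#' @return Tibble with `item`, `lag`, `median`, `q25`, `q75` across windows.
#' @export
summarise_window_acf <- function(x) {
  x |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$item, .data$lag) |>
    dplyr::summarise(median = median(.data$acf, na.rm = TRUE),
                     q25 = quantile(.data$acf, 0.25, na.rm = TRUE),
                     q75 = quantile(.data$acf, 0.75, na.rm = TRUE),
                     .groups = "drop")
}

#' Time-varying lag-1 autoregression
#'
#' Fits \eqn{y_t = \beta_0(t) + \phi_1(t) y_{t-1} + \epsilon_t} with both
#' curves expanded in cubic penalized B-splines (second-difference penalty,
#' basis dimension `k` each) via [mgcv::gam()], smoothing selected by
#' generalized cross-validation. The effective degrees of freedom (EDF) of the
#' varying-coefficient term measures the wiggliness of \eqn{\phi_1(t)}: the
#' term's penalty null space holds constant and linear coefficient paths, so
#' EDF near 2 means at most a linear trend while EDF above 2 signals a
#' definitely time-varying autocorrelation. `smooth_p` is mgcv's approximate
#' test that the smooth coefficient function differs from zero.
#'
#' Pairs with a missing `y_t` or `y_{t-1}` are dropped from the design.
#'
#' @param data An `ema_df` with at least 100 usable consecutive pairs per item.
#' @param items Items to fit (default all).
#' @param k Basis dimension per curve (default 10).
#' @return Tibble with `item`, `n_pairs`, `edf`, `smooth_p`, `gcv` and a
#'   list-column `fit` of `ema_tvar` objects supporting [tidy()] (coefficient
#'   curves), [glance()] and [autoplot()].
#' @examples
#' d <- generate_series("ar1", 400, phi = 0.5, seed = 1)
#' tvar_fit(d)[, c("item", "edf", "smooth_p")]
#' @export
tvar_fit <- function(data, items = NULL, k = 10) {
  items <- resolve_items(data, items)
  purrr::map_dfr(items, function(it) {
    fit <- tvar_fit_one(series_values(data, it), item = it, k = k)
    tibble::tibble(item = it, n_pairs = fit$n_pairs, edf = fit$edf,
                   smooth_p = fit$smooth_p, gcv = fit$gcv, fit = list(fit))
  })
}

tvar_fit_one <- function(y, item = "series", k = 10) {
  n <- length(y)
  df <- data.frame(y = y[-1], yl = y[-n], tt = seq_len(n - 1))
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 100) {
    abort("TV-AR needs at least 100 usable (y_{t-1}, y_t) pairs.",
          class = "ema_too_short")
  }
  if (var(df$yl) < .Machine$double.eps) {
    abort("Near-constant predictor: TV-AR design is rank deficient.",
          class = "ema_fit_error")
  }
  m <- tryCatch(
    mgcv::gam(y ~ s(tt, bs = "ps", k = k, m = c(2, 2)) +
                s(tt, by = yl, bs = "ps", k = k, m = c(2, 2)),
              data = df, method = "GCV.Cp"),
    error = function(e) abort(paste0("TV-AR fit failed: ", conditionMessage(e)),
                              class = "ema_fit_error"))
  sm <- summary(m)
  i_by <- grep(":yl", rownames(sm$s.table), fixed = TRUE)
  nd <- data.frame(tt = df$tt, yl = 1)
  terms <- predict(m, newdata = nd, type = "terms")
  by_col <- grepl(":yl", colnames(terms), fixed = TRUE)
  coef_curve <- as.numeric(terms[, by_col])
  intercept_curve <- as.numeric(attr(terms, "constant")) +
    as.numeric(terms[, which(!by_col)[1]])
  structure(list(item = item, model = m, lag = 1L,
                 n_pairs = nrow(df),
                 edf = unname(sm$s.table[i_by, "edf"]),
                 smooth_p = unname(sm$s.table[i_by, "p-value"]),
                 gcv = unname(m$gcv.ubre),
                 t = df$tt,
                 coef_curve = coef_curve,
                 intercept_curve = intercept_curve),
            class = "ema_tvar")
}

#' @export
print.ema_tvar <- function(x, ...) {
  cat(sprintf("TV-AR(1) fit for '%s': %d pairs, EDF %.2f, p %.3g\n",
              x$item, x$n_pairs, x$edf, x$smooth_p))
  invisible(x)
}

#' @rdname tvar_fit
#' @param x An `ema_tvar` object.
#' @param ... Unused.
#' @export
tidy.ema_tvar <- function(x, ...) {
  tibble::tibble(item = x$item, t = x$t,
                 intercept = x$intercept_curve, phi = x$coef_curve)
}

#' @rdname tvar_fit
#' @export
glance.ema_tvar <- function(x, ...) {
  tibble::tibble(item = x$item, n_pairs = x$n_pairs, edf = x$edf,
                 smooth_p = x$smooth_p, gcv = x$gcv)
}
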