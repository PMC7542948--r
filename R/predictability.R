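#' Delay-coordinate embedding
#'
#' Reconstructs a state space from one observable by using time-lagged copies
#' of the series as dimensions: the state vector at assessment `t` is
#' `(y_t, y_{t-tau}, ..., y_{t-(E-1)tau})`. There are `n - (E-1)*tau` such
#' vectors; those containing missing values are flagged incomplete.
#'
#' @param data An `ema_df`.
#' @param E Embedding dimension (>= 1).
#' @param tau Embedding delay (>= 1).
#' @param item Item label; may be omitted for single-item datasets.
#' @return Tibble with `t` (0-based index of the vector's most recent
#'   coordinate), `complete`, and coordinate columns `y_lag0`, `y_lag<tau>`,
#'   ... ordered from the current value back in time.
#' @examples
#' d <- as_ema_df(data.frame(time = 0:9, item = "x", value = 1:10))
#' delay_embed(d, E = 3, tau = 2)[1, ]
#' @export
delay_embed <- function(data, E, tau, item = NULL) {
  E <- as.integer(E)
  tau <- as.integer(tau)
  if (E < 1 || tau < 1) {
    abort("`E` and `tau` must be positive integers.",
          class = "ema_parameter_error")
  }
  y <- series_values(data, item)
  n <- length(y)
  offset <- (E - 1L) * tau
  if (n < offset + 1L) {
    abort("Series too short for the requested embedding.",
          class = "ema_embedding_error")
  }
  t_idx <- seq.int(offset, n - 1L)
  mat <- vapply(seq_len(E) - 1L, function(j) y[t_idx - j * tau + 1L],
                numeric(length(t_idx)))
  mat <- matrix(mat, nrow = length(t_idx), ncol = E)
  colnames(mat) <- paste0("y_lag", (seq_len(E) - 1L) * tau)
  dplyr::bind_cols(tibble::tibble(t = t_idx,
                                  complete = stats::complete.cases(mat)),
                   tibble::as_tibble(mat))
}

#' Simplex-projection forecast skill
#'
#' Nonparametric forecasting in the delay-embedded state space (Sugihara–May).
#' The embedded vectors of the first `library_length` observations form the
#' library; vectors from the remaining observations are the prediction set.
#' For each prediction vector and horizon `tp`, the `E + 1` nearest library
#' neighbors (Euclidean distance; ties broken by earlier library index) are
#' found among library vectors whose `tp`-step future still lies inside the
#' library, weighted by `w_i = exp(-d_i / d_min)` with `d_min` the nearest
#' distance (all weights 1 when `d_min = 0`), and the forecast is the
#' weighted mean of the neighbors' futures. Forecast skill at each horizon is
#' the Pearson correlation between forecasts and observations — invariant
#' under affine rescaling of the ratings.
#'
#' Prediction vectors never enter the library (the hard split makes
#' leave-one-out unnecessary), and no additional temporal exclusion is applied
#' inside the library. Missing observations are imputed within this analysis
#' by the forecaster's own neighbor-weighted one-step estimates
#' (interpolation-initialized), so embedding and scoring use a complete
#' series.
#'
#' @param data An `ema_df`.
#' @param E Embedding dimension (study configuration: 13).
#' @param tau Embedding delay (study configuration: 4).
#' @param library_length Number of leading observations forming the library
#'   (study configuration: 700); must exceed `E * tau`.
#' @param horizons Positive integer prediction horizons (default 1:10).
#' @param items Items to forecast (default all).
#' @return A tibble of class `ema_skill_curve`: `item`, `horizon`, `skill`
#'   (`NA` when predictions or observations are degenerate at that horizon),
#'   `n_predictions`.
#' @examples
#' d <- generate_series("sine", 300, period = 40)
#' simplex_forecast(d, E = 2, tau = 10, library_length = 150, horizons = 1:3)
#' @export
simplex_forecast <- function(data, E = 13, tau = 4, library_length = 700,
                             horizons = 1:10, items = NULL) {
  E <- as.integer(E)
  tau <- as.integer(tau)
  library_length <- as.integer(library_length)
  horizons <- sort(unique(as.integer(horizons)))
  if (length(horizons) == 0 || any(horizons < 1)) {
    abort("`horizons` must be positive integers.",
          class = "ema_parameter_error")
  }
  if (library_length <= E * tau) {
    abort("`library_length` must exceed E * tau.",
          class = "ema_parameter_error")
  }
  items <- resolve_items(data, items)
  out <- purrr::map_dfr(items, function(it) {
    y <- series_values(data, it)
    curve <- simplex_core(y, E, tau, library_length, horizons)
    dplyr::bind_cols(tibble::tibble(item = it), curve)
  })
  structure(out, E = E, tau = tau, library_length = library_length,
            class = c("ema_skill_curve", class(out)))
}

simplex_core <- function(y, E, tau, library_length, horizons,
                         details = FALSE) {
  n <- length(y)
  y <- simplex_impute(y, E, tau, library_length)
  offset <- (E - 1L) * tau
  if (n <= library_length || library_length <= offset + E + 1L) {
    abort("Series too short for the library/prediction split.",
          class = "ema_library_error")
  }
  t_all <- seq.int(offset, n - 1L)
  emb <- vapply(seq_len(E) - 1L, function(j) y[t_all - j * tau + 1L],
                numeric(length(t_all)))
  emb <- matrix(emb, ncol = E)
  lib_rows <- which(t_all <= library_length - 1L)
  pred_rows <- which(t_all >= library_length)
  if (length(lib_rows) < E + 2L) {
    abort("Fewer than E + 2 usable library vectors.",
          class = "ema_library_error")
  }
  lib_t <- t_all[lib_rows]
  pred_t <- t_all[pred_rows]
  d2 <- pair_dist2(emb[pred_rows, , drop = FALSE],
                   emb[lib_rows, , drop = FALSE])
  # per prediction row, library rows by increasing distance (earlier library
  # index wins ties)
  ord <- t(apply(d2, 1, function(d) order(d, seq_along(d))))

  fc_by_horizon <- list()
  out <- purrr::map_dfr(horizons, function(tp) {
    lib_ok_max <- library_length - 1L - tp # largest usable library time
    usable <- which(pred_t + tp <= n - 1L)
    if (length(usable) == 0 || !any(lib_t <= lib_ok_max)) {
      return(tibble::tibble(horizon = tp, skill = NA_real_,
                            n_predictions = 0L))
    }
    fc <- vapply(usable, function(i) {
      o <- ord[i, ]
      o <- o[lib_t[o] <= lib_ok_max]
      nn <- o[seq_len(min(E + 1L, length(o)))]
      d <- sqrt(d2[i, nn])
      w <- if (d[1] > 0) exp(-d / d[1]) else rep(1, length(d))
      sum(w * y[lib_t[nn] + tp + 1L]) / sum(w)
    }, numeric(1))
    obs <- y[pred_t[usable] + tp + 1L]
    if (details) {
      fc_by_horizon[[as.character(tp)]] <<- tibble::tibble(
        t = pred_t[usable], forecast = fc, observed = obs)
    }
    skill <- if (length(fc) > 3 && sd(fc) > 0 && sd(obs) > 0) {
      cor(fc, obs)
    } else NA_real_
    tibble::tibble(horizon = tp, skill = skill,
                   n_predictions = length(fc))
  })
  if (details) list(curve = out, forecasts = fc_by_horizon) else out
}

pair_dist2 <- function(a, b) {
  ra <- rowSums(a^2)
  rb <- rowSums(b^2)
  d2 <- outer(ra, rb, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

# fill missing cells: linear interpolation first, then replace each filled
# cell (where an embedded predecessor exists) with the simplex one-step
# neighbor-weighted estimate from the library
simplex_impute <- function(y, E, tau, library_length) {
  if (!anyNA(y)) return(y)
  n <- length(y)
  obs <- which(!is.na(y))
  yf <- approx(obs, y[obs], xout = seq_len(n), rule = 2)$y
  offset <- (E - 1L) * tau
  miss <- which(is.na(y))
  lib_t <- seq.int(offset, min(library_length - 2L, n - 2L))
  if (length(lib_t) < E + 2L) return(yf)
  lib_mat <- vapply(seq_len(E) - 1L, function(j) yf[lib_t - j * tau + 1L],
                    numeric(length(lib_t)))
  lib_mat <- matrix(lib_mat, ncol = E)
  for (m in miss) {
    tprev <- m - 2L # 0-based index of y_{m-1}
    if (tprev < offset) next
    v <- yf[tprev - (seq_len(E) - 1L) * tau + 1L]
    d <- sqrt(colSums((t(lib_mat) - v)^2))
    o <- order(d, seq_along(d))[seq_len(E + 1L)]
    dd <- d[o]
    w <- if (dd[1] > 0) exp(-dd / dd[1]) else rep(1, length(dd))
    yf[m] <- sum(w * yf[lib_t[o] + 2L]) / sum(w)
  }
  yf
}

#' Prediction-decay slope of a forecast-skill curve
#'
#' The ordinary least-squares slope of forecast skill on horizon over the
#' first few horizons (default 1–5) summarizes how quickly predictability
#' decays: near zero for both simple deterministic signals (always
#' predictable) and pure noise (never predictable), clearly negative for
#' chaotic dynamics with sensitive dependence on initial conditions.
#'
#' @param curve A [simplex_forecast()] result.
#' @param window Horizons entering the fit (default `1:5`).
#' @return Tibble with `item`, `decay_slope` (`NA` with a warning when fewer
#'   than 2 horizons have defined skill) and `n_horizons_used`.
#' @export
decay_slope <- function(curve, window = 1:5) {
  curve |>
    tibble::as_tibble() |>
    dplyr::filter(.data$horizon %in% window) |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(decay_slope = ols_slope(.data$horizon, .data$skill),
                     n_horizons_used = sum(!is.na(.data$skill)),
                     .groups = "drop")
}

ols_slope <- function(x, y) {
  ok <- !is.na(y)
  if (sum(ok) < 2) {
    warn("Fewer than 2 defined skill values; decay slope undefined.")
    return(NA_real_)
  }
  x <- x[ok]
  y <- y[ok]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
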