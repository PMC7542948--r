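#' KPSS test of level stationarity
#'
#' Null hypothesis: the series is stationary around a level; alternative: a
#' unit root. With demeaned residuals \eqn{e_t} and partial sums \eqn{S_t},
#' the statistic is \eqn{\eta = n^{-2} \sum_t S_t^2 / s^2(l)}, where
#' \eqn{s^2(l)} is the Bartlett-kernel long-run variance with weights
#' \eqn{1 - s/(l+1)} and the short truncation lag
#' \eqn{l = \lfloor 3\sqrt{n}/13 \rfloor}. The p-value is interpolated in the
#' level-stationarity critical-value table (0.347, 0.463, 0.574, 0.739 for
#' .10, .05, .025, .01) and is therefore clamped to `[0.01, 0.10]`; `p = .010`
#' is the test's significance bound. Missing values are excluded listwise.
#'
#' @param data An `ema_df` with at least 30 non-missing values per item.
#' @param items Items to test (default all).
#' @return Tibble with `item`, `n_used`, `statistic`, `truncation_lag`,
#'   `p_value` and `reject_level_stationarity` (p at the .010 bound).
#' @examples
#' d <- generate_series("white", 300, seed = 2)
#' kpss_level_test(d)
#' @export
kpss_level_test <- function(data, items = NULL) {
  items <- resolve_items(data, items)
  purrr::map_dfr(items, function(it) {
    x <- series_values(data, it)
    x <- x[!is.na(x)]
    res <- kpss_core(x)
    tibble::tibble(item = it, n_used = length(x), statistic = res$stat,
                   truncation_lag = res$lag, p_value = res$p,
                   reject_level_stationarity = res$p <= 0.010 + 1e-12)
  })
}

kpss_core <- function(x) {
  n <- length(x)
  if (n < 30) {
    abort("KPSS test needs at least 30 non-missing values.",
          class = "ema_too_short")
  }
  e <- x - mean(x)
  if (sum(e^2) == 0) {
    abort("Constant series: KPSS statistic undefined.",
          class = "ema_zero_variance")
  }
  s_t <- cumsum(e)
  l <- floor(3 * sqrt(n) / 13)
  s2 <- sum(e^2) / n
  if (l > 0) {
    for (s in seq_len(l)) {
      s2 <- s2 + 2 * (1 - s / (l + 1)) * sum(e[1:(n - s)] * e[(s + 1):n]) / n
    }
  }
  eta <- sum(s_t^2) / (n^2 * s2)
  crit <- c(0.347, 0.463, 0.574, 0.739)
  pvals <- c(0.10, 0.05, 0.025, 0.01)
  p <- approx(crit, pvals, xout = eta, rule = 2)$y
  list(stat = eta, lag = l, p = p)
}

#' Energy-statistic divisive change-point detection
#'
#' Hierarchical divisive search for multiple distributional change points. At
#' each step, over every current segment and every admissible split point, the
#' scaled sample energy divergence
#' \deqn{\hat Q(X, Y) = \frac{mn}{m+n}\Big(\frac{2}{mn}\sum |x_i - y_j|^\alpha
#'   - \binom{m}{2}^{-1}\sum_{i<k} |x_i - x_k|^\alpha
#'   - \binom{n}{2}^{-1}\sum_{j<l} |y_j - y_l|^\alpha\Big)}
#' is maximized; the best split's significance is assessed by permuting
#' observations within the current segment structure, with the add-one
#' estimator `p = (1 + #{perm >= obs}) / (1 + n_permutations)`, and the search
#' stops at the first split with `p > alpha_stop`. Sensitive to changes in
#' mean, variance, or any other distributional feature.
#'
#' Missing values are dropped and positions closed up before the search;
#' change indices are reported both in the compacted coordinate and mapped
#' back to original assessment indices.
#'
#' @param data An `ema_df`.
#' @param alpha_moment Moment index \eqn{\alpha} in (0, 2) (default 1).
#' @param min_segment Minimum segment length (default 30).
#' @param n_permutations Permutation draws per split (default 199).
#' @param alpha_stop Stopping significance level (default .05).
#' @param seed Optional integer seed for the permutations.
#' @param items Items to analyze (default all).
#' @return A tibble of class `ema_changepoints`: `item`, `n_used`,
#'   `n_changepoints`, and list-columns `change_indices` (0-based compacted
#'   positions of the first element of each new regime, sorted),
#'   `change_indices_original` (mapped back to assessment indices) and
#'   `p_values` (one per accepted split, in acceptance order).
#' @examples
#' d <- generate_series("regime", 240, segment_means = c(0, 4),
#'                      segment_sds = c(1, 1), change_points = 120, seed = 3)
#' e_divisive(d, n_permutations = 99, seed = 1)
#' @export
e_divisive <- function(data, alpha_moment = 1, min_segment = 30,
                       n_permutations = 199, alpha_stop = 0.05, seed = NULL,
                       items = NULL) {
  if (alpha_moment <= 0 || alpha_moment >= 2) {
    abort("`alpha_moment` must lie in (0, 2).", class = "ema_parameter_error")
  }
  if (min_segment < 2) {
    abort("`min_segment` must be at least 2.", class = "ema_parameter_error")
  }
  items <- resolve_items(data, items)
  run_item <- function(it) {
    x_full <- series_values(data, it)
    obs_idx <- which(!is.na(x_full)) - 1L # original 0-based indices
    x <- x_full[!is.na(x_full)]
    if (length(x) < 2 * min_segment) {
      abort(paste0("Item '", it, "': series too short for `min_segment`."),
            class = "ema_parameter_error")
    }
    res <- e_divisive_core(x, alpha_moment, min_segment, n_permutations,
                           alpha_stop)
    tibble::tibble(item = it, n_used = length(x),
                   n_changepoints = length(res$change_indices),
                   change_indices = list(res$change_indices),
                   change_indices_original =
                     list(obs_idx[res$change_indices + 1L]),
                   p_values = list(res$p_values))
  }
  out <- if (is.null(seed)) {
    purrr::map_dfr(items, run_item)
  } else {
    withr::with_seed(as.integer(seed), purrr::map_dfr(items, run_item))
  }
  structure(out, alpha_moment = alpha_moment, min_segment = min_segment,
            n_permutations = n_permutations, alpha_stop = alpha_stop,
            class = c("ema_changepoints", class(out)))
}

# x: complete numeric vector; returns 0-based compacted change indices in
# sorted order plus per-accepted-split permutation p-values
e_divisive_core <- function(x, alpha_moment, min_segment, n_permutations,
                            alpha_stop) {
  n <- length(x)
  bounds <- c(0L, n) # segment boundaries, 0-based half-open [b_i, b_{i+1})
  cps <- integer(0)
  pvals <- numeric(0)
  repeat {
    best <- best_split_over_segments(x, bounds, min_segment, alpha_moment)
    if (!is.finite(best$stat)) break
    perm <- vapply(seq_len(n_permutations), function(b) {
      xp <- x
      for (i in seq_len(length(bounds) - 1)) {
        seg <- (bounds[i] + 1):bounds[i + 1]
        if (length(seg) > 1) xp[seg] <- sample(xp[seg])
      }
      best_split_over_segments(xp, bounds, min_segment, alpha_moment)$stat
    }, numeric(1))
    p <- (1 + sum(perm >= best$stat)) / (1 + n_permutations)
    if (p > alpha_stop) break
    cps <- c(cps, best$index)
    pvals <- c(pvals, p)
    bounds <- sort(unique(c(bounds, best$index)))
  }
  ord <- order(cps)
  list(change_indices = cps[ord], p_values = pvals, p_order = ord)
}

# best energy split over all current segments; index is the global 0-based
# position of the first element of the proposed new regime
best_split_over_segments <- function(x, bounds, min_segment, alpha_moment) {
  best_stat <- -Inf
  best_index <- NA_integer_
  for (i in seq_len(length(bounds) - 1)) {
    lo <- bounds[i]
    hi <- bounds[i + 1]
    if (hi - lo < 2 * min_segment) next
    res <- energy_best_split(x[(lo + 1):hi], min_segment, alpha_moment)
    if (res$stat > best_stat) {
      best_stat <- res$stat
      best_index <- lo + res$k
    }
  }
  list(stat = best_stat, index = best_index)
}
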