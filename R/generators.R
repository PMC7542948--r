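#' Generate a single synthetic EMA-like series
#'
#' Ground-truth processes for exercising the complexity battery, spanning the
#' contrast the markers must resolve: memoryless noise, short-range memory
#' (AR(1)), long-range memory (fractional Gaussian noise), planted regime
#' shifts with optional pre-transition flickering, and fully deterministic
#' references (sine wave, logistic map).
#'
#' Kind-specific parameters (passed via `...`):
#' * `white`: `dist` (`"gaussian"` or `"uniform"`), `mean`, `sd`;
#' * `ar1`: `phi` (|phi| < 1), `sd` (innovation SD);
#' * `long_memory`: `hurst` in (0, 1), `sd` (marginal SD), simulated by exact
#'   circulant embedding of the fGn autocovariance;
#' * `regime`: `segment_means`, `segment_sds`, `change_points` (0-based indices
#'   of the first element of each new regime), `flicker_window` (length of the
#'   pre-shift window that alternates between the adjacent regimes),
#'   `flicker_dwell` (mean geometric dwell time within the window);
#' * `sine`: `period`, `amplitude`, `phase`, `noise_sd`;
#' * `logistic_map`: `r` in (0, 4], `x0` in (0, 1).
#'
#' If `likert_levels` is set, values are affinely mapped from their observed
#' range to `[1, likert_levels]`, rounded half-up and clamped — a discrete
#' bounded rating scale, order-preserving in the latent values.
#'
#' @param kind One of `"white"`, `"ar1"`, `"long_memory"`, `"regime"`,
#'   `"sine"`, `"logistic_map"`.
#' @param n Series length (at least 2).
#' @param ... Kind-specific parameters, see Details.
#' @param item Item label for the resulting series.
#' @param likert_levels Optional integer number of rating levels.
#' @param missing_rate Bernoulli missingness rate in `[0, 1)`.
#' @param seed Optional integer seed; the result is deterministic given it.
#' @return A single-item [as_ema_df()] tibble with ground-truth metadata.
#' @examples
#' generate_series("logistic_map", 4, r = 4, x0 = 0.2)$value
#' @export
generate_series <- function(kind, n, ..., item = kind, likert_levels = NULL,
                            missing_rate = 0, seed = NULL) {
  kind <- match.arg(kind, c("white", "ar1", "long_memory", "regime", "sine",
                            "logistic_map"))
  n <- as.integer(n)
  if (n < 2) abort("`n` must be at least 2.", class = "ema_parameter_error")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).", class = "ema_parameter_error")
  }
  params <- list(...)
  run <- function() {
    v <- switch(kind,
      white = gen_white(n, params),
      ar1 = gen_ar1(n, params),
      long_memory = gen_fgn(n, params),
      regime = gen_regime(n, params),
      sine = gen_sine(n, params),
      logistic_map = gen_logistic(n, params))
    if (!is.null(likert_levels)) v <- likert_discretize(v, likert_levels)
    v
  }
  v <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  bounds <- if (is.null(likert_levels)) range(v) else c(1, likert_levels)
  gt <- tibble::tibble(item = item, kind = kind,
                       params = list(params),
                       likert_levels = likert_levels %||% NA_integer_,
                       missing_rate = missing_rate,
                       seed = seed %||% NA_integer_)
  d <- as_ema_df(
    tibble::tibble(time = seq_len(n) - 1L, item = item, value = v,
                   missing = FALSE),
    scale_spec = tibble::tibble(item = item, scale_min = bounds[1],
                                scale_max = bounds[2]),
    ground_truth = gt)
  if (missing_rate > 0) {
    ms <- if (is.null(seed)) NULL else as.integer(seed) + 1L
    d <- inject_missing(d, missing_rate, seed = ms)
  }
  d
}

need_param <- function(params, name) {
  if (is.null(params[[name]])) {
    abort(paste0("Missing generator parameter `", name, "`."),
          class = "ema_parameter_error")
  }
  params[[name]]
}

gen_white <- function(n, p) {
  dist <- p$dist %||% "gaussian"
  m <- p$mean %||% 0
  s <- p$sd %||% 1
  switch(match.arg(dist, c("gaussian", "uniform")),
         gaussian = rnorm(n, m, s),
         uniform = runif(n, m - s * sqrt(3), m + s * sqrt(3)))
}

gen_ar1 <- function(n, p) {
  phi <- need_param(p, "phi")
  if (abs(phi) >= 1) {
    abort("AR(1) requires |phi| < 1.", class = "ema_parameter_error")
  }
  s <- p$sd %||% 1
  as.numeric(arima.sim(list(ar = phi), n, sd = s))
}

# Exact fractional Gaussian noise via circulant embedding of the fGn
# autocovariance gamma(k) = 0.5 * (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}).
gen_fgn <- function(n, p) {
  h <- need_param(p, "hurst")
  if (h <= 0 || h >= 1) {
    abort("`hurst` must lie in (0, 1).", class = "ema_parameter_error")
  }
  s <- p$sd %||% 1
  s * fgn_sim(n, h)
}

fgn_sim <- function(n, h) {
  k <- 0:n
  r <- 0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) + abs(k - 1)^(2 * h))
  cvec <- c(r, rev(r[2:n]))
  ev <- Re(fft(cvec))
  if (min(ev) < -1e-8) {
    abort("Circulant embedding produced negative eigenvalues.",
          class = "ema_parameter_error")
  }
  ev <- pmax(ev, 0)
  m <- length(cvec)
  w <- complex(real = rnorm(m), imaginary = rnorm(m))
  Re(fft(sqrt(ev) * w))[seq_len(n)] / sqrt(m)
}

#' Theoretical fGn autocorrelation
#'
#' Lag-k autocorrelation of fractional Gaussian noise with Hurst exponent
#' `hurst`: `0.5 * (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H))`.
#'
#' @param lags Non-negative integer lags.
#' @param hurst Hurst exponent in (0, 1).
#' @return Numeric vector of autocorrelations.
#' @export
fgn_acf_theoretical <- function(lags, hurst) {
  0.5 * (abs(lags + 1)^(2 * hurst) - 2 * abs(lags)^(2 * hurst) +
           abs(lags - 1)^(2 * hurst))
}

gen_regime <- function(n, p) {
  means <- need_param(p, "segment_means")
  sds <- p$segment_sds %||% rep(1, length(means))
  cps <- as.integer(need_param(p, "change_points"))
  if (length(sds) == 1) sds <- rep(sds, length(means))
  if (length(means) != length(cps) + 1 || length(sds) != length(means)) {
    abort("regime needs length(segment_means) == length(change_points) + 1.",
          class = "ema_parameter_error")
  }
  if (is.unsorted(cps, strictly = TRUE) || any(cps <= 0) || any(cps >= n)) {
    abort("`change_points` must be strictly increasing inside (0, n).",
          class = "ema_parameter_error")
  }
  fw <- p$flicker_window %||% 0
  dwell <- p$flicker_dwell %||% 5
  reg <- findInterval(seq_len(n) - 1L, cps) + 1L
  if (fw > 0) {
    for (i in seq_along(cps)) {
      lo <- max(cps[i] - fw, if (i > 1) cps[i - 1] else 0L)
      pos <- lo
      cur <- i # alternate between pre- (i) and post-shift (i + 1) regimes
      while (pos < cps[i]) {
        d <- rgeom(1, 1 / dwell) + 1L
        reg[(pos + 1):min(pos + d, cps[i])] <- cur
        pos <- pos + d
        cur <- if (cur == i) i + 1L else i
      }
    }
  }
  means[reg] + sds[reg] * rnorm(n)
}

gen_sine <- function(n, p) {
  period <- need_param(p, "period")
  amp <- p$amplitude %||% 1
  phase <- p$phase %||% 0
  noise <- p$noise_sd %||% 0
  t <- seq_len(n) - 1
  amp * sin(2 * pi * t / period + phase) +
    if (noise > 0) rnorm(n, 0, noise) else 0
}

gen_logistic <- function(n, p) {
  r <- p$r %||% 4
  x0 <- p$x0 %||% 0.2
  if (r <= 0 || r > 4) abort("`r` must lie in (0, 4].",
                             class = "ema_parameter_error")
  if (x0 <= 0 || x0 >= 1) abort("`x0` must lie in (0, 1).",
                                class = "ema_parameter_error")
  x <- numeric(n)
  x[1] <- x0
  for (t in seq_len(n - 1)) x[t + 1] <- r * x[t] * (1 - x[t])
  x
}

# affine map to [1, levels], round half-up, clamp
likert_discretize <- function(v, levels) {
  levels <- as.integer(levels)
  if (levels < 2) abort("`likert_levels` must be at least 2.",
                        class = "ema_parameter_error")
  rng <- range(v)
  if (diff(rng) == 0) return(rep((1 + levels) / 2, length(v)))
  z <- 1 + (v - rng[1]) * (levels - 1) / diff(rng)
  pmin(pmax(floor(z + 0.5), 1), levels)
}

#' Inject Bernoulli missingness
#'
#' Flags each cell missing independently with probability `rate`,
#' reproducibly given `seed`. Values under the mask are retained but flagged,
#' so ground truth is never destroyed; writers emit masked cells as empty.
#'
#' @param data An `ema_df`.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return The dataset with an updated `missing` column.
#' @export
inject_missing <- function(data, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) {
    abort("`rate` must lie in [0, 1).", class = "ema_parameter_error")
  }
  if (rate == 0) return(data)
  draw <- function() rbinom(nrow(data), 1, rate) == 1
  mask <- if (is.null(seed)) draw() else {
    withr::with_seed(as.integer(seed), draw())
  }
  out <- tibble::as_tibble(data)
  out$missing <- out$missing | mask
  new_ema_df(out, items = ema_items(data), scale_spec = scale_spec(data),
             baseline_end = baseline_end(data),
             ground_truth = ground_truth(data))
}

#' Generate a study-shaped synthetic EMA dataset
#'
#' Emulates a single-subject multi-item EMA study: a mixture of
#' "psychological-like" items with short-range (AR(1), phi ~ U(0.35, 0.7)) or
#' long-range (fGn, H ~ U(0.65, 0.85)) memory, a few items with planted
#' regime shifts preceded by flickering (placed after the baseline window),
#' and "physical-sensation-like" white-noise items; all discretized to a
#' 1–7 Likert scale around item-specific means (U(1.5, 4.5)) and SDs
#' (U(0.5, 1.1)), with sparse Bernoulli missingness (default rate
#' 103/(29*1476), about 0.24%) and a baseline window annotation.
#'
#' The full generating configuration is returned as the `ground_truth`
#' attribute (kind, parameters, change locations per item), so every marker
#' can be validated against known structure.
#'
#' @param n_items Number of items (>= 1).
#' @param n_timepoints Number of assessments.
#' @param seed Integer seed; the dataset (and any CSV export of it) is
#'   byte-identical across runs with the same seed.
#' @param baseline_end Exclusive baseline index (default 292).
#' @param missing_rate Cell-wise missingness probability.
#' @param likert_levels Number of rating levels (default 7).
#' @return An [as_ema_df()] tibble with `ground_truth` metadata.
#' @examples
#' d <- generate_study_like_dataset(n_items = 3, n_timepoints = 120, seed = 1,
#'                                  baseline_end = 40)
#' dplyr::count(ground_truth(d), kind)
#' @export
generate_study_like_dataset <- function(n_items = 29, n_timepoints = 1476,
                                        seed = 1, baseline_end = 292,
                                        missing_rate = 103 / (29 * 1476),
                                        likert_levels = 7) {
  n_items <- as.integer(n_items)
  if (n_items < 1) abort("`n_items` must be >= 1.",
                         class = "ema_parameter_error")
  n <- as.integer(n_timepoints)
  baseline_end <- min(as.integer(baseline_end), n)

  n_regime <- if (n_items >= 4) max(1L, round(0.10 * n_items)) else 0L
  n_white <- if (n_items >= 2) max(1L, round(0.28 * n_items)) else 0L
  n_rest <- n_items - n_regime - n_white
  n_ar1 <- ceiling(n_rest / 2)
  n_lm <- n_rest - n_ar1
  kinds <- c(rep("ar1", n_ar1), rep("long_memory", n_lm),
             rep("regime", n_regime), rep("white", n_white))
  labels <- c(sprintf("psych_ar1_%02d", seq_len(n_ar1)),
              if (n_lm > 0) sprintf("psych_lrd_%02d", seq_len(n_lm)),
              if (n_regime > 0) sprintf("psych_regime_%02d", seq_len(n_regime)),
              if (n_white > 0) sprintf("phys_white_%02d", seq_len(n_white)))

  build <- function() {
    rows <- vector("list", n_items)
    gt <- vector("list", n_items)
    for (i in seq_len(n_items)) {
      mu <- runif(1, 1.5, 4.5)
      s <- runif(1, 0.5, 1.1)
      kind <- kinds[i]
      params <- list()
      z <- switch(kind,
        ar1 = {
          phi <- runif(1, 0.35, 0.7)
          params <- list(phi = phi)
          # unit marginal SD so mu/s set the observed scale
          gen_ar1(n, list(phi = phi, sd = sqrt(1 - phi^2)))
        },
        long_memory = {
          h <- runif(1, 0.65, 0.85)
          params <- list(hurst = h)
          fgn_sim(n, h)
        },
        regime = {
          # segment spacing scaled to the record length so short synthetic
          # datasets stay feasible; shifts are placed after the baseline
          # window where the record is long enough to allow it
          gap <- max(15L, min(100L, n %/% 6L))
          n_cp <- max(1L, min(sample(2:3, 1), n %/% (2L * gap) - 1L))
          lo <- max(gap, min(baseline_end + 50L, n - (n_cp + 1L) * gap))
          hi <- n - gap
          cps <- NULL
          for (try in 1:200) {
            cand <- sort(sample(seq(lo, hi), n_cp))
            if (all(diff(c(0L, cand, n)) >= gap)) {
              cps <- cand
              break
            }
          }
          if (is.null(cps)) {
            cps <- round(seq(lo, hi, length.out = n_cp + 2L))[2:(n_cp + 1L)]
          }
          fw <- min(60L, gap %/% 2L)
          delta <- runif(n_cp, 1.2, 2.2) * sample(c(-1, 1), n_cp, TRUE)
          means <- cumsum(c(0, delta))
          params <- list(change_points = cps, segment_means = means,
                         flicker_window = fw, flicker_dwell = 5)
          gen_regime(n, list(segment_means = means,
                             segment_sds = rep(1, n_cp + 1),
                             change_points = cps, flicker_window = fw,
                             flicker_dwell = 5))
        },
        white = gen_white(n, list()))
      v <- pmin(pmax(floor(mu + s * z + 0.5), 1), likert_levels)
      rows[[i]] <- tibble::tibble(time = seq_len(n) - 1L, item = labels[i],
                                  value = as.numeric(v), missing = FALSE)
      gt[[i]] <- tibble::tibble(item = labels[i], kind = kind,
                                class = if (kind == "white") "physical"
                                        else "psychological",
                                target_mean = mu, target_sd = s,
                                params = list(params))
    }
    list(rows = dplyr::bind_rows(rows), gt = dplyr::bind_rows(gt))
  }
  parts <- withr::with_seed(as.integer(seed), build())
  d <- as_ema_df(parts$rows,
                 scale_spec = tibble::tibble(item = labels, scale_min = 1,
                                             scale_max = likert_levels),
                 baseline_end = baseline_end,
                 ground_truth = parts$gt)
  if (missing_rate > 0) {
    d <- inject_missing(d, missing_rate, seed = as.integer(seed) + 104729L)
  }
  d
}
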