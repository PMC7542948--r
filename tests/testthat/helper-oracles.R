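# Independent brute-force oracles, kept deliberately naive: each one
# re-derives the quantity it checks from first principles, without touching
# the implementation path it validates.

# single-item dataset from a plain numeric vector (NA = missing)
ema_from_vector <- function(x, item = "x", baseline_end = NULL) {
  as_ema_df(data.frame(time = seq_along(x) - 1L, item = item, value = x),
            baseline_end = baseline_end)
}

# rank von Neumann ratio computed from scratch
oracle_rvn <- function(x) {
  r <- rank(x)
  sum(diff(r)^2) / sum((r - mean(r))^2)
}

# Monte Carlo permutation p-value for the Bartels test (two-sided, centered
# on the null mean 2)
oracle_bartels_perm_p <- function(x, n_perm = 1e5, seed = 42) {
  withr::with_seed(seed, {
    obs <- abs(oracle_rvn(x) - 2)
    perm <- replicate(n_perm, abs(oracle_rvn(sample(x)) - 2))
    mean(perm >= obs - 1e-12)
  })
}

# Durbin-Levinson recursion: PACF from a sample ACF
oracle_pacf_from_acf <- function(rho, max_lag) {
  phi <- matrix(0, max_lag, max_lag)
  phi[1, 1] <- rho[1]
  if (max_lag > 1) {
    for (k in 2:max_lag) {
      num <- rho[k] - sum(phi[k - 1, 1:(k - 1)] * rho[(k - 1):1])
      den <- 1 - sum(phi[k - 1, 1:(k - 1)] * rho[1:(k - 1)])
      phi[k, k] <- num / den
      phi[k, 1:(k - 1)] <- phi[k - 1, 1:(k - 1)] -
        phi[k, k] * phi[k - 1, (k - 1):1]
    }
  }
  diag(phi)
}

# scaled energy divergence for one explicit split, straight from the
# definition (double loops via dist sums)
oracle_energy_stat <- function(x, k, alpha = 1) {
  left <- x[1:k]
  right <- x[(k + 1):length(x)]
  m <- length(left)
  n <- length(right)
  cross <- mean(abs(outer(left, right, "-"))^alpha)
  wl <- sum(abs(outer(left, left, "-"))^alpha) / (m * (m - 1))
  wr <- sum(abs(outer(right, right, "-"))^alpha) / (n * (n - 1))
  (m * n / (m + n)) * (2 * cross - wl - wr)
}

oracle_best_split <- function(x, min_segment = 30, alpha = 1) {
  ks <- min_segment:(length(x) - min_segment)
  stats <- vapply(ks, function(k) oracle_energy_stat(x, k, alpha), numeric(1))
  list(k = ks[which.max(stats)], stat = max(stats))
}

# brute-force simplex projection: explicit pairwise distances and sort,
# mirroring the documented algorithm but sharing no code with the package
oracle_simplex <- function(y, E, tau, library_length, tp) {
  n <- length(y)
  offset <- (E - 1) * tau
  t_all <- offset:(n - 1)
  embed_at <- function(t) y[t - (0:(E - 1)) * tau + 1]
  lib_t <- t_all[t_all <= library_length - 1 - tp]
  pred_t <- t_all[t_all >= library_length & t_all + tp <= n - 1]
  fc <- sapply(pred_t, function(t) {
    v <- embed_at(t)
    d <- sapply(lib_t, function(s) sqrt(sum((embed_at(s) - v)^2)))
    o <- order(d, seq_along(d))[1:(E + 1)]
    w <- if (d[o[1]] > 0) exp(-d[o] / d[o[1]]) else rep(1, E + 1)
    sum(w * y[lib_t[o] + tp + 1]) / sum(w)
  })
  list(pred_t = pred_t, forecast = fc, obs = y[pred_t + tp + 1])
}
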