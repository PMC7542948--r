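#' Bonferroni-corrected alpha for the item battery
#'
#' Divides the nominal alpha by the number of items tested and rounds
#' half-up to 3 decimals (so .05 over 29 items gives .002).
#'
#' @param alpha_nominal Nominal significance level (default .05).
#' @param n_items Number of items tested (>= 1).
#' @return The rounded threshold, with the unrounded ratio attached as
#'   attribute `"raw"`. If rounding collapses the threshold to 0 a precision
#'   warning is raised; use the raw ratio in that case.
#' @examples
#' bonferroni_alpha(0.05, 29)
#' @export
bonferroni_alpha <- function(alpha_nominal = 0.05, n_items) {
  if (alpha_nominal <= 0 || alpha_nominal >= 1) {
    abort("`alpha_nominal` must lie in (0, 1).", class = "ema_parameter_error")
  }
  n_items <- as.integer(n_items)
  if (n_items < 1) abort("`n_items` must be >= 1.",
                         class = "ema_parameter_error")
  raw <- alpha_nominal / n_items
  out <- floor(raw * 1000 + 0.5) / 1000 # round half-up, 3 decimals
  if (out == 0) {
    warn("Bonferroni threshold rounds to 0 at 3 decimals; use attr(, 'raw').")
  }
  attr(out, "raw") <- raw
  out
}

#' Battery configuration
#'
#' Bundles every marker's tunable parameters. Defaults are the study
#' configuration: ratings rescaled to 1–7, PACF significance counted up to
#' `n/3` lags at alpha .05, TV-AR with basis dimension 10, e-divisive with
#' moment index 1 / minimum segment 30 / 199 permutations / stop at .05, and
#' simplex projection with E = 13, tau = 4, a 700-point library and horizons
#' 1–10 with the decay slope over horizons 1–5.
#'
#' @param alpha_nominal Nominal alpha before Bonferroni correction.
#' @param acf_alpha Two-sided alpha for the PACF significance threshold.
#' @param acf_count_max_lag Largest lag scanned when counting significant
#'   partial autocorrelations; `NULL` means `floor(n/3)`.
#' @param tvar_k TV-AR basis dimension per curve.
#' @param edivisive_alpha_moment,edivisive_min_segment,edivisive_n_permutations,edivisive_alpha_stop
#'   Change-point parameters, see [e_divisive()].
#' @param simplex_E,simplex_tau,simplex_library,simplex_horizons,slope_window
#'   Forecasting parameters, see [simplex_forecast()] and [decay_slope()].
#' @param rescale_to Target rating range for descriptives and analysis.
#' @param seed Integer seed controlling every stochastic step of the battery.
#' @return A list of class `ema_battery_config`.
#' @export
battery_config <- function(alpha_nominal = 0.05,
                           acf_alpha = 0.05,
                           acf_count_max_lag = NULL,
                           tvar_k = 10,
                           edivisive_alpha_moment = 1,
                           edivisive_min_segment = 30,
                           edivisive_n_permutations = 199,
                           edivisive_alpha_stop = 0.05,
                           simplex_E = 13,
                           simplex_tau = 4,
                           simplex_library = 700,
                           simplex_horizons = 1:10,
                           slope_window = 1:5,
                           rescale_to = c(1, 7),
                           seed = 1) {
  structure(list(alpha_nominal = alpha_nominal, acf_alpha = acf_alpha,
                 acf_count_max_lag = acf_count_max_lag, tvar_k = tvar_k,
                 edivisive_alpha_moment = edivisive_alpha_moment,
                 edivisive_min_segment = edivisive_min_segment,
                 edivisive_n_permutations = edivisive_n_permutations,
                 edivisive_alpha_stop = edivisive_alpha_stop,
                 simplex_E = simplex_E, simplex_tau = simplex_tau,
                 simplex_library = simplex_library,
                 simplex_horizons = simplex_horizons,
                 slope_window = slope_window, rescale_to = rescale_to,
                 seed = as.integer(seed)),
            class = "ema_battery_config")
}

#' Run the full complexity battery
#'
#' Per item: rescales ratings to the common range, computes mean/SD on
#' non-missing values, then runs all three markers on the full measurement
#' period and re-runs Bartels, TV-AR, KPSS and the change-point analysis on
#' the baseline subset (after zero-variance exclusion). Significance flags
#' use the Bonferroni-corrected alpha, except the KPSS test, whose clamped
#' p-value is flagged significant only at its .010 bound. Decay slopes are
#' computed on the full period only (the library/prediction split does not
#' fit in a short baseline window). Per-item failures are recorded in the
#' row's `notes` and never abort the batch. Deterministic given `cfg$seed`.
#'
#' @param data An `ema_df` with `baseline_end` set.
#' @param cfg A [battery_config()].
#' @return A tibble of class `ema_battery_report` with one row per item and
#'   the Bonferroni alpha, configuration and excluded baseline items attached
#'   as attributes. Summarize with [summarise_battery()].
#' @examples
#' \donttest{
#' d <- generate_study_like_dataset(n_items = 4, n_timepoints = 400, seed = 1,
#'                                  baseline_end = 150)
#' cfg <- battery_config(simplex_E = 3, simplex_tau = 1, simplex_library = 200,
#'                       edivisive_n_permutations = 49)
#' run_battery(d, cfg)
#' }
#' @export
run_battery <- function(data, cfg = battery_config()) {
  if (!inherits(cfg, "ema_battery_config")) {
    abort("`cfg` must be a battery_config().", class = "ema_config_error")
  }
  items <- ema_items(data)
  alpha_b <- bonferroni_alpha(cfg$alpha_nominal, length(items))
  # rescale item by item so one degenerate native scale cannot sink the batch
  scaled <- data
  rescale_failures <- character(0)
  for (it in items) {
    scaled <- tryCatch(
      rescale_items(scaled, cfg$rescale_to[1], cfg$rescale_to[2], items = it),
      error = function(e) {
        rescale_failures[[it]] <<- conditionMessage(e)
        scaled
      })
  }
  parts <- split_baseline(scaled)
  baseline <- tryCatch(drop_zero_variance(parts$baseline),
                       error = function(e) NULL)
  excluded <- if (is.null(baseline)) items else excluded_items(baseline)
  n_full <- n_timepoints(scaled)
  count_lag <- cfg$acf_count_max_lag %||% floor(n_full / 3)

  rows <- purrr::imap_dfr(items, function(it, i) {
    notes <- character(0)
    if (it %in% names(rescale_failures)) {
      notes <- paste0("rescale: ", rescale_failures[[it]])
    }
    note <- function(step, e) {
      notes <<- c(notes, paste0(step, ": ", conditionMessage(e)))
      NULL
    }
    try_marker <- function(step, expr) {
      withCallingHandlers(
        tryCatch(expr, error = function(e) note(step, e)),
        warning = function(w) {
          notes <<- c(notes, paste0(step, ": ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
    }
    x <- series_values(scaled, it)
    in_subset <- !(it %in% excluded)

    bart_f <- try_marker("bartels_full", bartels_core(x[!is.na(x)]))
    bart_s <- if (in_subset) {
      xs <- series_values(parts$baseline, it)
      try_marker("bartels_subset", bartels_core(xs[!is.na(xs)]))
    }
    pacf_f <- try_marker("pacf_full", {
      pr <- acf_profile(scaled, max_lag = count_lag, alpha = cfg$acf_alpha,
                        items = it)
      summarise_acf_profile(pr)
    })
    tvar_f <- try_marker("tvar_full", tvar_fit_one(x, it, k = cfg$tvar_k))
    tvar_s <- if (in_subset) {
      try_marker("tvar_subset",
                 tvar_fit_one(series_values(parts$baseline, it), it,
                              k = cfg$tvar_k))
    }
    kpss_f <- try_marker("kpss_full", kpss_core(x[!is.na(x)]))
    kpss_s <- if (in_subset) {
      xs <- series_values(parts$baseline, it)
      try_marker("kpss_subset", kpss_core(xs[!is.na(xs)]))
    }
    cp_f <- try_marker("changepoints_full",
                       e_divisive(scaled, cfg$edivisive_alpha_moment,
                                  cfg$edivisive_min_segment,
                                  cfg$edivisive_n_permutations,
                                  cfg$edivisive_alpha_stop,
                                  seed = cfg$seed + i, items = it))
    cp_s <- if (in_subset) {
      try_marker("changepoints_subset",
                 e_divisive(parts$baseline, cfg$edivisive_alpha_moment,
                            cfg$edivisive_min_segment,
                            cfg$edivisive_n_permutations,
                            cfg$edivisive_alpha_stop,
                            seed = cfg$seed + i + 1000L, items = it))
    }
    slope <- try_marker("simplex_full", {
      curve <- simplex_forecast(scaled, E = cfg$simplex_E,
                                tau = cfg$simplex_tau,
                                library_length = cfg$simplex_library,
                                horizons = cfg$simplex_horizons, items = it)
      decay_slope(curve, cfg$slope_window)$decay_slope
    })

    tibble::tibble(
      item = it,
      mean = mean(x, na.rm = TRUE),
      sd = sd(x, na.rm = TRUE),
      bartels_p_full = bart_f$p %||% NA_real_,
      bartels_sig_full = if (!is.null(bart_f)) bart_f$p < alpha_b else NA,
      bartels_p_subset = bart_s$p %||% NA_real_,
      bartels_sig_subset = if (in_subset && !is.null(bart_s)) {
        bart_s$p < alpha_b
      } else NA,
      n_sig_pacf = pacf_f$n_sig_pacf %||% NA_integer_,
      max_sig_pacf_lag = pacf_f$max_sig_pacf_lag %||% NA_integer_,
      edf_full = tvar_f$edf %||% NA_real_,
      edf_sig_full = if (!is.null(tvar_f)) tvar_f$smooth_p < alpha_b else NA,
      edf_subset = tvar_s$edf %||% NA_real_,
      edf_sig_subset = if (in_subset && !is.null(tvar_s)) {
        tvar_s$smooth_p < alpha_b
      } else NA,
      kpss_p_full = kpss_f$p %||% NA_real_,
      kpss_sig_full = if (!is.null(kpss_f)) {
        kpss_f$p <= 0.010 + 1e-12
      } else NA,
      kpss_p_subset = kpss_s$p %||% NA_real_,
      kpss_sig_subset = if (in_subset && !is.null(kpss_s)) {
        kpss_s$p <= 0.010 + 1e-12
      } else NA,
      n_changepoints_full = cp_f$n_changepoints %||% NA_integer_,
      n_changepoints_subset = if (in_subset) {
        cp_s$n_changepoints %||% NA_integer_
      } else NA_integer_,
      decay_slope = slope %||% NA_real_,
      notes = paste(notes, collapse = "; "))
  })
  structure(rows, alpha_bonferroni = as.numeric(alpha_b), config = cfg,
            excluded_items = excluded,
            class = c("ema_battery_report", class(rows)))
}

#' Column-wise summary of significant tests
#'
#' Counts (and percentages) of items flagged significant per test column,
#' mirroring a report table's bottom summary row.
#'
#' @param report A [run_battery()] result.
#' @return Tibble with `column`, `n_sig`, `n_tested`, `pct`.
#' @export
summarise_battery <- function(report) {
  sig_cols <- names(report)[grepl("_sig_", names(report)) &
                              vapply(report, is.logical, logical(1))]
  purrr::map_dfr(sig_cols, function(cl) {
    v <- report[[cl]]
    tibble::tibble(column = cl, n_sig = sum(v, na.rm = TRUE),
                   n_tested = sum(!is.na(v)),
                   pct = 100 * sum(v, na.rm = TRUE) / max(sum(!is.na(v)), 1))
  })
}

#' Write a battery report to TSV (and optionally JSON)
#'
#' The TSV mirrors the per-item report layout: fixed column order, asterisk
#' columns (`*` / empty) next to each tested p-value or EDF rather than
#' glyphs embedded in numbers, and explicit `NA` tokens for subset cells of
#' items excluded from the baseline analysis. The JSON companion carries
#' full-precision values plus an echo of the configuration.
#'
#' @param report A [run_battery()] result.
#' @param path Output TSV path.
#' @param json_path Optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, json_path = NULL) {
  if (nrow(report) == 0) {
    abort("Empty report.", class = "ema_parameter_error")
  }
  star <- function(v) dplyr::if_else(is.na(v), NA_character_,
                                     dplyr::if_else(v, "*", ""))
  tsv <- tibble::as_tibble(report) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.logical), star))
  readr::write_tsv(tsv, path, na = "NA", progress = FALSE)
  if (!is.null(json_path)) {
    cfg <- attr(report, "config")
    payload <- list(
      alpha_bonferroni = attr(report, "alpha_bonferroni"),
      excluded_items = attr(report, "excluded_items"),
      config = unclass(cfg),
      rows = tibble::as_tibble(report))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
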