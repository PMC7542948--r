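#' Plot methods for battery result types
#'
#' `autoplot()` methods give quick ggplot2 views of each result: raw series
#' (`ema_df`), ACF/PACF profiles with their significance band
#' (`ema_acf_profile`), per-lag medians and interquartile ranges of windowed
#' ACFs (`ema_window_acf`), forecast-skill curves by horizon
#' (`ema_skill_curve`) and TV-AR coefficient curves (`ema_tvar`).
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name ema-autoplot
NULL

#' @rdname ema-autoplot
#' @export
autoplot.ema_df <- function(object, ...) {
  tbl <- tibble::as_tibble(object)
  tbl$value[tbl$missing] <- NA_real_
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$item), scales = "free_y") +
    ggplot2::labs(x = "assessment", y = "rating")
}

#' @rdname ema-autoplot
#' @export
autoplot.ema_acf_profile <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("acf", "pacf"), names_to = "fn",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$sig_threshold),
                        colour = "red", linetype = 2, linewidth = 0.3) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = -.data$sig_threshold),
                        colour = "red", linetype = 2, linewidth = 0.3) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0),
                          linewidth = 0.3) +
    ggplot2::facet_grid(ggplot2::vars(.data$fn), ggplot2::vars(.data$item)) +
    ggplot2::labs(y = "correlation")
}

#' @rdname ema-autoplot
#' @export
autoplot.ema_window_acf <- function(object, ...) {
  s <- summarise_window_acf(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$lag, y = .data$median)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                            linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$item)) +
    ggplot2::labs(y = "windowed autocorrelation (median, IQR)")
}

#' @rdname ema-autoplot
#' @export
autoplot.ema_skill_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$horizon, y = .data$skill,
                               colour = .data$item)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "prediction horizon (steps)",
                  y = "forecast skill (Pearson r)")
}

#' @rdname ema-autoplot
#' @export
autoplot.ema_tvar <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$t, y = .data$phi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "assessment", y = "time-varying lag-1 coefficient")
}

#' Plot a series with its detected change points
#'
#' @param data The `ema_df` the change points were estimated from.
#' @param changepoints An [e_divisive()] result for items of `data`.
#' @return A ggplot object with vertical lines at the change points (original
#'   assessment indices).
#' @export
plot_changepoints <- function(data, changepoints) {
  cps <- tibble::as_tibble(changepoints) |>
    dplyr::select("item", "change_indices_original") |>
    tidyr::unnest("change_indices_original")
  autoplot.ema_df(data[data$item %in% changepoints$item, ]) +
    ggplot2::geom_vline(data = cps,
                        ggplot2::aes(xintercept = .data$change_indices_original),
                        colour = "blue", linewidth = 0.3)
}
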