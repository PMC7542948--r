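#' EMA datasets as tidy tibbles
#'
#' An `ema_df` is a long tibble with one row per (assessment, item) cell and
#' columns `time` (0-based assessment rank, unit spacing), `item` (character),
#' `value` (numeric rating on the item's native scale; may be recorded even for
#' missing cells) and `missing` (logical flag). Items are assumed to share the
#' assessment index; beeps are treated as equally spaced, which is what every
#' marker in the battery assumes.
#'
#' Dataset-level metadata travels as attributes:
#' * `scale_spec` — tibble with `item`, `scale_min`, `scale_max`;
#' * `baseline_end` — exclusive 0-based index ending the pre-taper baseline
#'   window, or `NULL`;
#' * `items` — item labels in their original (input) order;
#' * `ground_truth` — for synthetic data, one row per item describing the
#'   generating process (see [generate_study_like_dataset()]).
#'
#' dplyr verbs may drop these attributes; use [as_ema_df()] to reattach them.
#'
#' @param x A data frame with columns `time`, `item`, `value` and optionally
#'   `missing` (defaults to `is.na(value)`).
#' @param scale_spec Tibble with columns `item`, `scale_min`, `scale_max`
#'   giving the native rating-scale bounds of every item. If `NULL`, bounds
#'   default to each item's observed range.
#' @param baseline_end Exclusive 0-based index of the end of the baseline
#'   window, or `NULL` if unknown.
#' @param ground_truth Optional tibble of per-item generator metadata.
#' @return An `ema_df` tibble, completed to the full time-by-item grid, with
#'   `time` re-indexed to the 0-based assessment rank.
#' @examples
#' d <- as_ema_df(data.frame(
#'   time = rep(0:3, 2), item = rep(c("a", "b"), each = 4),
#'   value = c(1, 2, 3, 2, 5, NA, 6, 7)
#' ))
#' n_timepoints(d)
#' @export
as_ema_df <- function(x, scale_spec = NULL, baseline_end = NULL,
                      ground_truth = NULL) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame.", class = "ema_type_error")
  }
  need <- c("time", "item", "value")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("`x` lacks required column(s): ", toString(miss)),
          class = "ema_type_error")
  }
  tbl <- tibble::as_tibble(x)
  tbl$item <- as.character(tbl$item)
  if (!"missing" %in% names(tbl)) tbl$missing <- is.na(tbl$value)
  tbl$missing <- as.logical(tbl$missing) | is.na(tbl$value)

  if (anyDuplicated(tbl[, c("time", "item")]) > 0) {
    dup <- tbl[duplicated(tbl[, c("time", "item")]), c("time", "item")][1, ]
    abort(sprintf("Duplicated (time, item) cell: time=%s, item=%s.",
                  format(dup$time), dup$item),
          class = "ema_data_error")
  }

  item_order <- unique(tbl$item)
  times <- sort(unique(tbl$time))
  # re-index to assessment rank (0-based, unit spacing)
  tbl$time <- match(tbl$time, times) - 1L
  grid <- tidyr::expand_grid(time = seq_along(times) - 1L, item = item_order)
  tbl <- dplyr::left_join(grid, tbl, by = c("time", "item"))
  tbl$missing[is.na(tbl$missing)] <- TRUE
  tbl <- dplyr::arrange(tbl, match(.data$item, item_order), .data$time)

  if (is.null(scale_spec)) {
    scale_spec <- tbl |>
      dplyr::filter(!.data$missing) |>
      dplyr::group_by(.data$item) |>
      dplyr::summarise(scale_min = min(.data$value),
                       scale_max = max(.data$value), .groups = "drop")
    # items that are entirely missing get a degenerate placeholder
    left_out <- setdiff(item_order, scale_spec$item)
    if (length(left_out) > 0) {
      scale_spec <- dplyr::bind_rows(
        scale_spec,
        tibble::tibble(item = left_out, scale_min = NA_real_,
                       scale_max = NA_real_))
    }
    scale_spec <- scale_spec[match(item_order, scale_spec$item), ]
  } else {
    scale_spec <- tibble::as_tibble(scale_spec)
    unknown <- setdiff(scale_spec$item, item_order)
    if (length(unknown) > 0) {
      abort(paste0("scale_spec names item(s) not present in the data: ",
                   toString(unknown)), class = "ema_config_error")
    }
    uncovered <- setdiff(item_order, scale_spec$item)
    if (length(uncovered) > 0) {
      abort(paste0("scale_spec does not cover item(s): ", toString(uncovered)),
            class = "ema_config_error")
    }
    scale_spec <- scale_spec[match(item_order, scale_spec$item), ]
    bad <- dplyr::left_join(dplyr::filter(tbl, !.data$missing),
                            scale_spec, by = "item")
    bad <- bad[bad$value < bad$scale_min | bad$value > bad$scale_max, ]
    if (nrow(bad) > 0) {
      abort(sprintf(
        "Value %s for item '%s' at time %d lies outside its scale [%s, %s].",
        format(bad$value[1]), bad$item[1], bad$time[1],
        format(bad$scale_min[1]), format(bad$scale_max[1])),
        class = "ema_data_error")
    }
  }

  n_tp <- length(times)
  if (!is.null(baseline_end)) {
    baseline_end <- as.integer(baseline_end)
    if (baseline_end <= 0 || baseline_end > n_tp) {
      abort("`baseline_end` must lie in (0, n_timepoints].",
            class = "ema_window_error")
    }
  }

  new_ema_df(tbl, items = item_order, scale_spec = scale_spec,
             baseline_end = baseline_end, ground_truth = ground_truth)
}

new_ema_df <- function(tbl, items, scale_spec, baseline_end = NULL,
                       ground_truth = NULL) {
  structure(tibble::as_tibble(tbl),
            items = items,
            scale_spec = scale_spec,
            baseline_end = baseline_end,
            ground_truth = ground_truth,
            class = c("ema_df", class(tibble::tibble())))
}

#' Accessors for `ema_df` metadata
#'
#' @param x An `ema_df` (see [as_ema_df()]).
#' @return `ema_items()`: character vector of item labels in input order.
#'   `n_timepoints()`: integer number of shared assessment indices.
#'   `scale_spec()`: tibble of per-item scale bounds. `baseline_end()`:
#'   exclusive baseline index or `NULL`. `ground_truth()`: generator metadata
#'   or `NULL`. `excluded_items()`: labels removed by [drop_zero_variance()].
#' @export
ema_items <- function(x) attr(x, "items") %||% unique(x$item)

#' @rdname ema_items
#' @export
n_timepoints <- function(x) length(unique(x$time))

#' @rdname ema_items
#' @export
scale_spec <- function(x) attr(x, "scale_spec")

#' @rdname ema_items
#' @export
baseline_end <- function(x) attr(x, "baseline_end")

#' @rdname ema_items
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' @rdname ema_items
#' @export
excluded_items <- function(x) attr(x, "excluded_items")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one item's ratings as a numeric vector
#'
#' Values flagged missing are returned as `NA`, preserving the assessment
#' index, so downstream analyses can choose their own missing-data policy.
#'
#' @param data An `ema_df`.
#' @param item Item label; may be omitted for single-item datasets.
#' @return Numeric vector of length `n_timepoints(data)` in time order.
#' @export
series_values <- function(data, item = NULL) {
  its <- ema_items(data)
  if (is.null(item)) {
    if (length(its) != 1) {
      abort("`item` must be given for multi-item datasets.",
            class = "ema_config_error")
    }
    item <- its
  }
  if (!item %in% its) {
    abort(paste0("Unknown item: ", item), class = "ema_config_error")
  }
  rows <- data[data$item == item, ]
  rows <- rows[order(rows$time), ]
  out <- rows$value
  out[rows$missing] <- NA_real_
  out
}

resolve_items <- function(data, items) {
  if (is.null(items)) return(ema_items(data))
  bad <- setdiff(items, ema_items(data))
  if (length(bad) > 0) {
    abort(paste0("Unknown item(s): ", toString(bad)),
          class = "ema_config_error")
  }
  items
}

#' Read an EMA table from CSV
#'
#' Wide layout: header row of item labels with a first column named `time`.
#' Long layout: columns `time,item,value`. Comma separator, UTF-8, `.`
#' decimal. Empty cells (or `NA`) are flagged missing. The assessment index is
#' the rank of the `time` column (0-based, unit spacing).
#'
#' @param path Path to a CSV file.
#' @param layout `"wide"` or `"long"`.
#' @param scale_spec Per-item scale bounds (tibble `item`, `scale_min`,
#'   `scale_max`); must cover exactly the items present. `NULL` infers bounds
#'   from the observed per-item range.
#' @param baseline_end Optional exclusive baseline index (0-based).
#' @return An [as_ema_df()] tibble with deterministic item order (input order).
#' @export
read_ema_table <- function(path, layout = c("wide", "long"),
                           scale_spec = NULL, baseline_end = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "ema_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (layout == "wide") {
    if (names(raw)[1] != "time") {
      abort("Wide layout requires the first column to be named 'time'.",
            class = "ema_data_error")
    }
    long <- tidyr::pivot_longer(raw, -"time", names_to = "item",
                                values_to = "value")
  } else {
    need <- c("time", "item", "value")
    if (!all(need %in% names(raw))) {
      abort("Long layout requires columns time, item, value.",
            class = "ema_data_error")
    }
    long <- raw[, need]
  }
  long$time <- parse_numeric_col(long$time, "time")
  long$value <- parse_numeric_col(long$value, "value")
  long$missing <- is.na(long$value)
  as_ema_df(long, scale_spec = scale_spec, baseline_end = baseline_end)
}

parse_numeric_col <- function(x, col) {
  x <- trimws(x)
  empty <- is.na(x) | x == "" | x == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!empty & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("Non-numeric %s value '%s' in row %d.", col, x[bad[1]],
                  bad[1]), class = "ema_parse_error")
  }
  out
}

#' Write an EMA dataset to CSV
#'
#' Inverse of [read_ema_table()]: missing cells are written as empty strings.
#' Note that the `missing` flag and the stored value cannot both survive a
#' round trip — masked cells are emitted as empty, matching the reader's
#' contract.
#'
#' @param data An `ema_df`.
#' @param path Output file path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_ema_table <- function(data, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  tbl <- tibble::as_tibble(data)[, c("time", "item", "value", "missing")]
  tbl$value[tbl$missing] <- NA_real_
  tbl$missing <- NULL
  if (layout == "wide") {
    wide <- tidyr::pivot_wider(tbl, names_from = "item",
                               values_from = "value")
    wide <- wide[, c("time", ema_items(data))]
    readr::write_csv(wide, path, na = "", progress = FALSE)
  } else {
    readr::write_csv(tbl, path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Rescale items to a common rating range
#'
#' Applies the affine map from each item's native scale bounds to
#' `[target_min, target_max]` (the battery reports descriptives with all
#' ratings on a 1–7 scale). Missing flags are unchanged; masked values are
#' rescaled too, since they live on the native scale.
#'
#' @param data An `ema_df`.
#' @param target_min,target_max Target scale bounds, `target_max > target_min`.
#' @param items Items to rescale (default all).
#' @return An `ema_df` with updated values and scale_spec.
#' @examples
#' d <- as_ema_df(data.frame(time = 0:2, item = "m", value = c(-3, 0, 3)),
#'                scale_spec = data.frame(item = "m", scale_min = -3,
#'                                        scale_max = 3))
#' series_values(rescale_items(d, 1, 7))
#' @export
rescale_items <- function(data, target_min = 1, target_max = 7, items = NULL) {
  if (target_max <= target_min) {
    abort("`target_max` must exceed `target_min`.",
          class = "ema_parameter_error")
  }
  items <- resolve_items(data, items)
  spec <- scale_spec(data)
  out <- tibble::as_tibble(data)
  for (it in items) {
    row <- spec[spec$item == it, ]
    w <- row$scale_max - row$scale_min
    if (is.na(w) || w <= 0) {
      abort(paste0("Item '", it, "' has a zero-width native scale."),
            class = "ema_degenerate_scale")
    }
    sel <- out$item == it
    out$value[sel] <- target_min +
      (out$value[sel] - row$scale_min) * (target_max - target_min) / w
    spec$scale_min[spec$item == it] <- target_min
    spec$scale_max[spec$item == it] <- target_max
  }
  new_ema_df(out, items = ema_items(data), scale_spec = spec,
             baseline_end = baseline_end(data),
             ground_truth = ground_truth(data))
}

#' Split off the baseline window
#'
#' Returns the baseline subset (assessments `[0, baseline_end)`) together with
#' the full dataset: the battery analyzes both the full measurement period and
#' the baseline window, not the complement.
#'
#' @param data An `ema_df` with `baseline_end` set.
#' @return Named list with elements `baseline` and `full`.
#' @export
split_baseline <- function(data) {
  be <- baseline_end(data)
  if (is.null(be) || be <= 1) {
    abort("`baseline_end` must be set and exceed 1.",
          class = "ema_window_error")
  }
  sub <- tibble::as_tibble(data)[data$time < be, ]
  baseline <- new_ema_df(sub, items = ema_items(data),
                         scale_spec = scale_spec(data),
                         baseline_end = be,
                         ground_truth = ground_truth(data))
  list(baseline = baseline, full = data)
}

#' Drop items with no variance
#'
#' Items whose non-missing values are all identical (or entirely missing) are
#' removed; the survivors keep their order. The excluded labels are attached as
#' the `excluded_items` attribute (see [excluded_items()]).
#'
#' @param data An `ema_df`.
#' @return An `ema_df` without the zero-variance items.
#' @export
drop_zero_variance <- function(data) {
  its <- ema_items(data)
  constant <- vapply(its, function(it) {
    v <- series_values(data, it)
    v <- v[!is.na(v)]
    length(unique(v)) < 2
  }, logical(1))
  excluded <- its[constant]
  if (all(constant)) {
    abort("All items have zero variance; nothing left to analyze.",
          class = "ema_empty_dataset")
  }
  keep <- its[!constant]
  out <- tibble::as_tibble(data)[data$item %in% keep, ]
  spec <- scale_spec(data)
  gt <- ground_truth(data)
  res <- new_ema_df(out, items = keep,
                    scale_spec = spec[spec$item %in% keep, ],
                    baseline_end = baseline_end(data),
                    ground_truth = if (!is.null(gt)) gt[gt$item %in% keep, ])
  attr(res, "excluded_items") <- excluded
  res
}
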