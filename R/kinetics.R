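#' Maximum growth amplitude of an OD600 curve
#'
#' The maximum of the (optionally smoothed) OD600 series -- the plateau
#' height a culture reaches over the monitored window.
#'
#' @param od OD600 values.
#' @param smooth_window Moving-average window (points) applied before
#'   taking the maximum; 1 (default) uses the raw series.
#' @return Maximum OD600 (single number).
#' @examples
#' curve <- simulate_growth_curve(0:48, 1, 0.8, 12)
#' max_amplitude(curve$od)
#' @export
max_amplitude <- function(od, smooth_window = 1) {
  max(moving_average(od, smooth_window))
}

# Centered moving average with shrinking windows at the ends, so the
# output has the same length and no NA padding.
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window > length(x)) abort("`smooth_window` larger than the series")
  if (window <= 1) return(x)
  half <- (window - 1) %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + (window - 1L - half), length(x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Maximum first-order growth rate of an OD600 curve
#'
#' Smooths the series with a centered moving average, differentiates it
#' with centered finite differences (one-sided at the ends), and returns
#' the maximum of the derivative together with the time at which it
#' occurs. For a noiseless logistic curve of amplitude `K` and rate `r`
#' the maximum first derivative is `r K / 4` at the inflection point.
#'
#' @param time Time points (hours), strictly increasing.
#' @param od OD600 values, same length as `time` (at least
#'   `smooth_window + 2` points).
#' @param smooth_window Moving-average window in points; 1 differentiates
#'   the raw curve. Default 5.
#' @return A list with `rate` (OD600/hour) and `t_max_rate` (hours).
#' @examples
#' curve <- simulate_growth_curve(seq(0, 30, 0.1), 1, 0.8, 12)
#' max_growth_rate(curve$time, curve$od)$rate  # ~ 0.8 * 1 / 4
#' @export
max_growth_rate <- function(time, od, smooth_window = 5) {
  if (length(time) != length(od)) abort("`time` and `od` lengths differ")
  if (any(diff(time) <= 0)) abort("`time` must be strictly increasing")
  if (length(od) < smooth_window + 2) {
    abort("need at least `smooth_window` + 2 points")
  }
  y <- moving_average(od, smooth_window)
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (time[2] - time[1])
  d[n] <- (y[n] - y[n - 1]) / (time[n] - time[n - 1])
  mid <- 2:(n - 1)
  d[mid] <- (y[mid + 1] - y[mid - 1]) / (time[mid + 1] - time[mid - 1])
  i <- which.max(d)
  list(rate = d[i], t_max_rate = time[i])
}

#' Summarize growth-curve features per strain and condition
#'
#' Computes the maximum amplitude and maximum first-order growth rate per
#' curve, then averages replicate curves of the same strain x condition
#' (per-curve maximization first, replicate averaging second).
#'
#' @param curves Long tibble with columns `strain_id`, `condition`,
#'   `time`, `od`, and optionally `replicate` (assumed 1 if absent).
#' @param smooth_window Moving-average window passed to the per-curve
#'   metrics. Default 5.
#' @return A tibble with `strain_id`, `condition`, `max_amplitude`,
#'   `max_rate`, `t_max_rate`, `n` (replicate curves).
#' @export
summarize_kinetics <- function(curves, smooth_window = 5) {
  if (!"replicate" %in% names(curves)) curves$replicate <- 1L
  curves |>
    dplyr::group_by(.data$strain_id, .data$condition, .data$replicate) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::summarise(
      max_amplitude = max_amplitude(.data$od, smooth_window),
      rate = list(max_growth_rate(.data$time, .data$od, smooth_window)),
      .groups = "drop") |>
    dplyr::mutate(max_rate = purrr::map_dbl(.data$rate, "rate"),
                  t_max_rate = purrr::map_dbl(.data$rate, "t_max_rate")) |>
    dplyr::group_by(.data$strain_id, .data$condition) |>
    dplyr::summarise(max_amplitude = mean(.data$max_amplitude),
                     max_rate = mean(.data$max_rate),
                     t_max_rate = mean(.data$t_max_rate),
                     n = dplyr::n(), .groups = "drop")
}

#' Fold change of growth metrics relative to WT
#'
#' Divides each strain's growth metrics by the WT value under the same
#' condition, giving the fold-change values used for heat-map style
#' comparisons across carbon sources. The WT rows are 1 by construction;
#' a WT metric of 0 yields `NA` (flagged undefined, not infinity) with a
#' warning.
#'
#' @param summaries Kinetics summary tibble from [summarize_kinetics()]
#'   (or any tibble with `strain_id`, `condition` and numeric metric
#'   columns).
#' @param wt_id WT strain id. Default `"WT"`.
#' @param metrics Metric columns to convert. Default
#'   `c("max_amplitude", "max_rate")`.
#' @return A tibble `strain_id`, `condition`, one `fold_<metric>` column
#'   per metric.
#' @export
fold_change_table <- function(summaries, wt_id = "WT",
                              metrics = c("max_amplitude", "max_rate")) {
  wt <- dplyr::filter(summaries, .data$strain_id == wt_id)
  missing_cond <- setdiff(unique(summaries$condition), wt$condition)
  if (length(missing_cond) > 0) {
    abort(paste0("no WT summary for condition(s): ",
                 paste(missing_cond, collapse = ", ")))
  }
  wt_ref <- wt[c("condition", metrics)]
  names(wt_ref) <- c("condition", paste0(".wt_", metrics))
  out <- dplyr::left_join(summaries[c("strain_id", "condition", metrics)],
                          wt_ref, by = "condition")
  for (m in metrics) {
    ref <- out[[paste0(".wt_", m)]]
    if (any(ref == 0)) warn(sprintf("WT metric '%s' is 0; fold change NA", m))
    out[[paste0("fold_", m)]] <- ifelse(ref == 0, NA_real_, out[[m]] / ref)
  }
  out[c("strain_id", "condition", paste0("fold_", metrics))]
}
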