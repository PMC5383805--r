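#' Daily trend series by grouping variable
#'
#' Exact per-day record counts per group level, zero-filled over the full
#' window range so every series shares the same day axis. Records with a
#' missing grouping value (unclassified queries, domains with no advocacy
#' stance) are dropped from the grouped series.
#'
#' @param classified Output of [classify_log()].
#' @param group_by One of `"category"`, `"tld_category"`,
#'   `"content_category"`, `"advocacy"`.
#' @param window A [event_window()] fixing the day axis.
#' @return A tibble of class `qp_trend` with columns `group, day, n`.
#' @export
daily_series <- function(classified, group_by = "tld_category",
                         window = event_window()) {
  stopifnot(is.data.frame(classified), inherits(window, "qp_window"))
  group_by <- rlang::arg_match(
    group_by, c("category", "tld_category", "content_category", "advocacy"))
  days <- seq(window$event_day - window$window_days,
              window$event_day + window$window_days - 1L)
  recs <- classified |>
    dplyr::filter(!is.na(.data[[group_by]]), .data$day %in% days)
  groups <- sort(unique(recs[[group_by]]))
  if (length(groups) == 0) groups <- "all"
  out <- recs |>
    dplyr::count(group = .data[[group_by]], .data$day) |>
    tidyr::complete(group = groups, day = days, fill = list(n = 0L)) |>
    dplyr::arrange(.data$group, .data$day)
  structure(out, window = window, group_by = group_by,
            class = c("qp_trend", class(out)))
}

trend_window <- function(series) {
  attr(series, "window") %||% event_window(0, max(abs(range(series$day))))
}

one_group_split <- function(series) {
  split(as_tibble(series), series$group)
}

#' Detect pre-event spikes in daily series
#'
#' A pre-event day is flagged as a spike when its count exceeds the median
#' of the pre-event days by more than `k` robust standard deviations
#' (MAD-based). Median/MAD statistics make detection insensitive to the
#' spikes themselves and invariant under uniform rescaling of the series.
#' At least 5 pre-event days are required.
#'
#' @param series A `qp_trend` from [daily_series()].
#' @param k Robust-SD multiplier (default 3).
#' @return A tibble `group, day` of flagged pre-event days (possibly empty).
#' @export
detect_spikes <- function(series, k = 3) {
  stopifnot(inherits(series, "qp_trend"))
  window <- trend_window(series)
  purrr::map_dfr(one_group_split(series), function(s) {
    pre <- s[s$day < window$event_day, ]
    if (nrow(pre) < 5) qp_config_abort("spike detection needs >= 5 pre-event days")
    thr <- median(pre$n) + k * mad(pre$n)
    tibble(group = pre$group[1], day = pre$day[pre$n > thr])
  })
}

#' Estimate the post-event return-to-baseline day
#'
#' Baseline level and spread are the median and MAD-based SD of the
#' pre-event days, excluding days flagged by [detect_spikes()] so isolated
#' pre-event news spikes do not inflate the baseline band. The return day
#' is the first post-event day opening a run of `consecutive` days whose
#' counts all sit within `baseline_mean + 2 * baseline_sd`; `NA` when the
#' series never re-enters the band inside the window.
#'
#' `consecutive = 1` estimates the band-crossing day itself; larger values
#' give a conservative declaration that tolerates single-day dips at the
#' cost of a systematically later (and near the window edge, censored)
#' estimate.
#'
#' @param series A `qp_trend` from [daily_series()].
#' @param consecutive Required run length of in-band days (default 3).
#' @param k Spike-detection multiplier used when cleaning the baseline.
#' @return A tibble `group, baseline_mean, baseline_sd, return_day`
#'   (`return_day` is `NA` when never returning).
#' @export
return_to_baseline_day <- function(series, consecutive = 3, k = 3) {
  stopifnot(inherits(series, "qp_trend"), consecutive >= 1)
  window <- trend_window(series)
  spikes <- detect_spikes(series, k = k)
  purrr::map_dfr(one_group_split(series), function(s) {
    g <- s$group[1]
    pre <- s[s$day < window$event_day, ]
    sp <- spikes$day[spikes$group == g]
    clean <- pre$n[!pre$day %in% sp]
    bmean <- median(clean)
    bsd <- mad(clean)
    post <- s[s$day >= window$event_day, ]
    below <- post$n <= bmean + 2 * bsd
    ret <- NA_integer_
    if (length(below) >= consecutive) {
      for (i in seq_len(length(below) - consecutive + 1)) {
        if (all(below[i:(i + consecutive - 1)])) { ret <- post$day[i]; break }
      }
    }
    tibble(group = g, baseline_mean = bmean, baseline_sd = bsd, return_day = ret)
  })
}
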