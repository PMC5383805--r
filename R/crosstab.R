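#' Relative change between the before and after windows
#'
#' The before/after contrast statistic: `100 * (after_n - before_n) /
#' before_n`, reported half-away-from-zero to `digits` decimals. A zero
#' before-count leaves the change undefined and yields `NA` (never
#' infinity).
#'
#' @param before_n,after_n Nonnegative counts (vectorised).
#' @param digits Decimals for reporting; `NULL` returns full precision.
#' @return Numeric vector of percent changes.
#' @examples
#' delta_percent(1345833, 2019526)
#' @export
delta_percent <- function(before_n, after_n, digits = 2) {
  out <- dplyr::if_else(before_n > 0,
                        100 * (after_n - before_n) / before_n,
                        NA_real_)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Running cumulative share of listed rows
#'
#' Running sum of `100 * n / total_n` in listed row order, as used for the
#' cumulative-percent column of the cross-tabulations. `total_n` is the
#' category total, which may exceed `sum(n)` when only the top classes are
#' listed.
#'
#' @param n Row counts in listed order.
#' @param total_n Category total count.
#' @param digits Decimals for reporting; `NULL` returns full precision.
#' @return Numeric vector of running percents.
#' @examples
#' cumulative_percent(c(965795, 595689), 3365359)
#' @export
cumulative_percent <- function(n, total_n, digits = 2) {
  out <- 100 * cumsum(n) / total_n
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Share of a total
#'
#' `100 * n / total_n`, the distribution statistic reported for category,
#' TLD, content and advocacy breakdowns.
#'
#' @param n Count (vectorised).
#' @param total_n Total count.
#' @param digits Decimals for reporting; `NULL` returns full precision.
#' @return Numeric vector of percents.
#' @examples
#' category_share(3370523, 5653588)
#' @export
category_share <- function(n, total_n, digits = 2) {
  out <- 100 * n / total_n
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

new_crosstab <- function(rows, group, window = NULL) {
  structure(rows, group = group, window = window,
            class = c("qp_crosstab", class(rows)))
}

#' Cross-tabulation from explicit before/after counts
#'
#' Builds a before/after cross-tabulation directly from per-class counts
#' (in listed row order), with optional category totals when only the top
#' classes are listed. Adds a residual row aggregating the unlisted
#' remainder when totals exceed the listed sum, and a total row. This is
#' both the finishing step of [build_crosstab()] and the entry point for
#' reproducing published tables whose counts are keyed in directly.
#'
#' @param counts Data frame with columns `class_label`, `before_n`,
#'   `after_n`, rows in the order they should be listed.
#' @param group Name of the query category the table describes.
#' @param total_before,total_after Category totals; default to the listed
#'   column sums.
#' @param window Optional [event_window()] carried as metadata.
#' @param residual_label Label for the residual row.
#' @return A `qp_crosstab`: a tibble with columns `class_label, n,
#'   before_n, before_pct, after_n, after_pct, delta_pct, cumulative_pct`,
#'   ending in a total row. Percent columns are reported to 2 decimals;
#'   counts are exact.
#' @export
crosstab_from_counts <- function(counts, group,
                                 total_before = NULL, total_after = NULL,
                                 window = NULL,
                                 residual_label = "all other classes") {
  stopifnot(is.data.frame(counts),
            all(c("class_label", "before_n", "after_n") %in% names(counts)))
  rows <- as_tibble(counts)[c("class_label", "before_n", "after_n")]
  total_before <- total_before %||% sum(rows$before_n)
  total_after <- total_after %||% sum(rows$after_n)
  if (total_before < sum(rows$before_n) || total_after < sum(rows$after_n)) {
    qp_config_abort("category totals cannot be smaller than the listed row sums")
  }
  res_b <- total_before - sum(rows$before_n)
  res_a <- total_after - sum(rows$after_n)
  if (res_b + res_a > 0) {
    rows <- dplyr::bind_rows(
      rows, tibble(class_label = residual_label, before_n = res_b, after_n = res_a))
  }
  total_n <- total_before + total_after
  body <- rows |>
    dplyr::mutate(
      n = .data$before_n + .data$after_n,
      before_pct = category_share(.data$before_n, .data$n),
      after_pct = category_share(.data$after_n, .data$n),
      delta_pct = delta_percent(.data$before_n, .data$after_n),
      cumulative_pct = if (total_n > 0) cumulative_percent(.data$n, total_n)
                       else rep(NA_real_, dplyr::n())
    )
  total <- tibble(
    class_label = "total",
    before_n = total_before, after_n = total_after, n = total_n,
    before_pct = category_share(total_before, total_n),
    after_pct = category_share(total_after, total_n),
    delta_pct = delta_percent(total_before, total_after),
    cumulative_pct = if (total_n > 0) 100 else NA_real_
  )
  out <- dplyr::bind_rows(body, total)[
    , c("class_label", "n", "before_n", "before_pct",
        "after_n", "after_pct", "delta_pct", "cumulative_pct")]
  new_crosstab(out, group = group, window = window)
}

#' Before/after cross-tabulation of one query category
#'
#' The workhorse table: counts classified records of one query category by
#' combined (content, TLD) class and before/after window, lists the
#' `top_k` classes by volume (descending), aggregates the remainder into a
#' residual row, and appends the category total with percent-change and
#' cumulative-share columns.
#'
#' @param classified Output of [classify_log()].
#' @param category Query category to tabulate.
#' @param window A [event_window()].
#' @param top_k Number of named class rows (default 4).
#' @return A `qp_crosstab` (empty categories give a zero total row, no error).
#' @export
build_crosstab <- function(classified, category, window = event_window(),
                           top_k = 4) {
  stopifnot(is.data.frame(classified), inherits(window, "qp_window"))
  recs <- classified |>
    dplyr::mutate(side = assign_window(.data$day, window)) |>
    dplyr::filter(.data$category == !!category, .data$side != "excluded",
                  !is.na(.data$class_label))
  if (nrow(recs) == 0) {
    return(crosstab_from_counts(
      tibble(class_label = character(0), before_n = integer(0), after_n = integer(0)),
      group = category, window = window))
  }
  wide <- recs |>
    dplyr::count(.data$class_label, .data$side) |>
    tidyr::pivot_wider(names_from = "side", values_from = "n", values_fill = 0L)
  for (col in c("before", "after")) if (!col %in% names(wide)) wide[[col]] <- 0L
  wide <- wide |>
    dplyr::rename(before_n = "before", after_n = "after") |>
    dplyr::mutate(n = .data$before_n + .data$after_n) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$class_label)
  top <- head(wide, top_k)
  crosstab_from_counts(
    top[c("class_label", "before_n", "after_n")], group = category,
    total_before = sum(wide$before_n), total_after = sum(wide$after_n),
    window = window)
}

#' Advocacy-view cross-tabulation per query category
#'
#' For each query category, tabulates records that landed on an advocacy
#' domain by advocacy view (gun rights vs gun control): count, share of the
#' category's advocacy traffic, before/after percent split, and percent
#' change, plus a per-category total row.
#'
#' @param classified Output of [classify_log()].
#' @param window A [event_window()].
#' @return A tibble of class `qp_advocacy` with columns `group, advocacy,
#'   n, share_pct, before_n, before_pct, after_n, after_pct, delta_pct`.
#' @export
advocacy_crosstab <- function(classified, window = event_window()) {
  stopifnot(is.data.frame(classified), inherits(window, "qp_window"))
  recs <- classified |>
    dplyr::mutate(side = assign_window(.data$day, window)) |>
    dplyr::filter(!is.na(.data$advocacy), !is.na(.data$category),
                  .data$side != "excluded")
  body <- recs |>
    dplyr::count(group = .data$category, advocacy = .data$advocacy, .data$side) |>
    tidyr::pivot_wider(names_from = "side", values_from = "n", values_fill = 0L)
  for (col in c("before", "after")) if (!col %in% names(body)) body[[col]] <- 0L
  body <- body |> dplyr::rename(before_n = "before", after_n = "after")
  totals <- body |>
    dplyr::summarise(before_n = sum(.data$before_n), after_n = sum(.data$after_n),
                     .by = "group") |>
    dplyr::mutate(advocacy = "total")
  out <- dplyr::bind_rows(body, totals) |>
    dplyr::mutate(n = .data$before_n + .data$after_n) |>
    dplyr::mutate(
      share_pct = category_share(.data$n, .data$n[.data$advocacy == "total"]),
      .by = "group"
    ) |>
    dplyr::mutate(
      before_pct = category_share(.data$before_n, .data$n),
      after_pct = category_share(.data$after_n, .data$n),
      delta_pct = delta_percent(.data$before_n, .data$after_n)
    ) |>
    dplyr::arrange(.data$group, .data$advocacy == "total", .data$advocacy)
  out <- out[, c("group", "advocacy", "n", "share_pct", "before_n", "before_pct",
                 "after_n", "after_pct", "delta_pct")]
  structure(out, window = window, class = c("qp_advocacy", class(out)))
}

#' Advocacy table from published shares
#'
#' Reconstructs an advocacy cross-tabulation from the form in which such
#' tables are published: per row a total count `n` and a before-period
#' percent. Integer counts are reconstructed as `before_n =
#' round(n * before_pct / 100)` (half away from zero) and `after_n = n -
#' before_n`, and the percent change is computed from those integers.
#' Because the printed percent carries only two decimals, rows with large
#' `n` can lose the true integer count and the reconstructed change may
#' differ from the published one in the second decimal.
#'
#' @param shares Data frame with columns `group`, `advocacy`, `n`,
#'   `before_pct`.
#' @return A tibble of class `qp_advocacy` (share_pct computed against each
#'   group's `total` row when present).
#' @export
advocacy_from_shares <- function(shares) {
  stopifnot(is.data.frame(shares),
            all(c("group", "advocacy", "n", "before_pct") %in% names(shares)))
  out <- as_tibble(shares) |>
    dplyr::mutate(
      before_n = round_half_up(.data$n * .data$before_pct / 100, 0),
      after_n = .data$n - .data$before_n,
      after_pct = 100 - .data$before_pct,
      delta_pct = delta_percent(.data$before_n, .data$after_n)
    ) |>
    dplyr::mutate(
      share_pct = if (any(.data$advocacy == "total")) {
        category_share(.data$n, .data$n[.data$advocacy == "total"])
      } else NA_real_,
      .by = "group"
    )
  out <- out[, c("group", "advocacy", "n", "share_pct", "before_n", "before_pct",
                 "after_n", "after_pct", "delta_pct")]
  structure(out, class = c("qp_advocacy", class(out)))
}

#' Contrast a target cross-tabulation against the control
#'
#' Descriptive counterfactual comparison: for each class of the target
#' table (and the total row), reports the target's percent change minus
#' the control's for the matching class. Classes missing from the control
#' table fall back to the control's total-row change, with a warning. A
#' change is flagged event-attributable when the target change exceeds the
#' control change.
#'
#' @param target,control `qp_crosstab` objects (see [build_crosstab()]).
#' @param warn Warn when target classes are missing from the control table
#'   (set `FALSE` for batch runs where the fallback is expected).
#' @return A tibble of class `qp_contrast`: `class_label, target_delta_pct,
#'   control_delta_pct, contrast_points, event_attributable`.
#' @export
control_contrast <- function(target, control, warn = TRUE) {
  stopifnot(inherits(target, "qp_crosstab"), inherits(control, "qp_crosstab"))
  ctl <- setNames(control$delta_pct, control$class_label)
  ctl_total <- unname(ctl["total"])
  matched <- target$class_label %in% names(ctl)
  if (any(!matched) && warn) {
    rlang::warn(paste0(
      "classes absent from control contrasted against its total row: ",
      paste(target$class_label[!matched], collapse = ", ")))
  }
  out <- tibble(
    class_label = target$class_label,
    target_delta_pct = target$delta_pct,
    control_delta_pct = dplyr::if_else(matched, unname(ctl[target$class_label]),
                                       ctl_total)
  ) |>
    dplyr::mutate(
      contrast_points = round_half_up(.data$target_delta_pct - .data$control_delta_pct, 2),
      event_attributable = .data$target_delta_pct > .data$control_delta_pct
    )
  structure(out,
            target_group = attr(target, "group"),
            control_group = attr(control, "group"),
            class = c("qp_contrast", class(out)))
}
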