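#' Tidy a cross-tabulation
#'
#' Returns the class rows of a [build_crosstab()] result (total row
#' dropped) as a plain tibble with the table's query category attached.
#'
#' @param x A `qp_crosstab`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy qp_crosstab
#' @export
tidy.qp_crosstab <- function(x, ...) {
  out <- as_tibble(x)[x$class_label != "total", ]
  dplyr::mutate(out, group = attr(x, "group") %||% NA_character_, .before = 1)
}

#' One-row summary of a cross-tabulation
#'
#' @param x A `qp_crosstab`.
#' @param ... Unused.
#' @return A one-row tibble: group, total counts and percent change.
#' @method glance qp_crosstab
#' @export
glance.qp_crosstab <- function(x, ...) {
  tot <- as_tibble(x)[x$class_label == "total", ]
  tibble(
    group = attr(x, "group") %||% NA_character_,
    n = tot$n, before_n = tot$before_n, after_n = tot$after_n,
    delta_pct = tot$delta_pct,
    n_classes = sum(x$class_label != "total")
  )
}

#' @rdname tidy.qp_crosstab
#' @method tidy qp_advocacy
#' @export
tidy.qp_advocacy <- function(x, ...) as_tibble(x)[x$advocacy != "total", ]

#' @rdname tidy.qp_crosstab
#' @method tidy qp_contrast
#' @export
tidy.qp_contrast <- function(x, ...) as_tibble(x)

#' Plot a cross-tabulation's percent changes
#'
#' Horizontal bar chart of the before-to-after percent change per class,
#' total row highlighted.
#'
#' @param object A `qp_crosstab`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qp_crosstab
#' @export
autoplot.qp_crosstab <- function(object, ...) {
  df <- as_tibble(object)
  df$class_label <- factor(df$class_label, levels = rev(df$class_label))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$delta_pct, y = .data$class_label,
    fill = .data$class_label == "total")) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "change after vs before (%)", y = NULL,
                  title = attr(object, "group")) +
    ggplot2::theme_minimal()
}

#' Plot daily trend series
#'
#' One line per group with the event day marked; the canonical view of
#' before/after dynamics (event step, decay back to baseline, pre-event
#' spikes).
#'
#' @param object A `qp_trend` from [daily_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qp_trend
#' @export
autoplot.qp_trend <- function(object, ...) {
  window <- trend_window(object)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$day, y = .data$n, colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = window$event_day, linetype = 2) +
    ggplot2::labs(x = "day relative to event", y = "records/day",
                  colour = attr(object, "group_by")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.qp_trend
#' @param series A `qp_trend`.
#' @export
plot_trend <- function(series, ...) autoplot.qp_trend(series, ...)
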