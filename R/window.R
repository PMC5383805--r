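#' Define a before/after event window
#'
#' Paired half-open windows flanking an event: before covers days
#' `event_day - W` to `event_day - 1`, after covers `event_day` to
#' `event_day + W - 1`. The event day itself belongs to the after window,
#' so both windows are contiguous, disjoint, and of equal length `W`.
#'
#' @param event_day Integer day index of the event (default 0).
#' @param window_days Window half-length `W >= 1` (default 14).
#' @return An object of class `qp_window`.
#' @export
event_window <- function(event_day = 0, window_days = 14) {
  if (window_days < 1) qp_config_abort("`window_days` must be >= 1")
  structure(
    list(event_day = as.integer(event_day),
         window_days = as.integer(window_days)),
    class = "qp_window"
  )
}

#' @export
print.qp_window <- function(x, ...) {
  cat(sprintf("<qp_window> before [%d, %d] / after [%d, %d]\n",
              x$event_day - x$window_days, x$event_day - 1L,
              x$event_day, x$event_day + x$window_days - 1L))
  invisible(x)
}

#' Assign days to the before/after window
#'
#' @param day Integer vector of day offsets.
#' @param window A [event_window()].
#' @return Character vector over `"before"`, `"after"`, `"excluded"`.
#' @examples
#' assign_window(c(-15, -1, 0, 13, 14), event_window())
#' @export
assign_window <- function(day, window = event_window()) {
  stopifnot(inherits(window, "qp_window"))
  rel <- day - window$event_day
  dplyr::case_when(
    rel >= -window$window_days & rel < 0 ~ "before",
    rel >= 0 & rel < window$window_days ~ "after",
    .default = "excluded"
  )
}
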