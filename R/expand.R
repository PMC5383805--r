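#' Expand a seed query set by correlated daily behaviour
#'
#' Emulates recursive related-query discovery over a search log: each
#' distinct query gets a daily count series (zero-filled over the log's day
#' range); starting from the seeds, every frontier query contributes its
#' `k` most correlated other queries (Pearson correlation of daily series,
#' ties broken lexicographically) whose correlation is at least `rho_min`;
#' the frontier is iterated to a fixpoint. The result is the closure
#' including the seeds and is fully deterministic.
#'
#' Constant daily series have undefined Pearson correlation; it is defined
#' as 0 here so flat queries never expand anything.
#'
#' @param seeds Character vector of seed query strings.
#' @param log A search-log data frame with columns `day` and `query`.
#' @param k Number of top-correlated queries taken per frontier query.
#' @param rho_min Minimum Pearson correlation for inclusion, in `[-1, 1]`
#'   (values above 1 simply yield no expansion).
#' @return Character vector: the closure of `seeds`, sorted.
#' @export
expand_related_queries <- function(seeds, log, k = 10, rho_min = 0.8) {
  stopifnot(is.data.frame(log), all(c("day", "query") %in% names(log)))
  if (nrow(log) == 0) qp_config_abort("`log` must contain at least one record")
  if (k < 1) qp_config_abort("`k` must be >= 1")
  seeds <- unique(as.character(seeds))

  days <- seq(min(log$day), max(log$day))
  counts <- log |>
    dplyr::count(.data$query, .data$day) |>
    tidyr::complete(query = unique(log$query), day = days, fill = list(n = 0L)) |>
    dplyr::arrange(.data$query, .data$day)
  queries <- sort(unique(counts$query))
  mat <- matrix(counts$n, nrow = length(days),
                dimnames = list(NULL, queries))

  missing <- setdiff(seeds, queries)
  if (length(missing)) {
    rlang::warn(paste0("seed queries absent from log ignored for expansion: ",
                       paste(missing, collapse = ", ")))
  }

  if (length(queries) < 2) return(sort(seeds))
  suppressWarnings(rho <- cor(mat))
  rho[!is.finite(rho)] <- 0 # constant series: correlation defined as 0

  top_related <- function(q) {
    r <- rho[q, setdiff(queries, q)]
    ord <- order(-r, names(r)) # ties broken lexicographically
    cand <- names(r)[ord][seq_len(min(k, length(r)))]
    cand[r[cand] >= rho_min]
  }

  closure <- seeds
  frontier <- intersect(seeds, queries)
  while (length(frontier)) {
    found <- unique(unlist(purrr::map(frontier, top_related)))
    new <- setdiff(found, closure)
    closure <- c(closure, new)
    frontier <- new
  }
  sort(closure)
}
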