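#' Reference before/after cross-tabulation counts
#'
#' Published per-class before/after counts from a large-scale study of
#' firearm-related search behaviour around the December 2012 Sandy Hook
#' school shooting (14-day windows either side of the event), keyed in at
#' full printed count precision: per query category the top (content, TLD)
#' classes plus the category totals. Useful for exercising the table
#' arithmetic against known published percentages.
#'
#' @return A tibble `group, class_label, before_n, after_n, is_total`.
#' @seealso [crosstab_from_counts()]
#' @export
reference_crosstab_counts <- function() {
  readr::read_csv(extdata("reference_crosstab_counts.csv"),
                  col_types = readr::cols(
                    group = readr::col_character(),
                    class_label = readr::col_character(),
                    before_n = readr::col_double(),
                    after_n = readr::col_double(),
                    is_total = readr::col_logical()))
}

#' Reference advocacy-view shares
#'
#' Published advocacy tables from the same study, in their printed form:
#' per query category and advocacy view the total count and the
#' before-period percent (the underlying integer counts were not printed).
#'
#' @return A tibble `group, advocacy, n, before_pct`.
#' @seealso [advocacy_from_shares()]
#' @export
reference_advocacy_shares <- function() {
  readr::read_csv(extdata("reference_advocacy_shares.csv"),
                  col_types = readr::cols(
                    group = readr::col_character(),
                    advocacy = readr::col_character(),
                    n = readr::col_double(),
                    before_pct = readr::col_double()))
}

#' Reference marginal distributions
#'
#' Published marginal counts from the same study: query-category volumes,
#' top-level-domain, content-category and advocacy distributions, with the
#' grand totals they are shares of.
#'
#' @return A tibble `table, level, n, total_n`.
#' @seealso [category_share()]
#' @export
reference_category_totals <- function() {
  readr::read_csv(extdata("reference_category_totals.csv"),
                  col_types = readr::cols(
                    table = readr::col_character(),
                    level = readr::col_character(),
                    n = readr::col_double(),
                    total_n = readr::col_double()))
}
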