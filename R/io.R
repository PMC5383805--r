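#' Read a search log from JSONL or CSV
#'
#' One record per search event with fields `day` (integer offset from the
#' event), `query` (raw text) and `clicked_url`. JSONL holds one JSON
#' object per line; CSV the same three columns. Format is chosen by file
#' extension.
#'
#' @param path Path to a `.jsonl`/`.ndjson` or `.csv` file.
#' @return A tibble `day, query, clicked_url`.
#' @export
read_search_log <- function(path) {
  if (!file.exists(path)) qp_config_abort(paste0("log file not found: ", path))
  df <- if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::stream_in(file(path), verbose = FALSE))
  } else {
    readr::read_csv(path, col_types = readr::cols(
      day = readr::col_integer(),
      query = readr::col_character(),
      clicked_url = readr::col_character()))
  }
  if (!all(c("day", "query", "clicked_url") %in% names(df))) {
    qp_config_abort("log needs fields day, query, clicked_url")
  }
  df$day <- as.integer(df$day)
  df[c("day", "query", "clicked_url")]
}

#' Write a search log as JSONL or CSV
#'
#' @param log A tibble `day, query, clicked_url`.
#' @param path Output path; `.jsonl`/`.ndjson` writes one JSON object per
#'   line, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_search_log <- function(log, path) {
  stopifnot(is.data.frame(log),
            all(c("day", "query", "clicked_url") %in% names(log)))
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(log), con, verbose = FALSE)
  } else {
    readr::write_csv(log, path)
  }
  invisible(path)
}
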