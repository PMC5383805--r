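CONTENT_LEVELS <- c("retail", "news", "educational", "showbiz", "other")
ADVOCACY_LEVELS <- c("gun_rights", "gun_control")
TLD_LEVELS <- c("commercial", "noncommercial", "government",
                "educational_institution", "other")

#' Build a domain registry
#'
#' The registry maps registrable domains to a manually assigned content
#' category (retail, news, educational, showbiz, other) and optionally to an
#' advocacy view (gun_rights or gun_control). Domains absent from the
#' registry classify as content "other" and advocacy none, mirroring
#' manual categorisation workflows where low-frequency domains stay
#' uncategorised.
#'
#' @param domains Data frame with columns `domain`, `content_category` and
#'   optionally `advocacy` (`NA` for none). Domains must be unique,
#'   lowercase registrable domains without scheme or path.
#' @return A tibble of class `qp_registry`.
#' @seealso [default_registry()], [read_registry()]
#' @export
domain_registry <- function(domains) {
  stopifnot(is.data.frame(domains))
  if (!all(c("domain", "content_category") %in% names(domains))) {
    qp_config_abort("registry needs `domain` and `content_category` columns")
  }
  out <- as_tibble(domains)
  out$domain <- stringr::str_to_lower(stringr::str_trim(out$domain))
  if (anyDuplicated(out$domain)) {
    dup <- unique(out$domain[duplicated(out$domain)])
    qp_config_abort(paste0("registry lists domains more than once: ",
                           paste(dup, collapse = ", ")))
  }
  if (any(stringr::str_detect(out$domain, "[/:]"))) {
    qp_config_abort("registry domains must not contain a scheme, port or path")
  }
  bad <- setdiff(unique(out$content_category), CONTENT_LEVELS)
  if (length(bad)) {
    qp_config_abort(paste0("unknown content categories: ", paste(bad, collapse = ", ")))
  }
  if (!"advocacy" %in% names(out)) out$advocacy <- NA_character_
  out$advocacy[out$advocacy %in% c("", "none")] <- NA_character_
  bad <- setdiff(unique(out$advocacy[!is.na(out$advocacy)]), ADVOCACY_LEVELS)
  if (length(bad)) {
    qp_config_abort(paste0("unknown advocacy views: ", paste(bad, collapse = ", ")))
  }
  out <- out[c("domain", "content_category", "advocacy")]
  class(out) <- c("qp_registry", class(out))
  out
}

#' Bundled synthetic domain registry
#'
#' A small illustrative registry of invented domains covering every content
#' category, the advocacy views, and each top-level-domain class. It is a
#' synthetic stand-in (the original study's manual registry and advocacy
#' affiliate lists were never published) intended for examples, tests and
#' the synthetic-log generator; replace it with your own registry for real
#' analyses.
#'
#' @return A `qp_registry`.
#' @export
default_registry <- function() {
  read_registry(extdata("registry_synthetic.csv"))
}

#' Read a domain registry from CSV or YAML
#'
#' CSV needs columns `domain, content_category[, advocacy]`; YAML a list of
#' records with the same fields.
#'
#' @param path File path; format chosen by extension (`.csv` / `.yaml` / `.yml`).
#' @return A `qp_registry`.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) qp_config_abort(paste0("registry file not found: ", path))
  df <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    purrr::map_dfr(yaml::read_yaml(path), as_tibble)
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  }
  domain_registry(df)
}
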