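#' Build a keyword taxonomy
#'
#' A keyword taxonomy is an ordered mapping from category names to keyword
#' lists, plus a priority order used to resolve queries that match keywords
#' from more than one category (each query is assigned to exactly one
#' category, the highest-priority match).
#'
#' Matching semantics (see [classify_query()]): a single-word keyword matches
#' when it is a prefix of some whitespace token of the normalized query
#' ("gun" matches "guns" and "gunsmith" but not "handgun" across tokens);
#' a multi-word keyword matches as a contiguous substring of the normalized
#' query. Token-prefix rather than raw substring matching avoids false
#' positives such as "ammo" inside "mammogram".
#'
#' @param categories Named list of character keyword vectors. Keywords must
#'   be nonempty; they are normalized (lowercased, trimmed) on construction.
#' @param priority Character vector, a permutation of `names(categories)`,
#'   highest priority first. Defaults to the order of `categories`.
#' @return An object of class `qp_taxonomy`.
#' @seealso [default_taxonomy()], [classify_query()], [read_taxonomy()]
#' @export
keyword_taxonomy <- function(categories, priority = names(categories)) {
  if (!is.list(categories) || length(categories) == 0 ||
      is.null(names(categories)) || any(!nzchar(names(categories)))) {
    qp_config_abort("`categories` must be a nonempty named list of keyword vectors")
  }
  if (anyDuplicated(names(categories))) {
    qp_config_abort("taxonomy category names must be unique")
  }
  categories <- purrr::map(categories, function(kw) {
    kw <- normalize_query(as.character(kw))
    if (length(kw) == 0 || any(!nzchar(kw))) {
      qp_config_abort("every category needs at least one nonempty keyword")
    }
    unique(kw)
  })
  priority <- as.character(priority)
  if (!setequal(priority, names(categories)) ||
      length(priority) != length(categories)) {
    qp_config_abort("`priority` must be a permutation of the category names")
  }
  structure(
    list(categories = categories, priority = priority),
    class = "qp_taxonomy"
  )
}

#' @export
print.qp_taxonomy <- function(x, ...) {
  cat("<qp_taxonomy> ", length(x$categories), " categories\n", sep = "")
  for (nm in x$priority) {
    cat("  ", nm, ": ", paste(x$categories[[nm]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Default firearm-search taxonomy
#'
#' The keyword categories used throughout the package for firearm-related
#' query surveillance: gun type (gun, firearm, handgun, rifle, pistol,
#' revolver, shotgun), ammunition (ammunition, ammo, bullets), law related
#' (brady act, second amendment), shooting, and an event-agnostic control
#' topic (bicycle and synonyms) used as the seasonal counterfactual.
#'
#' Multi-category queries resolve most-specific-first:
#' law_related > shooting > ammunition > gun_type > control.
#'
#' @return A `qp_taxonomy`.
#' @export
default_taxonomy <- function() {
  keyword_taxonomy(
    categories = list(
      gun_type    = c("gun", "firearm", "handgun", "rifle", "pistol",
                      "revolver", "shotgun"),
      ammunition  = c("ammunition", "ammo", "bullets"),
      law_related = c("brady act", "second amendment"),
      shooting    = "shooting",
      control     = c("bicycle", "bike", "cycling")
    ),
    priority = c("law_related", "shooting", "ammunition", "gun_type", "control")
  )
}

#' Read a taxonomy from a YAML file
#'
#' Expected layout: a `categories` mapping of name to keyword list and an
#' optional `priority` list (defaults to the category order in the file).
#'
#' @param path Path to a YAML file.
#' @return A `qp_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) qp_config_abort(paste0("taxonomy file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$categories)) qp_config_abort("taxonomy YAML needs a `categories` mapping")
  keyword_taxonomy(raw$categories, priority = raw$priority %||% names(raw$categories))
}

category_pattern <- function(keywords) {
  single <- keywords[!stringr::str_detect(keywords, stringr::fixed(" "))]
  multi <- setdiff(keywords, single)
  parts <- character(0)
  if (length(single)) {
    # keyword must start a whitespace token (prefix match within the token)
    parts <- c(parts, paste0(
      "(?:^|\\s)(?:", paste(stringr::str_escape(single), collapse = "|"), ")"
    ))
  }
  if (length(multi)) {
    # phrases match as contiguous substrings of the normalized query
    parts <- c(parts, paste(stringr::str_escape(multi), collapse = "|"))
  }
  paste(parts, collapse = "|")
}

#' Classify queries into taxonomy categories
#'
#' Vectorised classification of raw query strings. Queries are normalized
#' with [normalize_query()] first, so classification is invariant under
#' normalization. A query matching keywords from several categories is
#' assigned to the highest-priority one; a query matching none gets `NA`
#' (classification never errors on query content).
#'
#' @param query Character vector of raw queries.
#' @param taxonomy A `qp_taxonomy`; defaults to [default_taxonomy()].
#' @return Character vector of category names (`NA` where unclassified).
#' @examples
#' classify_query(c("remington shotgun for sale", "cheap ammo online", "weather"))
#' @export
classify_query <- function(query, taxonomy = default_taxonomy()) {
  stopifnot(inherits(taxonomy, "qp_taxonomy"))
  nq <- normalize_query(query)
  out <- rep(NA_character_, length(nq))
  # classify distinct strings once, then fan back out
  uq <- unique(nq)
  res <- rep(NA_character_, length(uq))
  for (nm in taxonomy$priority) {
    pat <- category_pattern(taxonomy$categories[[nm]])
    hit <- is.na(res) & stringr::str_detect(uq, pat)
    res[hit] <- nm
  }
  out <- res[match(nq, uq)]
  out
}
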