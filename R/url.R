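# Public-suffix snapshot is loaded once per session from the bundled
# rule table; live suffix lists drift, so a frozen fixture keeps
# classification hermetic and reproducible.
the <- new.env(parent = emptyenv())

public_suffixes <- function() {
  if (is.null(the$psl)) {
    lines <- readr::read_lines(extdata("public_suffixes.txt"))
    lines <- stringr::str_trim(lines)
    the$psl <- lines[nzchar(lines) & !stringr::str_starts(lines, "#")]
  }
  the$psl
}

url_host <- function(url) {
  h <- stringr::str_to_lower(stringr::str_trim(url))
  h <- stringr::str_remove(h, "^[a-z][a-z0-9+.-]*://") # scheme
  h <- stringr::str_remove(h, "^[^/?#@]*@")            # userinfo
  h <- stringr::str_remove(h, "[/?#].*$")              # path/query/fragment
  h <- stringr::str_remove(h, ":[0-9]*$")              # port
  h
}

#' Extract the registrable domain from a clicked URL
#'
#' Returns the registrable domain — one label plus the public suffix — with
#' any subdomains stripped and multi-part suffixes (co.uk, state.us)
#' preserved, e.g. `http://en.wikipedia.org/wiki/Foo` resolves to
#' `wikipedia.org`. Suffixes come from a frozen rule-table snapshot
#' bundled with the package; hosts matching no rule fall back to their
#' last two labels. Unresolvable URLs (empty host, no dot, IP literals,
#' bare public suffixes) yield `NA` rather than an error, so a single bad
#' record never aborts a run.
#'
#' @param url Character vector of absolute URLs.
#' @return Character vector of registrable domains (`NA` where unparseable).
#' @examples
#' extract_domain("http://en.wikipedia.org/wiki/Second_Amendment")
#' extract_domain("https://shop.example.com/ammo?id=1")
#' @export
extract_domain <- function(url) {
  if (length(url) == 0) return(character(0))
  host <- url_host(as.character(url))
  uh <- unique(host)
  res <- purrr::map_chr(uh, registrable_one)
  res[match(host, uh)]
}

registrable_one <- function(host) {
  if (is.na(host) || !nzchar(host)) return(NA_character_)
  if (!stringr::str_detect(host, "^[a-z0-9.-]+$")) return(NA_character_)
  if (stringr::str_detect(host, "^[0-9.]+$")) return(NA_character_) # IPv4 literal
  labels <- stringr::str_split_1(host, stringr::fixed("."))
  if (length(labels) < 2 || any(!nzchar(labels))) return(NA_character_)
  psl <- public_suffixes()
  # longest matching suffix rule wins; registrable = one label + suffix
  for (i in seq_along(labels)[-1]) {
    suffix <- paste(labels[i:length(labels)], collapse = ".")
    if (suffix %in% psl) {
      return(paste(labels[(i - 1):length(labels)], collapse = "."))
    }
  }
  if (paste(labels, collapse = ".") %in% psl) return(NA_character_) # bare suffix
  paste(utils::tail(labels, 2), collapse = ".") # default rule: last two labels
}

#' Categorise a domain by its top-level domain
#'
#' Ordered rules, first match wins: any domain under `.state.us` is
#' government (this outranks the `.us` country-code rule), `.gov` and
#' `.mil` are government, `.com` commercial, `.org` noncommercial, `.edu`
#' an educational institution; everything else (country-specific, `.pro`,
#' `.tv`, ...) is other.
#'
#' @param domain Character vector of registrable domains.
#' @return Character vector over `commercial`, `noncommercial`,
#'   `government`, `educational_institution`, `other` (`NA` in, `NA` out).
#' @examples
#' tld_category(c("wikipedia.org", "ct.state.us", "example.co.uk"))
#' @export
tld_category <- function(domain) {
  last <- stringr::str_extract(domain, "[^.]+$")
  dplyr::case_when(
    is.na(domain) ~ NA_character_,
    stringr::str_ends(domain, stringr::fixed(".state.us")) ~ "government",
    last %in% c("gov", "mil") ~ "government",
    last == "com" ~ "commercial",
    last == "org" ~ "noncommercial",
    last == "edu" ~ "educational_institution",
    .default = "other"
  )
}

#' Look up a domain's content category
#'
#' Exact-domain lookup in the registry; domains not listed are `"other"`
#' (uncategorised), matching manual-registry workflows where rare domains
#' are left unclassified.
#'
#' @param domain Character vector of registrable domains.
#' @param registry A `qp_registry`.
#' @return Character vector over retail, news, educational, showbiz, other.
#' @export
content_category <- function(domain, registry = default_registry()) {
  stopifnot(inherits(registry, "qp_registry"))
  out <- registry$content_category[match(domain, registry$domain)]
  out[is.na(out) & !is.na(domain)] <- "other"
  out
}

#' Look up a domain's advocacy view
#'
#' @param domain Character vector of registrable domains.
#' @param registry A `qp_registry`.
#' @return `"gun_rights"`, `"gun_control"`, or `NA` (no advocacy stance).
#' @export
advocacy_view <- function(domain, registry = default_registry()) {
  stopifnot(inherits(registry, "qp_registry"))
  registry$advocacy[match(domain, registry$domain)]
}

#' Combined (content, TLD) class label
#'
#' Joins the content and TLD categories into the class descriptor used in
#' the cross-tabulations, e.g. retail content on a commercial domain is
#' `"retail content, .com"` and an unregistered domain under a country
#' suffix is `"other content, .other"`.
#'
#' @param content Character vector of content categories.
#' @param tld Character vector of TLD categories.
#' @return Character vector of class labels.
#' @examples
#' class_label("retail", "commercial")
#' @export
class_label <- function(content, tld) {
  suffix <- c(commercial = ".com", noncommercial = ".org",
              government = ".gov", educational_institution = ".edu",
              other = ".other")[tld]
  dplyr::if_else(is.na(content) | is.na(tld), NA_character_,
                 paste0(content, " content, ", suffix))
}

#' Classify a full search log
#'
#' Runs query and URL classification over a raw log: assigns each record a
#' taxonomy category, registrable domain, TLD category, content category,
#' advocacy view, and the combined class label. Records whose query matches
#' no category keep `NA` in `category`; unparseable URLs keep `NA` domain
#' and are flagged in `url_error`. Both tallies surface in the pipeline
#' manifest rather than aborting the run.
#'
#' @param log Data frame with columns `day`, `query`, `clicked_url`.
#' @param taxonomy A `qp_taxonomy`.
#' @param registry A `qp_registry`.
#' @return A tibble: `day, query, category, domain, tld_category,
#'   content_category, advocacy, class_label, url_error`.
#' @export
classify_log <- function(log, taxonomy = default_taxonomy(),
                         registry = default_registry()) {
  stopifnot(is.data.frame(log),
            all(c("day", "query", "clicked_url") %in% names(log)))
  domain <- extract_domain(log$clicked_url)
  content <- content_category(domain, registry)
  tld <- tld_category(domain)
  tibble(
    day = as.integer(log$day),
    query = log$query,
    category = classify_query(log$query, taxonomy),
    domain = domain,
    tld_category = tld,
    content_category = content,
    advocacy = advocacy_view(domain, registry),
    class_label = class_label(content, tld),
    url_error = is.na(domain)
  )
}
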