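#' Normalize a raw search query
#'
#' Canonicalises query text before keyword matching: Unicode NFKC folding,
#' lower-casing, punctuation mapped to spaces, and whitespace collapsed.
#' The transform is idempotent, so classification is invariant under
#' repeated normalization.
#'
#' @param query Character vector of raw query strings (may be empty strings).
#' @return Character vector of normalized queries, same length as `query`.
#' @examples
#' normalize_query("Second  Amendment!")
#' normalize_query("AMMO   prices")
#' @export
normalize_query <- function(query) {
  if (length(query) == 0) return(character(0))
  out <- stringi::stri_trans_nfkc(as.character(query))
  out <- stringr::str_to_lower(out)
  out <- stringr::str_replace_all(out, "[^[:alnum:][:space:]]+", " ")
  out <- stringr::str_squish(out)
  out
}
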