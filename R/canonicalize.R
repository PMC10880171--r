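#' Canonicalize term text
#'
#' Every string entering the pipeline -- dictionary terms, query surfaces, and
#' translation variants -- passes through one canonical form so that the
#' string and semantic channels always see identical text. The canonical form
#' is: Unicode NFKC normalization, lower-casing, collapsing any whitespace run
#' to a single ASCII space, and stripping leading/trailing whitespace.
#'
#' The map is idempotent: `canonicalize(canonicalize(x))` equals
#' `canonicalize(x)`. Empty input maps to the empty string; callers that
#' require non-empty terms reject empties themselves.
#'
#' @param text character vector (any unicode strings).
#' @return character vector of the same length, canonicalized.
#' @examples
#' canonicalize("  Double   Renal Pelvis ")
#' @export
canonicalize <- function(text) {
  if (length(text) == 0L) {
    return(character(0))
  }
  out <- stringi::stri_trans_nfkc(as.character(text))
  out <- stringi::stri_trans_tolower(out)
  out <- stringi::stri_replace_all_regex(out, "\\s+", " ")
  stringi::stri_trim_both(out)
}
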