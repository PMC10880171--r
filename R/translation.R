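#' Translation provider contract
#'
#' The translation step of the pipeline is modeled as a provider contract:
#' a provider has a `name` and a `translate` function mapping one source text
#' to an ordered character vector of candidate translations (possibly empty).
#' Live web engines (Baidu Fanyi, Youdao, Tencent Translator and kin) are
#' represented only by this contract; the package ships a deterministic
#' table-driven mock so that the whole pipeline is testable offline.
#'
#' @param name provider name (used in error messages and variant tags).
#' @param translate_fun function(text) -> character vector of translations.
#' @return an object of class `translation_provider`.
#' @seealso [mock_translation_provider()], [unify_translations()]
#' @export
translation_provider <- function(name, translate_fun) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.function(translate_fun))
  structure(
    list(name = name, translate = translate_fun),
    class = "translation_provider"
  )
}

#' Table-driven mock translation provider
#'
#' Deterministic provider backed by a lookup table: source term to an ordered
#' list of translations. The table is either a data frame with columns
#' `source` and `translation` (several rows per source allowed, order kept)
#' or a path to a 2-column TSV of the same layout. Both sides are
#' canonicalized; a source absent from the table translates to an empty
#' vector.
#'
#' @param name provider name.
#' @param table data frame or TSV file path.
#' @return a [translation_provider()].
#' @export
mock_translation_provider <- function(name, table) {
  if (is.character(table) && length(table) == 1L) {
    if (!file.exists(table)) {
      stop("mock provider table not found: ", table, call. = FALSE)
    }
    lines <- readLines(table, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 2L)
    if (length(bad) > 0L) {
      stop("malformed mock provider row ", bad[1], " in ", table, call. = FALSE)
    }
    table <- data.frame(
      source = vapply(fields, `[[`, character(1), 1L),
      translation = vapply(fields, `[[`, character(1), 2L),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(table), all(c("source", "translation") %in% names(table)))
  src <- canonicalize(table$source)
  tgt <- canonicalize(table$translation)
  lut <- split(tgt, factor(src, levels = unique(src)))
  translation_provider(name, function(text) {
    out <- lut[[canonicalize(text)]]
    if (is.null(out)) character(0) else unname(out)
  })
}

#' Translate one term through a provider
#'
#' Calls the provider and canonicalizes its output. An empty result is legal
#' (the provider has no translation for the term). A failure inside the
#' provider is re-signaled as a condition of class `translation_error`
#' carrying the provider name, so callers can continue with the remaining
#' providers.
#'
#' @param provider a [translation_provider()].
#' @param text non-empty source text.
#' @return character vector of canonicalized candidate translations.
#' @export
translate <- function(provider, text) {
  stopifnot(inherits(provider, "translation_provider"))
  if (length(text) != 1L || is.na(text) || !nzchar(canonicalize(text))) {
    stop("text must be a single non-empty string", call. = FALSE)
  }
  out <- tryCatch(
    provider$translate(text),
    error = function(e) {
      stop(structure(
        class = c("translation_error", "error", "condition"),
        list(
          message = paste0(
            "translation provider '", provider$name, "' failed: ",
            conditionMessage(e)
          ),
          call = NULL, provider = provider$name
        )
      ))
    }
  )
  out <- canonicalize(as.character(out))
  out[nzchar(out)]
}

#' Unify translation variants from multiple providers
#'
#' Runs every provider on the same source text and unifies the outputs into
#' one variant set: the union of all canonicalized translations,
#' de-duplicated, each variant tagged with the set of providers that produced
#' it. Variant order is first-seen order over the fixed provider sequence, so
#' it is deterministic and usable for downstream tie-breaking. A provider
#' failure is downgraded to a warning and the union is taken over the
#' succeeding providers; if every provider fails, an error is raised.
#'
#' @param text non-empty source text.
#' @param providers non-empty list of [translation_provider()] objects, in a
#'   fixed order.
#' @return a tibble with columns `text` (unique canonical variants) and
#'   `providers` (list of character vectors of contributing provider names).
#' @export
unify_translations <- function(text, providers) {
  if (inherits(providers, "translation_provider")) providers <- list(providers)
  stopifnot(length(providers) >= 1L)
  variants <- character(0)
  tags <- list()
  n_failed <- 0L
  for (p in providers) {
    out <- tryCatch(translate(p, text), translation_error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      n_failed <<- n_failed + 1L
      NULL
    })
    if (is.null(out)) next
    for (v in out) {
      at <- match(v, variants)
      if (is.na(at)) {
        variants <- c(variants, v)
        tags[[length(variants)]] <- p$name
      } else {
        tags[[at]] <- unique(c(tags[[at]], p$name))
      }
    }
  }
  if (n_failed == length(providers)) {
    stop("all ", n_failed, " translation providers failed for input text",
      call. = FALSE
    )
  }
  tibble::tibble(text = variants, providers = tags)
}
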