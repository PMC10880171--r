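#' Build a query set
#'
#' A query is a surface term to be normalized, an optional language tag, a
#' possibly-empty set of gold concept ids (labels), and a possibly-empty set
#' of translation variants. Gold labels are sets because one term may
#' legitimately map to several concept ids; downstream a prediction counts as
#' correct when it hits any gold id.
#'
#' Surfaces and translation variants are canonicalized; variants are
#' de-duplicated preserving first-seen order. Query ids must be unique and
#' surfaces non-empty.
#'
#' @param query_id character vector of unique opaque ids.
#' @param surface character vector of surface terms (source language).
#' @param language character vector (recycled), default `"und"`.
#' @param gold_concept_ids list of character vectors (one per query), or
#'   `NULL` for unlabeled (inference-only) queries.
#' @param translations list of character vectors of translation variants,
#'   or `NULL`.
#' @return a tibble with columns `query_id`, `surface`, `language`,
#'   `gold_concept_ids` (list), `translations` (list).
#' @export
query_set <- function(query_id, surface, language = "und",
                      gold_concept_ids = NULL, translations = NULL) {
  n <- length(query_id)
  query_id <- as.character(query_id)
  if (anyDuplicated(query_id)) {
    stop(
      "duplicate query_id: ",
      paste(unique(query_id[duplicated(query_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  surface <- canonicalize(surface)
  empty <- !nzchar(surface) | is.na(surface)
  if (any(empty)) {
    stop("empty surface in query record(s): ",
      paste(query_id[empty], collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(gold_concept_ids)) gold_concept_ids <- rep(list(character(0)), n)
  if (is.null(translations)) translations <- rep(list(character(0)), n)
  stopifnot(length(gold_concept_ids) == n, length(translations) == n)
  translations <- lapply(translations, function(v) {
    if (length(v) == 0L) {
      return(character(0))
    }
    v <- canonicalize(v)
    unique(v[nzchar(v)])
  })
  gold_concept_ids <- lapply(gold_concept_ids, function(g) {
    unique(as.character(g[nzchar(as.character(g))]))
  })
  tibble::tibble(
    query_id = query_id,
    surface = surface,
    language = rep_len(as.character(language), n),
    gold_concept_ids = gold_concept_ids,
    translations = translations
  )
}

#' Read a query set from file
#'
#' Two formats:
#' * `"tsv"`: columns `query_id`, `surface`, and optionally a third column of
#'   semicolon-joined gold concept ids. Lines starting with `#` are skipped.
#' * `"jsonl"`: one JSON object per line with fields `query_id`, `surface`,
#'   and optionally `language`, `gold_concept_ids`, `translations`.
#'
#' @param path file path (UTF-8).
#' @param format `"tsv"` or `"jsonl"`.
#' @return a [query_set()] tibble.
#' @export
read_queries <- function(path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("query file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(query_set(character(0), character(0)))
  }
  if (format == "tsv") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 2L | nf > 3L)
    if (length(bad) > 0L) {
      stop("malformed query row at line ", lineno[bad[1]],
        ": expected 2-3 tab-delimited fields, got ", nf[bad[1]],
        call. = FALSE
      )
    }
    query_id <- vapply(fields, function(f) f[[1]], character(1))
    surface <- vapply(fields, function(f) f[[2]], character(1))
    gold <- lapply(fields, function(f) {
      if (length(f) >= 3L && nzchar(f[[3]])) {
        strsplit(f[[3]], ";", fixed = TRUE)[[1]]
      } else {
        character(0)
      }
    })
    query_set(query_id, surface, gold_concept_ids = gold)
  } else {
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(
        jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
        error = function(e) {
          stop("malformed JSON at line ", lineno[i], ": ",
            conditionMessage(e),
            call. = FALSE
          )
        }
      )
      if (is.null(rec$query_id) || is.null(rec$surface)) {
        stop("query record at line ", lineno[i],
          " lacks query_id or surface",
          call. = FALSE
        )
      }
      rec
    })
    pick <- function(field, default) {
      vapply(
        recs,
        function(r) if (is.null(r[[field]])) default else as.character(r[[field]])[1],
        character(1)
      )
    }
    query_set(
      query_id = pick("query_id", ""),
      surface = pick("surface", ""),
      language = pick("language", "und"),
      gold_concept_ids = lapply(recs, function(r) {
        as.character(r$gold_concept_ids %||% character(0))
      }),
      translations = lapply(recs, function(r) {
        as.character(r$translations %||% character(0))
      })
    )
  }
}

#' Write a query set as JSON lines
#'
#' One JSON object per query with the full field set; round-trips through
#' [read_queries()] with `format = "jsonl"`.
#'
#' @param queries a [query_set()] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_queries_jsonl <- function(queries, path) {
  lines <- vapply(seq_len(nrow(queries)), function(i) {
    jsonlite::toJSON(
      list(
        query_id = jsonlite::unbox(queries$query_id[i]),
        surface = jsonlite::unbox(queries$surface[i]),
        language = jsonlite::unbox(queries$language[i]),
        gold_concept_ids = queries$gold_concept_ids[[i]],
        translations = queries$translations[[i]]
      )
    )
  }, character(1))
  writeLines(lines, con = path, useBytes = FALSE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
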