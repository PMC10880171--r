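#' Build a term dictionary
#'
#' A `term_dictionary` is the reference vocabulary the pipeline ranks against:
#' an ordered collection of (concept id, term) entries plus lookup indexes.
#' One concept (for example a UMLS CUI) usually carries several synonymous
#' terms; one canonical term may belong to several concepts.
#'
#' Terms are canonicalized on construction (see [canonicalize()]). Entries
#' whose term or concept id is empty after canonicalization are skipped with a
#' logged count, and exact duplicate (concept id, term) pairs are collapsed to
#' the first occurrence. Iteration order is input order.
#'
#' @param entries data frame with columns `concept_id` and `term`, and
#'   optionally `language` (ISO 639-1 or `"und"`), `source`, and
#'   `semantic_group`.
#' @return an object of class `term_dictionary` with components `entries`
#'   (a tibble), `by_concept` and `by_term` (maps from id / canonical term to
#'   entry positions).
#' @examples
#' term_dictionary(data.frame(
#'   concept_id = c("C0021400", "C0021400"),
#'   term = c("Influenza", "Flu")
#' ))
#' @export
term_dictionary <- function(entries) {
  stopifnot(is.data.frame(entries))
  if (!all(c("concept_id", "term") %in% names(entries))) {
    stop("entries must have 'concept_id' and 'term' columns", call. = FALSE)
  }
  n <- nrow(entries)
  col <- function(name, default) {
    if (name %in% names(entries)) as.character(entries[[name]]) else rep(default, n)
  }
  df <- tibble::tibble(
    concept_id = as.character(entries$concept_id),
    term = canonicalize(as.character(entries$term)),
    language = col("language", "und"),
    source = col("source", ""),
    semantic_group = col("semantic_group", "")
  )
  bad <- is.na(df$term) | !nzchar(df$term) | is.na(df$concept_id) | !nzchar(df$concept_id)
  if (any(bad)) {
    message(sum(bad), " dictionary row(s) skipped (empty term or concept id after canonicalization)")
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(paste0(df$concept_id, "\x1f", df$term))
  df <- df[!dup, , drop = FALSE]
  idx <- seq_len(nrow(df))
  structure(
    list(
      entries = df,
      by_concept = split(idx, df$concept_id),
      by_term = split(idx, df$term)
    ),
    class = "term_dictionary"
  )
}

#' @export
length.term_dictionary <- function(x) nrow(x$entries)

#' @export
print.term_dictionary <- function(x, ...) {
  cat(
    "<term_dictionary> ", nrow(x$entries), " entries, ",
    length(x$by_concept), " concepts\n",
    sep = ""
  )
  print(utils::head(x$entries, 5))
  invisible(x)
}

#' Read a concept dictionary from file
#'
#' Supports two dialects:
#' * `"tsv"`: `concept_id TAB term` with optional extra columns
#'   `language`, `source`, `semantic_group`; lines starting with `#` are
#'   skipped.
#' * `"mrconso"`: MRCONSO.RRF-style pipe-delimited rows. Only the columns
#'   CUI (field 1), LAT (2), SAB (12), STR (15) and, when present, SUPPRESS
#'   (17) are consulted. Suppressed rows (flag `O` or `E`) are kept unless
#'   `keep_suppressed = FALSE`.
#'
#' @param path file path (UTF-8).
#' @param format `"tsv"` or `"mrconso"`.
#' @param semantic_group_filter optional character vector; only entries whose
#'   semantic group tag is in the set are kept (e.g. `"Disorders"` to restrict
#'   the candidate dictionary to the disorder semantic group).
#' @param semantic_groups optional named character vector mapping concept id
#'   to a semantic group tag (a sidecar for formats that do not carry one).
#' @param keep_suppressed keep MRCONSO rows flagged `O`/`E`? Default `TRUE`.
#' @return a [term_dictionary()].
#' @export
read_concept_dictionary <- function(path, format = c("tsv", "mrconso"),
                                    semantic_group_filter = NULL,
                                    semantic_groups = NULL,
                                    keep_suppressed = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("dictionary file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(term_dictionary(data.frame(concept_id = character(), term = character())))
  }
  if (format == "mrconso") {
    fields <- strsplit(lines, "|", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 15L)
    if (length(bad) > 0L) {
      stop(
        "malformed MRCONSO row at line ", lineno[bad[1]],
        ": expected >= 15 pipe-delimited fields, got ", nf[bad[1]],
        call. = FALSE
      )
    }
    pick <- function(k) vapply(fields, function(f) f[[k]], character(1))
    concept_id <- pick(1L)
    language <- pick(2L)
    source <- pick(12L)
    term <- pick(15L)
    suppress <- vapply(
      fields,
      function(f) if (length(f) >= 17L) f[[17L]] else "",
      character(1)
    )
    if (!keep_suppressed) {
      ok <- !(suppress %in% c("O", "E"))
      concept_id <- concept_id[ok]
      language <- language[ok]
      source <- source[ok]
      term <- term[ok]
    }
    semantic_group <- rep("", length(concept_id))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 2L | nf > 5L)
    if (length(bad) > 0L) {
      stop(
        "malformed TSV row at line ", lineno[bad[1]],
        ": expected 2-5 tab-delimited fields, got ", nf[bad[1]],
        call. = FALSE
      )
    }
    pick <- function(k, default) {
      vapply(
        fields,
        function(f) if (length(f) >= k) f[[k]] else default,
        character(1)
      )
    }
    concept_id <- pick(1L, "")
    term <- pick(2L, "")
    language <- pick(3L, "und")
    source <- pick(4L, "")
    semantic_group <- pick(5L, "")
  }
  if (!is.null(semantic_groups)) {
    looked <- unname(semantic_groups[concept_id])
    semantic_group <- ifelse(is.na(looked), semantic_group, looked)
  }
  df <- data.frame(
    concept_id = concept_id, term = term, language = language,
    source = source, semantic_group = semantic_group,
    stringsAsFactors = FALSE
  )
  if (!is.null(semantic_group_filter)) {
    df <- df[df$semantic_group %in% semantic_group_filter, , drop = FALSE]
  }
  term_dictionary(df)
}

#' Write a term dictionary as TSV
#'
#' Writes the 5-column TSV dialect understood by [read_concept_dictionary()]
#' (`concept_id`, `term`, `language`, `source`, `semantic_group`) preceded by
#' a commented header line. Re-reading the file yields an identical
#' dictionary (same entries in the same order).
#'
#' @param dictionary a [term_dictionary()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dictionary_tsv <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "term_dictionary"))
  e <- dictionary$entries
  body <- paste(e$concept_id, e$term, e$language, e$source, e$semantic_group,
    sep = "\t"
  )
  writeLines(
    c("# concept_id\tterm\tlanguage\tsource\tsemantic_group", body),
    con = path, useBytes = FALSE
  )
  invisible(path)
}

# positions of a concept's entries (integer(0) when absent)
concept_positions <- function(dictionary, concept_id) {
  pos <- dictionary$by_concept[[concept_id]]
  if (is.null(pos)) integer(0) else pos
}
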