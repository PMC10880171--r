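#' Extract character n-grams
#'
#' All contiguous character substrings of each requested order `n`, taken
#' over the full canonical string including internal spaces (no word-boundary
#' padding: multiword medical terms stay comparable as whole strings).
#' Strings shorter than `n` contribute nothing for that order. The result is
#' a multiset: repeated n-grams appear with their multiplicity.
#'
#' @param text a single canonical string.
#' @param n_values integer vector of n-gram orders (each >= 1), e.g. `2`,
#'   `3`, or `c(2, 3)`.
#' @return character vector of n-grams with repeats (the multiset).
#' @examples
#' extract_ngrams("abc", 2) # "ab" "bc"
#' @export
extract_ngrams <- function(text, n_values) {
  n_values <- sort(unique(as.integer(n_values)))
  if (length(n_values) == 0L || any(n_values < 1L)) {
    stop("n_values must be integers >= 1", call. = FALSE)
  }
  stopifnot(length(text) == 1L)
  len <- nchar(text)
  out <- lapply(n_values, function(n) {
    if (is.na(len) || len < n) {
      return(character(0))
    }
    substring(text, 1:(len - n + 1L), n:len)
  })
  unlist(out, use.names = FALSE)
}

#' Fit the character n-gram TF-IDF bag-of-words encoder
#'
#' Each dictionary entry's term is one document. The vocabulary is every
#' n-gram (orders in `n_values`) appearing in at least one term; when several
#' orders are requested they share a single vocabulary and, at transform
#' time, a single term-frequency denominator, so each text maps to one
#' vector.
#'
#' Two idf dialects are provided:
#' * `"paper"` (default): `idf(g) = ln(N / df(g))` -- the textbook unsmoothed
#'   inverse document frequency; an n-gram present in every term gets weight
#'   0 and drops out of all vectors.
#' * `"smoothed"`: `idf(g) = ln((1 + N) / (1 + df(g))) + 1` -- the smoothed
#'   variant used by common vectorizer libraries, strictly positive.
#'
#' @param dictionary a non-empty [term_dictionary()].
#' @param n_values n-gram orders, default `3`.
#' @param dialect `"paper"` or `"smoothed"`.
#' @return an immutable object of class `sparse_encoder` with components
#'   `n_values`, `vocabulary` (character vector; column `j` is
#'   `vocabulary[j]`), `idf` (aligned numeric), `dialect`, `corpus_size`.
#' @export
fit_tfidf <- function(dictionary, n_values = 3, dialect = c("paper", "smoothed")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dictionary, "term_dictionary"))
  terms <- dictionary$entries$term
  if (length(terms) == 0L) {
    stop("cannot fit TF-IDF encoder on an empty dictionary", call. = FALSE)
  }
  n_values <- sort(unique(as.integer(n_values)))
  if (any(n_values < 1L)) stop("n_values must be integers >= 1", call. = FALSE)
  grams_per_doc <- lapply(terms, extract_ngrams, n_values = n_values)
  df_tab <- table(unlist(lapply(grams_per_doc, unique), use.names = FALSE))
  vocabulary <- sort(names(df_tab)) # deterministic column order
  df <- as.numeric(df_tab[vocabulary])
  n_docs <- length(terms)
  idf <- switch(dialect,
    paper = log(n_docs / df),
    smoothed = log((1 + n_docs) / (1 + df)) + 1
  )
  structure(
    list(
      n_values = n_values,
      vocabulary = vocabulary,
      idf = idf,
      dialect = dialect,
      corpus_size = n_docs
    ),
    class = "sparse_encoder"
  )
}

#' @export
print.sparse_encoder <- function(x, ...) {
  cat("<sparse_encoder> n = {", paste(x$n_values, collapse = ","),
    "}, dialect = ", x$dialect,
    ", vocabulary = ", length(x$vocabulary),
    " n-grams, corpus = ", x$corpus_size, " terms\n",
    sep = ""
  )
  invisible(x)
}

#' Transform a text into a sparse TF-IDF vector
#'
#' For each in-vocabulary n-gram `g` of the text,
#' `tf(g) = count(g) / total n-gram count of the text` and the stored value
#' is `tf(g) * idf(g)`. Out-of-vocabulary n-grams are ignored; entries whose
#' value is exactly 0 (zero idf under the paper dialect) are dropped. A text
#' with no in-vocabulary n-grams yields the empty vector.
#'
#' @param encoder a fitted [fit_tfidf()] encoder.
#' @param text a single canonical string.
#' @return an object of class `sparse_vector`: list with strictly increasing
#'   `indices` (1-based columns), positive `values`, and `dim` (vocabulary
#'   size).
#' @export
transform_sparse <- function(encoder, text) {
  stopifnot(inherits(encoder, "sparse_encoder"))
  grams <- extract_ngrams(text, encoder$n_values)
  total <- length(grams)
  if (total == 0L) {
    return(new_sparse_vector(integer(0), numeric(0), length(encoder$vocabulary)))
  }
  tab <- table(grams)
  idx <- match(names(tab), encoder$vocabulary)
  inv <- !is.na(idx)
  idx <- idx[inv]
  vals <- (as.numeric(tab)[inv] / total) * encoder$idf[idx]
  keep <- vals != 0
  ord <- order(idx[keep])
  new_sparse_vector(idx[keep][ord], vals[keep][ord], length(encoder$vocabulary))
}

new_sparse_vector <- function(indices, values, dim) {
  structure(
    list(indices = as.integer(indices), values = as.numeric(values), dim = as.integer(dim)),
    class = "sparse_vector"
  )
}

#' @export
print.sparse_vector <- function(x, ...) {
  cat("<sparse_vector> ", length(x$indices), " / ", x$dim, " nonzero\n", sep = "")
  invisible(x)
}

vec_dim <- function(x) if (inherits(x, "sparse_vector")) x$dim else length(x)

vec_norm <- function(x) {
  if (inherits(x, "sparse_vector")) sqrt(sum(x$values^2)) else sqrt(sum(x^2))
}

vec_dot <- function(a, b) {
  sa <- inherits(a, "sparse_vector")
  sb <- inherits(b, "sparse_vector")
  if (sa && sb) {
    at <- match(a$indices, b$indices)
    hit <- !is.na(at)
    sum(a$values[hit] * b$values[at[hit]])
  } else if (sa) {
    sum(a$values * b[a$indices])
  } else if (sb) {
    sum(b$values * a[b$indices])
  } else {
    sum(a * b)
  }
}

#' Cosine similarity between two vectors
#'
#' `dot(a, b) / (|a| |b|)`, for any mix of [transform_sparse()] sparse
#' vectors and plain numeric vectors of the same dimension. If either
#' argument is all-zero the similarity is 0 by convention.
#'
#' @param a,b vectors of identical dimension (sparse or dense).
#' @return a number in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  da <- vec_dim(a)
  db <- vec_dim(b)
  if (da != db) {
    stop("dimension mismatch: ", da, " vs ", db, call. = FALSE)
  }
  na <- vec_norm(a)
  nb <- vec_norm(b)
  if (na == 0 || nb == 0) {
    return(0)
  }
  vec_dot(a, b) / (na * nb)
}

# texts -> sparse document-term Matrix (rows = texts, cols = vocabulary)
sparse_doc_matrix <- function(encoder, texts) {
  vecs <- lapply(texts, function(t) transform_sparse(encoder, t))
  nnz <- vapply(vecs, function(v) length(v$indices), integer(1))
  Matrix::sparseMatrix(
    i = rep.int(seq_along(texts), nnz),
    j = unlist(lapply(vecs, `[[`, "indices"), use.names = FALSE),
    x = unlist(lapply(vecs, `[[`, "values"), use.names = FALSE),
    dims = c(length(texts), length(encoder$vocabulary))
  )
}

row_l2_normalize <- function(m) {
  rs <- sqrt(Matrix::rowSums(m * m))
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% m
}

#' String similarity score matrix
#'
#' Entry `(i, j)` is the cosine similarity between query text `i`'s sparse
#' TF-IDF vector and dictionary entry `j`'s. Rows whose query vector is empty
#' (no in-vocabulary n-grams) are all 0.
#'
#' @param encoder a fitted [fit_tfidf()] encoder (fitted on `dictionary`
#'   under the dialect the run uses).
#' @param queries character vector of canonical query texts.
#' @param dictionary a [term_dictionary()].
#' @return a dense numeric matrix, `length(queries)` rows by
#'   `length(dictionary)` columns.
#' @export
sparse_score_matrix <- function(encoder, queries, dictionary) {
  stopifnot(inherits(encoder, "sparse_encoder"), inherits(dictionary, "term_dictionary"))
  qm <- row_l2_normalize(sparse_doc_matrix(encoder, queries))
  dm <- row_l2_normalize(sparse_doc_matrix(encoder, dictionary$entries$term))
  as.matrix(qm %*% Matrix::t(dm))
}

#' Save / load a fitted sparse encoder
#'
#' The archive is a versioned single-file store of the vocabulary, idf
#' weights, n-gram orders, dialect, and corpus size; reloading reproduces
#' transforms bit-identically.
#'
#' @param encoder a fitted [fit_tfidf()] encoder.
#' @param path archive file path.
#' @return `path` (save) / the `sparse_encoder` (load).
#' @export
save_sparse_encoder <- function(encoder, path) {
  stopifnot(inherits(encoder, "sparse_encoder"))
  saveRDS(list(format = "termlink_sparse_encoder", version = 1L, encoder = encoder),
    file = path
  )
  invisible(path)
}

#' @rdname save_sparse_encoder
#' @export
load_sparse_encoder <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "termlink_sparse_encoder")) {
    stop("not a sparse-encoder archive: ", path, call. = FALSE)
  }
  if (!identical(obj$version, 1L)) {
    stop("unsupported encoder archive version: ", obj$version, call. = FALSE)
  }
  obj$encoder
}
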