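#' Dense embedder contract
#'
#' The semantic channel scores candidates by cosine similarity between dense
#' vectors of queries and dictionary terms. Real backends are pretrained
#' language models (SapBERT-class) pooled at the sequence-start special token
#' of the final layer (CLS convention); those run offline and feed the
#' pipeline through the precomputed-vector file interface
#' ([read_dense_vectors()], [vector_embedder()]). For tests and synthetic
#' benchmarks the package ships a deterministic toy backend
#' ([toy_embedder()]).
#'
#' An embedder has a `name`, a `dim`, and an `embed` function mapping a batch
#' of canonical texts to a matrix with one row per text, `dim` columns, all
#' entries finite; the map is deterministic for a fixed embedder instance.
#' Vectors are not l2-normalized at embed time -- cosine is scale-invariant
#' and raw backend outputs stay inspectable.
#'
#' @param name backend name (used in errors).
#' @param dim positive integer output dimension.
#' @param embed_fun function(character vector) -> numeric matrix.
#' @return an object of class `dense_embedder`.
#' @export
dense_embedder <- function(name, dim, embed_fun) {
  stopifnot(is.character(name), length(name) == 1L)
  dim <- as.integer(dim)
  stopifnot(dim >= 1L, is.function(embed_fun))
  structure(
    list(name = name, dim = dim, embed = embed_fun),
    class = "dense_embedder"
  )
}

#' Embed a batch of texts
#'
#' Runs the backend and enforces the contract: one row per input text,
#' `embedder$dim` columns, finite entries.
#'
#' @param embedder a [dense_embedder()].
#' @param texts character vector of non-empty canonical strings.
#' @return numeric matrix, `length(texts)` x `embedder$dim`.
#' @export
embed_texts <- function(embedder, texts) {
  stopifnot(inherits(embedder, "dense_embedder"))
  texts <- as.character(texts)
  if (length(texts) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = embedder$dim))
  }
  m <- embedder$embed(texts)
  if (!is.matrix(m) || nrow(m) != length(texts) || ncol(m) != embedder$dim) {
    stop("embedder '", embedder$name, "' violated the shape contract",
      call. = FALSE
    )
  }
  if (!all(is.finite(m))) {
    stop("embedder '", embedder$name, "' produced non-finite values",
      call. = FALSE
    )
  }
  m
}

# deterministic 31-bit polynomial string hash (fits exactly in doubles)
hash_string <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) {
    h <- (h * 131 + code) %% 2147483647
  }
  h
}

#' Deterministic toy dense embedder
#'
#' A text is embedded as the l2-normalized sum of seeded pseudo-random unit
#' vectors hashed from its character 3-grams (a text shorter than 3
#' characters falls back to a single whole-string gram). Texts sharing many
#' 3-grams get a high cosine; unrelated texts concentrate near 0 at
#' moderate dimensions. Fully deterministic given `(dim, seed)`, across
#' sessions and processes; per-gram vectors are cached inside the instance.
#'
#' This backend is a stand-in for language-model embedders in tests and
#' synthetic benchmarks only -- it knows characters, not meaning.
#'
#' @param dim output dimension, >= 8 (default 256).
#' @param seed integer seed for the per-gram vector construction.
#' @return a [dense_embedder()].
#' @export
toy_embedder <- function(dim = 256, seed = 1) {
  dim <- as.integer(dim)
  if (dim < 8L) stop("toy embedder needs dim >= 8", call. = FALSE)
  seed <- as.integer(seed)
  cache <- new.env(parent = emptyenv())
  gram_vector <- function(g) {
    v <- cache[[g]]
    if (is.null(v)) {
      s <- as.integer((hash_string(g) + abs(seed) * 48271) %% 2147483647)
      v <- withr::with_seed(s, stats::rnorm(dim))
      v <- v / sqrt(sum(v^2))
      cache[[g]] <- v
    }
    v
  }
  dense_embedder(
    name = sprintf("toy(dim=%d,seed=%d)", dim, seed),
    dim = dim,
    embed_fun = function(texts) {
      rows <- lapply(texts, function(t) {
        grams <- extract_ngrams(t, 3L)
        if (length(grams) == 0L) grams <- t
        v <- Reduce(`+`, lapply(grams, gram_vector))
        n <- sqrt(sum(v^2))
        if (n > 0) v / n else v
      })
      do.call(rbind, rows)
    }
  )
}

#' Read / write a precomputed dense-vector file
#'
#' The file interface for vectors produced offline by a real language-model
#' backend: a header line `<dim> <N>`, then one line per term,
#' `term TAB space-separated floats`. Terms are canonicalized on load and
#' must be unique; every row must have exactly `dim` finite values.
#'
#' @param path vector file path.
#' @return for the reader, a numeric matrix with terms as rownames; for the
#'   writer, `path` invisibly.
#' @export
read_dense_vectors <- function(path) {
  if (!file.exists(path)) {
    stop("dense vector file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty dense vector file: ", path, call. = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  if (length(hdr) != 2L || any(is.na(hdr)) || hdr[1] < 1L) {
    stop("malformed header in ", path, " (expected '<dim> <N>')", call. = FALSE)
  }
  dim <- hdr[1]
  n <- hdr[2]
  body <- lines[-1]
  if (length(body) != n) {
    stop(
      "dense vector file declares ", n, " terms but has ", length(body),
      call. = FALSE
    )
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed vector row in ", path, call. = FALSE)
  }
  terms <- canonicalize(vapply(parts, `[[`, character(1), 1L))
  if (anyDuplicated(terms)) {
    stop("duplicate term in dense vector file: ",
      terms[duplicated(terms)][1],
      call. = FALSE
    )
  }
  vals <- lapply(parts, function(p) {
    as.numeric(strsplit(p[[2]], " ", fixed = TRUE)[[1]])
  })
  if (any(lengths(vals) != dim)) {
    stop("vector row with wrong dimension in ", path, call. = FALSE)
  }
  m <- do.call(rbind, vals)
  if (!all(is.finite(m))) stop("non-finite vector values in ", path, call. = FALSE)
  rownames(m) <- terms
  m
}

#' @rdname read_dense_vectors
#' @param vectors numeric matrix with term rownames.
#' @export
write_dense_vectors <- function(vectors, path) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  body <- vapply(seq_len(nrow(vectors)), function(i) {
    paste0(
      rownames(vectors)[i], "\t",
      paste(sprintf("%.17g", vectors[i, ]), collapse = " ")
    )
  }, character(1))
  writeLines(c(paste(ncol(vectors), nrow(vectors)), body),
    con = path, useBytes = FALSE
  )
  invisible(path)
}

#' Embedder backed by a precomputed vector table
#'
#' Looks texts up (after canonicalization) in a term-to-vector matrix such as
#' one loaded by [read_dense_vectors()]. A text absent from the table raises
#' an embedder error naming the text. Interchangeable with [toy_embedder()]
#' in all downstream modules.
#'
#' @param vectors numeric matrix with term rownames, or a vector-file path.
#' @param name backend name.
#' @return a [dense_embedder()].
#' @export
vector_embedder <- function(vectors, name = "precomputed") {
  if (is.character(vectors) && length(vectors) == 1L) {
    vectors <- read_dense_vectors(vectors)
  }
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  dense_embedder(
    name = name,
    dim = ncol(vectors),
    embed_fun = function(texts) {
      at <- match(canonicalize(texts), rownames(vectors))
      if (anyNA(at)) {
        stop("embedder '", name, "': no vector for term '",
          texts[which(is.na(at))[1]], "'",
          call. = FALSE
        )
      }
      vectors[at, , drop = FALSE]
    }
  )
}

#' Semantic similarity score matrix
#'
#' Entry `(i, j)` is the cosine similarity between the dense vectors of query
#' text `i` and dictionary entry `j` under the given embedder. All-zero
#' vectors (possible in principle for degenerate backends) yield 0 rows or
#' columns.
#'
#' @param embedder a [dense_embedder()].
#' @param queries character vector of canonical query texts.
#' @param dictionary a [term_dictionary()].
#' @return dense numeric matrix, `length(queries)` x `length(dictionary)`.
#' @export
semantic_score_matrix <- function(embedder, queries, dictionary) {
  stopifnot(inherits(dictionary, "term_dictionary"))
  qm <- embed_texts(embedder, queries)
  dm <- embed_texts(embedder, dictionary$entries$term)
  norm_rows <- function(m) {
    ns <- sqrt(rowSums(m^2))
    ns[ns == 0] <- 1
    m / ns
  }
  out <- norm_rows(qm) %*% t(norm_rows(dm))
  dimnames(out) <- NULL
  out
}
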