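# Independent brute-force reference implementations used as oracles.
# Deliberately written with plain loops and named lists so they share no code
# path with the package internals.

`%or%` <- function(x, y) if (is.null(x)) y else x

oracle_ngrams <- function(text, n_values) {
  out <- character(0)
  for (n in sort(unique(n_values))) {
    len <- nchar(text)
    if (len >= n) {
      for (i in 1:(len - n + 1)) {
        out <- c(out, substr(text, i, i + n - 1))
      }
    }
  }
  out
}

# fit on a plain character vector of terms; returns idf as a named list
oracle_tfidf_fit <- function(terms, n_values, dialect = "paper") {
  df <- list()
  for (term in terms) {
    for (g in unique(oracle_ngrams(term, n_values))) {
      df[[g]] <- (df[[g]] %or% 0) + 1
    }
  }
  n_docs <- length(terms)
  idf <- list()
  for (g in names(df)) {
    idf[[g]] <- if (dialect == "paper") {
      log(n_docs / df[[g]])
    } else {
      log((1 + n_docs) / (1 + df[[g]])) + 1
    }
  }
  list(idf = idf, n_docs = n_docs, n_values = n_values)
}

# returns a named list gram -> tf*idf (zeros dropped)
oracle_tfidf_transform <- function(model, text) {
  grams <- oracle_ngrams(text, model$n_values)
  total <- length(grams)
  vec <- list()
  if (total == 0) {
    return(vec)
  }
  for (g in unique(grams)) {
    w <- model$idf[[g]]
    if (!is.null(w)) {
      val <- (sum(grams == g) / total) * w
      if (val != 0) vec[[g]] <- val
    }
  }
  vec
}

oracle_cosine <- function(va, vb) {
  dot <- 0
  for (g in names(va)) {
    if (!is.null(vb[[g]])) dot <- dot + va[[g]] * vb[[g]]
  }
  na <- sqrt(sum(unlist(va)^2))
  nb <- sqrt(sum(unlist(vb)^2))
  if (length(va) == 0 || length(vb) == 0 || na == 0 || nb == 0) {
    return(0)
  }
  dot / (na * nb)
}

oracle_score_matrix <- function(query_texts, dict_terms, n_values, dialect = "paper") {
  model <- oracle_tfidf_fit(dict_terms, n_values, dialect)
  dvecs <- lapply(dict_terms, function(t) oracle_tfidf_transform(model, t))
  out <- matrix(0, length(query_texts), length(dict_terms))
  for (i in seq_along(query_texts)) {
    qv <- oracle_tfidf_transform(model, query_texts[i])
    for (j in seq_along(dict_terms)) {
      out[i, j] <- oracle_cosine(qv, dvecs[[j]])
    }
  }
  out
}

# package sparse_vector -> named list keyed by vocabulary gram, for comparison
sparse_vec_as_list <- function(vec, encoder) {
  out <- list()
  for (k in seq_along(vec$indices)) {
    out[[encoder$vocabulary[vec$indices[k]]]] <- vec$values[k]
  }
  out
}
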