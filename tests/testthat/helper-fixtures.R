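# Shared fixture builders (all generated in code; no stored data files).

make_dict <- function(terms, concept_ids = NULL) {
  if (is.null(concept_ids)) {
    concept_ids <- sprintf("C%03d", seq_along(terms))
  }
  term_dictionary(data.frame(concept_id = concept_ids, term = terms))
}

# random lowercase multi-word strings (used for oracle fixtures)
random_texts <- function(n, min_words = 1, max_words = 3) {
  vapply(seq_len(n), function(i) {
    words <- vapply(
      seq_len(sample(min_words:max_words, 1)),
      function(j) {
        paste(sample(letters, sample(3:7, 1), replace = TRUE), collapse = "")
      },
      character(1)
    )
    paste(words, collapse = " ")
  }, character(1))
}

# a labeled candidate pool with random scores and at least one positive
random_pool <- function(m = 12, n_pos = NULL) {
  if (is.null(n_pos)) n_pos <- sample(1:(m - 1), 1)
  cids <- sprintf("C%03d", seq_len(m))
  gold <- sample(cids, n_pos)
  mine_candidates(
    string_scores = runif(m), semantic_scores = runif(m),
    concept_ids = cids, params = combiner_params("linear"),
    k = m, gold = gold
  )
}

# tiny deterministic mock providers for translation tests
provider_fixture <- function() {
  p1 <- mock_translation_provider("baidu-mock", data.frame(
    source = c("脂沉积症", "脂沉积症", "双肾盂"),
    translation = c("Lipid Deposition Disorder", "Liposis", "Double renal pelvis")
  ))
  p2 <- mock_translation_provider("youdao-mock", data.frame(
    source = "脂沉积症",
    translation = "lipid storage disease"
  ))
  list(p1 = p1, p2 = p2)
}
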