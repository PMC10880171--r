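# shared small benchmark for the mapping tests
bench <- generate_benchmark(synthetic_config(
  n_concepts = 30, synonyms_per_concept = 2, n_queries = 20,
  string_noise = 0.1, channel_mode = "both", seed = 11
))
bench_enc <- fit_tfidf(bench$dictionary, 3)
bench_emb <- vector_embedder(bench$dense_vectors)

test_that("an exact dictionary match ranks first under every scheme", {
  d <- bench$dictionary
  target <- d$entries$term[7]
  gold <- d$entries$concept_id[7]
  q <- query_set("q1", target,
    gold_concept_ids = list(gold),
    translations = list(target)
  )
  for (scheme in c("linear", "string_only", "semantic_only", "zscore", "minmax", "tanh")) {
    res <- map_entities(q, d, bench_enc, bench_emb, combiner_params(scheme))
    expect_equal(res$hit_rank[1], 1L, info = scheme)
  }
})

test_that("single-channel schemes reproduce the raw channel rankings", {
  res_sem <- map_entities(
    bench$queries, bench$dictionary, bench_enc, bench_emb,
    combiner_params("semantic_only")
  )
  ch <- channel_score_matrices(bench$queries, bench$dictionary, bench_enc, bench_emb)
  nd <- length(bench$dictionary)
  cids <- bench$dictionary$entries$concept_id
  for (i in seq_len(nrow(bench$queries))) {
    ord <- order(-ch$semantic[i, ], seq_len(nd))
    ord <- ord[!duplicated(cids[ord])]
    expect_identical(
      res_sem$ranked[[i]]$concept_id,
      cids[utils::head(ord, 10)]
    )
  }
})

test_that("linear ranking matches a hand-fused brute-force sort on a small fixture", {
  set.seed(61)
  terms <- unique(random_texts(20))
  d <- make_dict(terms)
  enc <- fit_tfidf(d, 3)
  emb <- toy_embedder(dim = 64, seed = 4)
  q <- query_set("q1", terms[5], translations = list(terms[5]))
  p <- combiner_params("linear", 1, 1)
  res <- map_entities(q, d, enc, emb, p, n_max = length(d), dedup_concepts = FALSE)
  s_str <- sparse_score_matrix(enc, terms[5], d)[1, ]
  s_sem <- semantic_score_matrix(emb, terms[5], d)[1, ]
  want <- order(-(s_str + s_sem), seq_along(terms))
  expect_identical(
    res$ranked[[1]]$concept_id,
    d$entries$concept_id[want]
  )
  expect_equal(res$ranked[[1]]$s_combined, unname((s_str + s_sem)[want]), tolerance = 1e-12)
})

test_that("duplicate concepts collapse before rank counting unless disabled", {
  d <- term_dictionary(data.frame(
    concept_id = c("C1", "C1", "C2"),
    term = c("acute flu", "flu", "cold")
  ))
  enc <- fit_tfidf(d, 2)
  emb <- toy_embedder(64, 2)
  q <- query_set("q1", "flu", gold_concept_ids = list("C2"), translations = list("flu"))
  dd <- map_entities(q, d, enc, emb, combiner_params("string_only"), n_max = 3)
  # C1 holds ranks by two terms; deduped, C2 is rank 2
  expect_equal(dd$hit_rank[1], 2L)
  expect_identical(dd$ranked[[1]]$concept_id[1:2], c("C1", "C2"))
  raw <- map_entities(q, d, enc, emb, combiner_params("string_only"),
    n_max = 3, dedup_concepts = FALSE
  )
  expect_equal(raw$hit_rank[1], 3L) # both C1 term rows outrank C2
})

test_that("adding translation variants never lowers the gold candidate's channel scores", {
  qs <- bench$queries
  one_variant <- qs
  one_variant$translations <- lapply(qs$translations, function(v) v[1])
  ch_full <- channel_score_matrices(qs, bench$dictionary, bench_enc, bench_emb)
  ch_one <- channel_score_matrices(one_variant, bench$dictionary, bench_enc, bench_emb)
  expect_true(all(ch_full$string >= ch_one$string - 1e-12))
  expect_true(all(ch_full$semantic >= ch_one$semantic - 1e-12))
})

test_that("scaling (alpha, beta) by a positive constant leaves rankings unchanged", {
  p1 <- combiner_params("linear", 1.2, 0.7)
  p2 <- combiner_params("linear", 3 * 1.2, 3 * 0.7)
  r1 <- map_entities(bench$queries, bench$dictionary, bench_enc, bench_emb, p1)
  r2 <- map_entities(bench$queries, bench$dictionary, bench_enc, bench_emb, p2)
  for (i in seq_len(nrow(r1))) {
    expect_identical(r1$ranked[[i]]$concept_id, r2$ranked[[i]]$concept_id)
  }
  expect_identical(r1$hit_rank, r2$hit_rank)
})

test_that("queries with no variants fall back to the surface with a warning", {
  d <- bench$dictionary
  q <- query_set("q1", d$entries$term[1],
    gold_concept_ids = list(d$entries$concept_id[1])
  )
  expect_warning(
    res <- map_entities(q, d, bench_enc, bench_emb, combiner_params("linear")),
    "falling back"
  )
  expect_equal(res$hit_rank[1], 1L)
  expect_error(
    map_entities(q, d, bench_enc, bench_emb, combiner_params("linear"), n_max = 0),
    "n_max"
  )
})

test_that("providers supply variants for queries that lack them", {
  d <- bench$dictionary
  target <- d$entries$term[3]
  p <- mock_translation_provider(
    "mock",
    data.frame(source = "源术语", translation = target)
  )
  q <- query_set("q1", "源术语", gold_concept_ids = list(d$entries$concept_id[3]))
  res <- map_entities(q, d, bench_enc, bench_emb, combiner_params("linear"),
    providers = list(p)
  )
  expect_equal(res$hit_rank[1], 1L)
})

test_that("acc_at_n reproduces hand counts and is monotone in n", {
  res <- tibble::tibble(
    query_id = paste0("q", 1:4),
    hit_rank = c(1L, 3L, 7L, NA_integer_),
    has_gold = TRUE
  )
  expect_equal(acc_at_n(res, 1), 25)
  expect_equal(acc_at_n(res, 5), 50)
  expect_equal(acc_at_n(res, 10), 75)
  perfect <- tibble::tibble(query_id = "q", hit_rank = 1L, has_gold = TRUE)
  expect_equal(acc_at_n(perfect, 1), 100)
  expect_error(acc_at_n(res[0, ], 1), "empty")
  expect_error(acc_at_n(res, 0), ">= 1")
  res$has_gold[2] <- FALSE
  expect_error(acc_at_n(res, 1), "gold")

  set.seed(67)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    ranks <- sample(c(1:10, NA), n, replace = TRUE)
    r <- tibble::tibble(query_id = as.character(1:n), hit_rank = ranks, has_gold = TRUE)
    accs <- vapply(c(1, 5, 10), acc_at_n, numeric(1), results = r)
    expect_true(all(diff(accs) >= 0))
    expect_equal(accs[3], 100 * sum(!is.na(ranks) & ranks <= 10) / n)
  }
})

test_that("mcnemar_test matches exact-binomial and corrected chi-square forms", {
  mk <- function(b, c_, n = 100) {
    # build aligned hit vectors with the requested discordance
    a <- rep(FALSE, n)
    bb <- rep(FALSE, n)
    if (b > 0) a[1:b] <- TRUE
    if (c_ > 0) bb[(b + 1):(b + c_)] <- TRUE
    list(a = a, b = bb)
  }
  h <- mk(5, 5)
  r <- mcnemar_test(h$a, h$b)
  expect_equal(r$p_value, 1, tolerance = 1e-9)
  expect_identical(r$method, "exact_binomial")
  expect_true(is.na(r$statistic))

  h <- mk(20, 10)
  r <- mcnemar_test(h$a, h$b)
  expect_identical(r$method, "chi2_corrected")
  expect_equal(r$statistic, 2.7, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(2.7, 1, lower.tail = FALSE), tolerance = 1e-12)

  same <- rep(c(TRUE, FALSE), 10)
  r <- mcnemar_test(same, same)
  expect_equal(r$p_value, 1)
  expect_true(is.na(r$statistic))
  expect_equal(r$b + r$c, 0L)

  # boundary: 24 discordant pairs exact, 25 chi-square
  expect_identical(mcnemar_test(mk(12, 12)$a, mk(12, 12)$b)$method, "exact_binomial")
  expect_identical(mcnemar_test(mk(13, 12)$a, mk(13, 12)$b)$method, "chi2_corrected")
})

test_that("strategy reports tabulate accuracies consistently and reproducibly", {
  strategies <- list(
    string_tfidf = combiner_params("string_only"),
    linear = combiner_params("linear", 2, 1)
  )
  path1 <- withr::local_tempfile(fileext = ".tsv")
  tab <- strategy_report(bench, strategies, path = path1)
  expect_equal(nrow(tab), 2L)
  expect_identical(tab$strategy, c("string_tfidf", "linear"))
  expect_true(is.na(tab$mcnemar_p[1])) # baseline row
  expect_false(is.na(tab$mcnemar_p[2]))
  # accuracies equal acc_at_n recomputed from the raw results
  raw <- attr(tab, "results")
  expect_equal(tab$acc5[1], acc_at_n(raw$string_tfidf, 5))
  expect_equal(tab$acc10[2], acc_at_n(raw$linear, 10))
  # byte-for-byte reproducible
  path2 <- withr::local_tempfile(fileext = ".tsv")
  strategy_report(bench, strategies, path = path2)
  expect_identical(readLines(path1), readLines(path2))
  expect_error(strategy_report(bench, strategies, baseline = "nope"), "unknown baseline")
})
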