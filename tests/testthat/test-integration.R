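test_that("normalization schemes match closed forms and degenerate conventions", {
  expect_equal(normalize_channel(c(1, 2, 3), "zscore"),
    c(-1, 0, 1) * sqrt(3 / 2), # population sigma = sqrt(2/3)
    tolerance = 1e-6
  )
  expect_equal(normalize_channel(c(1, 2, 3), "minmax"), c(0, 0.5, 1))
  expect_equal(normalize_channel(c(5, 5, 5), "tanh"), c(0.5, 0.5, 0.5))
  expect_equal(normalize_channel(c(5, 5, 5), "minmax"), c(0.5, 0.5, 0.5))
  expect_equal(normalize_channel(c(5, 5, 5), "zscore"), c(0, 0, 0))
  expect_error(normalize_channel(1:3, "rank"), "arg")
})

test_that("normalization preserves within-pool score order", {
  set.seed(71)
  for (i in 1:25) {
    s <- sample(round(runif(12, 0, 1), 2)) # rounded to force some ties
    for (scheme in c("zscore", "minmax", "tanh")) {
      z <- normalize_channel(s, scheme)
      ord <- order(s)
      expect_true(all(diff(z[ord]) >= -1e-12)) # monotone: ties merge, never invert
    }
  }
})

test_that("combine_linear applies the weights and reduces to single channels", {
  p <- combiner_params("linear", alpha = 33.11, beta = 7.28)
  expect_equal(combine_linear(0.9, 0.5, p), 33.439, tolerance = 1e-12)
  expect_equal(combine_linear(0.7, 0.3, combiner_params("semantic_only")), 0.7)
  expect_equal(combine_linear(0.7, 0.3, combiner_params("string_only")), 0.3)
  expect_error(combine_linear(NaN, 1, p), "non-finite")
  expect_error(combine_linear(1, 1, combiner_params("zscore")), "linear-family")
})

test_that("mine_candidates matches a brute-force full sort with stable ties", {
  set.seed(17)
  n <- 50
  cids <- sprintf("C%03d", seq_len(n))
  str_s <- round(runif(n), 1) # coarse scores: plenty of ties
  sem_s <- round(runif(n), 1)
  p <- combiner_params("linear", alpha = 2, beta = 1)
  pool <- mine_candidates(str_s, sem_s, cids, params = p, k = 10, gold = "C001")
  comb <- 2 * sem_s + 1 * str_s
  want <- order(-comb, seq_len(n))[1:10] # brute-force stable sort
  expect_identical(pool$candidates$position, want)
  expect_true(all(diff(pool$candidates$s_combined) <= 1e-12))
  expect_identical(pool$candidates$is_positive, cids[want] %in% "C001")

  # k = dictionary size: the whole dictionary, sorted
  full <- mine_candidates(str_s, sem_s, cids, params = p, k = n)
  expect_identical(full$candidates$position, order(-comb, seq_len(n)))
  expect_warning(
    trunc <- mine_candidates(str_s, sem_s, cids, params = p, k = n + 5),
    "truncated"
  )
  expect_equal(trunc$k, n)

  # exact ties resolve by dictionary position
  tied <- mine_candidates(c(1, 1, 1), c(0, 0, 0), c("A", "B", "C"), k = 3)
  expect_identical(tied$candidates$concept_id, c("A", "B", "C"))
})

test_that("marginal probability matches softmax closed forms", {
  p11 <- combiner_params("linear", 1, 1)
  mk_pool <- function(sem, str, gold_mask) {
    cids <- sprintf("C%02d", seq_along(sem))
    mine_candidates(str, sem, cids,
      params = p11, k = length(sem),
      gold = cids[gold_mask]
    )
  }
  # two candidates, combined scores (2, 0), first positive
  pool <- mk_pool(sem = c(2, 0), str = c(0, 0), gold_mask = 1)
  expect_equal(marginal_probability(pool, p11), exp(2) / (exp(2) + 1), tolerance = 1e-12)
  # all positive: softmax sums to one
  expect_equal(marginal_probability(mk_pool(runif(5), runif(5), 1:5), p11), 1)
  # uniform pool of m with p positives: p/m
  expect_equal(
    marginal_probability(mk_pool(rep(0.3, 8), rep(0.1, 8), 1:3), p11),
    3 / 8,
    tolerance = 1e-12
  )
  expect_error(
    marginal_probability(mk_pool(c(1, 0), c(0, 0), integer(0)), p11),
    "no positive"
  )
})

test_that("marginal probability equals a brute-force softmax-and-sum loop", {
  set.seed(29)
  p <- combiner_params("linear", alpha = 1.7, beta = 0.4)
  for (i in 1:20) {
    pool <- random_pool(m = sample(3:20, 1))
    cand <- pool$candidates
    s <- 1.7 * cand$s_semantic + 0.4 * cand$s_string
    brute <- sum(exp(s)[cand$is_positive]) / sum(exp(s))
    expect_equal(marginal_probability(pool, p), brute, tolerance = 1e-12)
  }
})

test_that("marginal loss matches closed forms and responds to score changes", {
  p11 <- combiner_params("linear", 1, 1)
  cids <- c("C1", "C2")
  pool <- mine_candidates(c(0, 0), c(2, 0), cids, params = p11, k = 2, gold = "C1")
  expect_equal(marginal_loss(list(pool), p11), -log(exp(2) / (exp(2) + 1)),
    tolerance = 1e-12
  )
  expect_equal(round(marginal_loss(list(pool), p11), 4), 0.1269)
  allpos <- mine_candidates(runif(4), runif(4), paste0("C", 1:4),
    params = p11,
    k = 4, gold = paste0("C", 1:4)
  )
  expect_equal(marginal_loss(list(allpos), p11), 0)
  expect_error(marginal_loss(list(), p11), "empty")

  # raising a positive candidate's semantic score strictly lowers the loss
  set.seed(43)
  for (i in 1:10) {
    m <- 10
    sem <- runif(m)
    str <- runif(m)
    cids <- sprintf("C%02d", 1:m)
    gold <- cids[1:2]
    base <- mine_candidates(str, sem, cids, params = p11, k = m, gold = gold)
    sem2 <- sem
    sem2[1] <- sem2[1] + 0.5
    raised <- mine_candidates(str, sem2, cids, params = p11, k = m, gold = gold)
    expect_lt(
      marginal_loss(list(raised), p11),
      marginal_loss(list(base), p11)
    )
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(37)
  pools <- lapply(1:20, function(i) random_pool(m = sample(5:20, 1)))
  for (pars in list(c(1, 1), c(3, 0.5), c(0.2, 2.5))) {
    p <- combiner_params("linear", pars[1], pars[2])
    g <- marginal_loss_gradient(pools, p)
    h <- 1e-5
    fd <- c(
      (marginal_loss(pools, combiner_params("linear", pars[1] + h, pars[2])) -
        marginal_loss(pools, combiner_params("linear", pars[1] - h, pars[2]))) / (2 * h),
      (marginal_loss(pools, combiner_params("linear", pars[1], pars[2] + h)) -
        marginal_loss(pools, combiner_params("linear", pars[1], pars[2] - h))) / (2 * h)
    )
    expect_equal(unname(g), fd, tolerance = 1e-6)
  }
})

test_that("train_combiner descends on a tiny separable fixture", {
  set.seed(53)
  cfg <- synthetic_config(
    n_concepts = 40, synonyms_per_concept = 2, n_queries = 30,
    channel_mode = "both", seed = 19
  )
  b <- generate_benchmark(cfg)
  enc <- fit_tfidf(b$dictionary, 3)
  ch <- channel_score_matrices(b$queries, b$dictionary, enc, vector_embedder(b$dense_vectors))
  fit <- train_combiner(b$queries, b$dictionary, ch$string, ch$semantic,
    train_config(epochs = 15, learning_rate = 0.3, seed = 19)
  )
  expect_length(fit$loss_history, 15L)
  expect_lt(fit$loss_history[15], fit$loss_history[1])
  # deterministic: same inputs, same trajectory
  fit2 <- train_combiner(b$queries, b$dictionary, ch$string, ch$semantic,
    train_config(epochs = 15, learning_rate = 0.3, seed = 19)
  )
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_identical(fit$params, fit2$params)

  # a query whose gold is absent from the dictionary violates the contract
  qs <- b$queries
  qs$gold_concept_ids[[1]] <- "C-not-there"
  expect_error(
    train_combiner(qs, b$dictionary, ch$string, ch$semantic, train_config(epochs = 1)),
    "no gold concept"
  )
})

test_that("combiner parameter files round-trip", {
  fit <- list(
    params = combiner_params("linear", 33.11, 7.28),
    loss_history = c(1.5, 0.7, 0.3),
    config = train_config(epochs = 3)
  )
  class(fit) <- "combiner_fit"
  path <- withr::local_tempfile(fileext = ".json")
  write_combiner_params(fit, path)
  back <- read_combiner_params(path)
  expect_equal(back$params, fit$params)
  expect_equal(back$loss_history, fit$loss_history)
  expect_equal(back$config$epochs, 3L)
})
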