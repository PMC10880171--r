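#' Combiner parameters
#'
#' The fused ranking score is `S = alpha * S_semantic + beta * S_string`
#' under the `linear` scheme (with `string_only` and `semantic_only` as the
#' degenerate single-channel settings). The `zscore`, `minmax` and `tanh`
#' schemes instead normalize each channel per query (see
#' [normalize_channel()]) and sum them with fixed unit weights; pass
#' `weighted = TRUE` to [map_entities()] to apply `alpha`/`beta` after
#' normalization instead.
#'
#' @param scheme one of `"linear"`, `"zscore"`, `"minmax"`, `"tanh"`,
#'   `"string_only"`, `"semantic_only"`.
#' @param alpha semantic-channel weight (finite).
#' @param beta string-channel weight (finite).
#' @return an object of class `combiner_params`.
#' @examples
#' combiner_params("linear", alpha = 33.11, beta = 7.28)
#' @export
combiner_params <- function(scheme = c(
                              "linear", "zscore", "minmax", "tanh",
                              "string_only", "semantic_only"
                            ),
                            alpha = 1, beta = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "string_only") {
    alpha <- 0
    beta <- 1
  } else if (scheme == "semantic_only") {
    alpha <- 1
    beta <- 0
  }
  if (!is.finite(alpha) || !is.finite(beta)) {
    stop("alpha and beta must be finite", call. = FALSE)
  }
  structure(
    list(scheme = scheme, alpha = as.numeric(alpha), beta = as.numeric(beta)),
    class = "combiner_params"
  )
}

#' @export
print.combiner_params <- function(x, ...) {
  cat(sprintf(
    "<combiner_params> scheme = %s, alpha = %.4g, beta = %.4g\n",
    x$scheme, x$alpha, x$beta
  ))
  invisible(x)
}

#' Normalize one score channel within a candidate pool
#'
#' Score-fusion normalization applied per query over a candidate pool's
#' channel (string or semantic) before the channels are summed:
#' * `zscore`: `(s - mu) / sigma` with population sigma;
#' * `minmax`: `(s - min) / (max - min)`;
#' * `tanh`: `0.5 * (tanh(0.01 * (s - mu) / sigma) + 1)` (the conventional
#'   robust tanh score-normalization; the 0.01 constant is part of that
#'   convention).
#'
#' Degenerate pools (zero spread) map to all 0 for `zscore` and all 0.5 for
#' `minmax`/`tanh`. All three maps are monotone non-decreasing, so within-pool
#' score order is preserved (ties may merge, never invert).
#'
#' @param scores numeric vector, length >= 1.
#' @param scheme `"zscore"`, `"minmax"`, or `"tanh"`.
#' @return numeric vector of normalized scores.
#' @export
normalize_channel <- function(scores, scheme = c("zscore", "minmax", "tanh")) {
  scheme <- match.arg(scheme)
  stopifnot(length(scores) >= 1L, all(is.finite(scores)))
  mu <- mean(scores)
  sigma <- sqrt(mean((scores - mu)^2))
  switch(scheme,
    zscore = if (sigma == 0) rep(0, length(scores)) else (scores - mu) / sigma,
    minmax = {
      lo <- min(scores)
      hi <- max(scores)
      if (hi == lo) rep(0.5, length(scores)) else (scores - lo) / (hi - lo)
    },
    tanh = {
      if (sigma == 0) {
        rep(0.5, length(scores))
      } else {
        0.5 * (tanh(0.01 * (scores - mu) / sigma) + 1)
      }
    }
  )
}

#' Linear score combination
#'
#' `alpha * s_semantic + beta * s_string`. With `semantic_only` parameters
#' this returns the semantic score unchanged; with `string_only`, the string
#' score.
#'
#' @param s_semantic,s_string numeric (vectors recycle together).
#' @param params a [combiner_params()] with scheme `linear`, `string_only`,
#'   or `semantic_only`.
#' @return numeric combined score(s).
#' @export
combine_linear <- function(s_semantic, s_string, params) {
  stopifnot(inherits(params, "combiner_params"))
  if (!params$scheme %in% c("linear", "string_only", "semantic_only")) {
    stop("combine_linear requires a linear-family scheme, got ", params$scheme,
      call. = FALSE
    )
  }
  if (!all(is.finite(s_semantic)) || !all(is.finite(s_string))) {
    stop("non-finite channel scores", call. = FALSE)
  }
  params$alpha * s_semantic + params$beta * s_string
}

#' Mine a top-k candidate pool for one query
#'
#' Selects the top-k dictionary entries by the current combined score
#' (`alpha * semantic + beta * string`), keeping the per-channel scores
#' unfused so the marginal-probability loss can be re-evaluated under new
#' parameters without re-mining. Ties are broken by dictionary position
#' (stable), so pools are bit-reproducible. When gold labels are supplied,
#' each candidate's `is_positive` records whether its concept id is in the
#' gold set.
#'
#' @param string_scores,semantic_scores aligned numeric score vectors over
#'   the dictionary entries (one matrix row each).
#' @param concept_ids character vector of the aligned entry concept ids.
#' @param params a [combiner_params()] (linear family).
#' @param k pool size (default 20, the mined-recommendation count used in
#'   combiner training); a k beyond the dictionary size is truncated with a
#'   warning.
#' @param gold optional character vector of gold concept ids.
#' @param terms optional aligned character vector of entry terms.
#' @param query_id optional id carried on the pool.
#' @return an object of class `candidate_pool`: list with `query_id`,
#'   `candidates` (tibble: `rank`, `position`, `concept_id`, `term`,
#'   `s_string`, `s_semantic`, `s_combined`, `is_positive`), and `k`.
#' @export
mine_candidates <- function(string_scores, semantic_scores, concept_ids,
                            params = combiner_params("linear"), k = 20,
                            gold = NULL, terms = NULL, query_id = NA_character_) {
  n <- length(concept_ids)
  stopifnot(
    length(string_scores) == n, length(semantic_scores) == n,
    k >= 1L
  )
  if (k > n) {
    warning("candidate pool truncated from k = ", k, " to dictionary size ", n,
      call. = FALSE
    )
    k <- n
  }
  combined <- combine_linear(semantic_scores, string_scores, params)
  ord <- order(-combined, seq_len(n))[seq_len(k)]
  is_positive <- if (is.null(gold)) {
    rep(NA, k)
  } else {
    concept_ids[ord] %in% gold
  }
  structure(
    list(
      query_id = query_id,
      candidates = tibble::tibble(
        rank = seq_len(k),
        position = ord,
        concept_id = concept_ids[ord],
        term = if (is.null(terms)) NA_character_ else terms[ord],
        s_string = string_scores[ord],
        s_semantic = semantic_scores[ord],
        s_combined = combined[ord],
        is_positive = is_positive
      ),
      k = as.integer(k)
    ),
    class = "candidate_pool"
  )
}

#' Marginal probability of positive candidates in a pool
#'
#' Softmax over the pool's combined scores under the given parameters,
#' summed over the positive (synonymous) candidates:
#' `P'(q) = sum_{i positive} exp(S_i) / sum_j exp(S_j)`, computed max-shifted
#' for numerical stability. Requires labeled candidates with at least one
#' positive -- pools without a positive are excluded upstream, because their
#' log-probability is unbounded below.
#'
#' @param pool a labeled [mine_candidates()] pool.
#' @param params a [combiner_params()] (linear family).
#' @return a number in `(0, 1]`.
#' @export
marginal_probability <- function(pool, params) {
  stopifnot(inherits(pool, "candidate_pool"))
  cand <- pool$candidates
  if (anyNA(cand$is_positive)) {
    stop("candidate pool is unlabeled (is_positive not set)", call. = FALSE)
  }
  if (!any(cand$is_positive)) {
    stop("candidate pool contains no positive candidate", call. = FALSE)
  }
  s <- combine_linear(cand$s_semantic, cand$s_string, params)
  w <- exp(s - max(s))
  p <- w / sum(w)
  sum(p[cand$is_positive])
}

#' Marginal-probability training loss
#'
#' The negative mean log marginal probability over a collection of labeled
#' candidate pools: `-(1/Q) * sum_q log P'(q)`. Finite whenever every pool
#' contains at least one positive.
#'
#' @param pools non-empty list of labeled [mine_candidates()] pools.
#' @param params a [combiner_params()] (linear family).
#' @return a nonnegative number.
#' @export
marginal_loss <- function(pools, params) {
  if (length(pools) == 0L) stop("empty pool collection", call. = FALSE)
  -mean(vapply(pools, function(p) log(marginal_probability(p, params)), numeric(1)))
}

#' Analytic gradient of the marginal loss
#'
#' Closed-form gradient of [marginal_loss()] with respect to `(alpha, beta)`.
#' With softmax weights `p_i` and per-candidate channel scores `a_i`
#' (semantic) and `b_i` (string), for each pool
#' `dP'/dalpha = sum_{i positive} p_i * (a_i - abar)` where
#' `abar = sum_j p_j a_j`, and
#' `dLoss/dalpha = -(1/Q) sum_q (1/P') dP'/dalpha` (same for beta with `b`).
#'
#' @inheritParams marginal_loss
#' @return named numeric vector `c(alpha = ..., beta = ...)`.
#' @export
marginal_loss_gradient <- function(pools, params) {
  if (length(pools) == 0L) stop("empty pool collection", call. = FALSE)
  grads <- vapply(pools, function(pool) {
    cand <- pool$candidates
    a <- cand$s_semantic
    b <- cand$s_string
    pos <- cand$is_positive
    s <- params$alpha * a + params$beta * b
    w <- exp(s - max(s))
    p <- w / sum(w)
    pprime <- sum(p[pos])
    abar <- sum(p * a)
    bbar <- sum(p * b)
    c(
      sum(p[pos] * (a[pos] - abar)) / pprime,
      sum(p[pos] * (b[pos] - bbar)) / pprime
    )
  }, numeric(2))
  -c(alpha = mean(grads[1, ]), beta = mean(grads[2, ]))
}
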