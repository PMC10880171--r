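#' Map queries to ranked dictionary concepts
#'
#' Runs the end-to-end normalization pipeline for one strategy:
#'
#' 1. build each query's variant set -- its stored translation variants if
#'    present, else translations mined from the providers, else the surface
#'    alone (a query ending up with zero variants falls back to its surface
#'    with a warning);
#' 2. score every variant against every dictionary entry on both channels
#'    and take, per channel, the maximum over variants (adding variants can
#'    therefore never lower a candidate's channel score);
#' 3. fuse the channels: linear-family schemes use
#'    `alpha * semantic + beta * string` on the raw cosines; `zscore` /
#'    `minmax` / `tanh` normalize each channel per query over the dictionary
#'    and sum them (unit weights unless `weighted = TRUE`);
#' 4. rank by fused score, ties broken by dictionary position, collapse
#'    duplicate concept ids to their best-ranked term so that "top n" counts
#'    distinct concepts (`dedup_concepts = FALSE` preserves the raw
#'    term-row reading), and report the top `n_max`.
#'
#' When a query carries gold ids, `hit_rank` is the smallest rank whose
#' concept id is in the gold set, or `NA` when the gold concept is not within
#' the top `n_max`.
#'
#' @param queries a [query_set()] tibble.
#' @param dictionary a [term_dictionary()].
#' @param encoder a [fit_tfidf()] encoder fitted on `dictionary`.
#' @param embedder a [dense_embedder()].
#' @param params a [combiner_params()].
#' @param providers optional list of [translation_provider()]s used for
#'   queries without stored variants.
#' @param n_max number of candidates returned per query (default 10).
#' @param dedup_concepts collapse duplicate concepts before ranking
#'   (default `TRUE`).
#' @param weighted apply `alpha`/`beta` after normalization for the
#'   normalization schemes (default `FALSE`: unit weights).
#' @return a tibble of class `mapping_results`, one row per query:
#'   `query_id`, `hit_rank`, `has_gold`, and `ranked` (list of per-candidate
#'   tibbles: `rank`, `concept_id`, `term`, `s_string`, `s_semantic`,
#'   `s_combined`).
#' @export
map_entities <- function(queries, dictionary, encoder, embedder, params,
                         providers = NULL, n_max = 10,
                         dedup_concepts = TRUE, weighted = FALSE) {
  stopifnot(
    inherits(dictionary, "term_dictionary"),
    inherits(encoder, "sparse_encoder"),
    inherits(embedder, "dense_embedder"),
    inherits(params, "combiner_params")
  )
  n_max <- as.integer(n_max)
  if (n_max < 1L) stop("n_max must be >= 1", call. = FALSE)
  nq <- nrow(queries)
  variants <- lapply(seq_len(nq), function(i) {
    v <- queries$translations[[i]]
    if (length(v) == 0L && !is.null(providers)) {
      v <- tryCatch(
        unify_translations(queries$surface[i], providers)$text,
        error = function(e) character(0)
      )
    }
    if (length(v) == 0L) {
      warning("query ", queries$query_id[i],
        " has no translation variants; falling back to its surface",
        call. = FALSE
      )
      v <- queries$surface[i]
    }
    v
  })
  all_texts <- unique(unlist(variants, use.names = FALSE))
  s_str_all <- sparse_score_matrix(encoder, all_texts, dictionary)
  s_sem_all <- semantic_score_matrix(embedder, all_texts, dictionary)
  cids <- dictionary$entries$concept_id
  terms <- dictionary$entries$term
  nd <- length(cids)
  rows <- lapply(seq_len(nq), function(i) {
    at <- match(variants[[i]], all_texts)
    if (length(at) == 1L) {
      str_row <- s_str_all[at, ]
      sem_row <- s_sem_all[at, ]
    } else {
      str_row <- as.vector(Reduce(pmax, asplit(s_str_all[at, , drop = FALSE], 1L)))
      sem_row <- as.vector(Reduce(pmax, asplit(s_sem_all[at, , drop = FALSE], 1L)))
    }
    if (params$scheme %in% c("linear", "string_only", "semantic_only")) {
      comb <- combine_linear(sem_row, str_row, params)
    } else {
      zs <- normalize_channel(str_row, params$scheme)
      zd <- normalize_channel(sem_row, params$scheme)
      comb <- if (weighted) params$alpha * zd + params$beta * zs else zd + zs
    }
    ord <- order(-comb, seq_len(nd))
    if (dedup_concepts) ord <- ord[!duplicated(cids[ord])]
    top <- utils::head(ord, n_max)
    gold <- queries$gold_concept_ids[[i]]
    has_gold <- length(gold) > 0L
    hit_rank <- NA_integer_
    if (has_gold) {
      hits <- which(cids[top] %in% gold)
      if (length(hits) > 0L) hit_rank <- hits[1]
    }
    list(
      hit_rank = hit_rank,
      has_gold = has_gold,
      ranked = tibble::tibble(
        rank = seq_along(top),
        concept_id = cids[top],
        term = terms[top],
        s_string = unname(str_row[top]),
        s_semantic = unname(sem_row[top]),
        s_combined = unname(comb[top])
      )
    )
  })
  out <- tibble::tibble(
    query_id = queries$query_id,
    hit_rank = vapply(rows, `[[`, integer(1), "hit_rank"),
    has_gold = vapply(rows, `[[`, logical(1), "has_gold"),
    ranked = lapply(rows, `[[`, "ranked")
  )
  class(out) <- c("mapping_results", class(out))
  out
}

#' Top-n accuracy (Acc\@n)
#'
#' The percentage of queries whose gold concept appears among the top `n`
#' ranked candidates: `Acc@n = 100 * TP_n / N`, where `TP_n` counts queries
#' with `hit_rank <= n`. Non-decreasing in `n` by construction.
#'
#' @param results a [map_entities()] result whose queries all carried gold
#'   labels.
#' @param n rank threshold (>= 1; at most the `n_max` used in mapping).
#' @return a percentage in `[0, 100]`.
#' @examples
#' \dontrun{
#' acc_at_n(results, 5)
#' }
#' @export
acc_at_n <- function(results, n) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("empty result collection", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!all(results$has_gold)) {
    stop("Acc@n requires gold labels on every query", call. = FALSE)
  }
  100 * sum(!is.na(results$hit_rank) & results$hit_rank <= n) / nrow(results)
}

#' McNemar paired significance test
#'
#' Compares two systems on the same queries through their discordant
#' outcomes: `b` queries correct under A only, `c` correct under B only.
#' With fewer than 25 discordant pairs an exact two-sided binomial test on
#' `(b, b + c, 1/2)` is used; otherwise the continuity-corrected chi-square
#' statistic `(|b - c| - 1)^2 / (b + c)` with 1 degree of freedom. No
#' discordance at all gives `p = 1` and no statistic.
#'
#' @param hits_a,hits_b logical vectors of per-query correctness, aligned.
#' @return an object of class `mcnemar_result`: list with `b`, `c`,
#'   `statistic` (chi-square value or `NA`), `p_value`, `method`
#'   (`"exact_binomial"` or `"chi2_corrected"`).
#' @export
mcnemar_test <- function(hits_a, hits_b) {
  stopifnot(
    is.logical(hits_a), is.logical(hits_b),
    length(hits_a) == length(hits_b), !anyNA(hits_a), !anyNA(hits_b)
  )
  b <- sum(hits_a & !hits_b)
  c_ <- sum(!hits_a & hits_b)
  if (b + c_ == 0L) {
    res <- list(
      b = b, c = c_, statistic = NA_real_, p_value = 1,
      method = "exact_binomial"
    )
  } else if (b + c_ < 25L) {
    res <- list(
      b = b, c = c_, statistic = NA_real_,
      p_value = stats::binom.test(b, b + c_, p = 0.5)$p.value,
      method = "exact_binomial"
    )
  } else {
    stat <- (abs(b - c_) - 1)^2 / (b + c_)
    res <- list(
      b = b, c = c_, statistic = stat,
      p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      method = "chi2_corrected"
    )
  }
  structure(res, class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf(
    "<mcnemar_result> b = %d, c = %d, %s, p = %.4g\n",
    x$b, x$c, x$method, x$p_value
  ))
  invisible(x)
}

#' Strategy comparison report
#'
#' Runs [map_entities()] on a benchmark for each configured strategy,
#' tabulates Acc\@1/5/10, and tests each strategy against a declared baseline
#' with [mcnemar_test()] on the Acc\@1 hit vectors. Optionally written as a
#' UTF-8 TSV with a commented header, reproducible byte-for-byte at a fixed
#' seed.
#'
#' @param benchmark a [generate_benchmark()] result (or any list with
#'   `dictionary`, `queries`, `dense_vectors`).
#' @param strategies named list of [combiner_params()], one per report row.
#' @param baseline name of the baseline strategy (default: the first).
#' @param n_values,dialect encoder settings (see [fit_tfidf()]).
#' @param n_max candidates ranked per query.
#' @param path optional output TSV path.
#' @return a tibble: `strategy`, `acc1`, `acc5`, `acc10`, `mcnemar_p`
#'   (`NA` for the baseline row), plus the raw results in attribute
#'   `"results"`.
#' @export
strategy_report <- function(benchmark, strategies,
                            baseline = names(strategies)[1],
                            n_values = 3, dialect = "paper", n_max = 10,
                            path = NULL) {
  if (length(strategies) < 1L || is.null(names(strategies))) {
    stop("strategies must be a non-empty named list", call. = FALSE)
  }
  if (!baseline %in% names(strategies)) {
    stop("unknown baseline strategy: ", baseline, call. = FALSE)
  }
  encoder <- fit_tfidf(benchmark$dictionary, n_values = n_values, dialect = dialect)
  embedder <- vector_embedder(benchmark$dense_vectors)
  results <- lapply(strategies, function(p) {
    map_entities(benchmark$queries, benchmark$dictionary, encoder, embedder,
      params = p, n_max = n_max
    )
  })
  hits1 <- lapply(results, function(r) !is.na(r$hit_rank) & r$hit_rank <= 1L)
  tab <- tibble::tibble(
    strategy = names(strategies),
    acc1 = unname(vapply(results, acc_at_n, numeric(1), n = 1)),
    acc5 = unname(vapply(results, acc_at_n, numeric(1), n = min(5L, n_max))),
    acc10 = unname(vapply(results, acc_at_n, numeric(1), n = min(10L, n_max))),
    mcnemar_p = unname(vapply(names(strategies), function(s) {
      if (s == baseline) {
        NA_real_
      } else {
        mcnemar_test(hits1[[baseline]], hits1[[s]])$p_value
      }
    }, numeric(1)))
  )
  if (!is.null(path)) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0(
      "# strategy report; baseline = ", baseline,
      "; columns: strategy acc1 acc5 acc10 mcnemar_p"
    ), con)
    utils::write.table(tab, con,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  attr(tab, "results") <- results
  tab
}

#' Per-query channel score matrices
#'
#' Computes the two channel score matrices the trainer and evaluator consume:
#' row `i`, column `j` is the similarity between query `i` and dictionary
#' entry `j`, maximized over the query's translation variants (its surface
#' when it has none) -- the same variant reduction [map_entities()] applies.
#'
#' @param queries a [query_set()] tibble.
#' @param dictionary a [term_dictionary()].
#' @param encoder a [fit_tfidf()] encoder fitted on `dictionary`.
#' @param embedder a [dense_embedder()].
#' @return list with numeric matrices `string` and `semantic`
#'   (`nrow(queries)` x `length(dictionary)`).
#' @export
channel_score_matrices <- function(queries, dictionary, encoder, embedder) {
  stopifnot(
    inherits(dictionary, "term_dictionary"),
    inherits(encoder, "sparse_encoder"),
    inherits(embedder, "dense_embedder")
  )
  variants <- lapply(seq_len(nrow(queries)), function(i) {
    v <- queries$translations[[i]]
    if (length(v) == 0L) queries$surface[i] else v
  })
  all_texts <- unique(unlist(variants, use.names = FALSE))
  s_str <- sparse_score_matrix(encoder, all_texts, dictionary)
  s_sem <- semantic_score_matrix(embedder, all_texts, dictionary)
  reduce <- function(m) {
    rows <- lapply(variants, function(v) {
      at <- match(v, all_texts)
      if (length(at) == 1L) {
        m[at, ]
      } else {
        as.vector(Reduce(pmax, asplit(m[at, , drop = FALSE], 1L)))
      }
    })
    out <- do.call(rbind, rows)
    dimnames(out) <- NULL
    out
  }
  list(string = reduce(s_str), semantic = reduce(s_sem))
}
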