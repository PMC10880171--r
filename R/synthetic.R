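#' Synthetic benchmark configuration
#'
#' The generator emulates the computational structure of a cross-lingual
#' normalization study without any download: a synonym-rich disorder-style
#' concept dictionary over pseudo-words, queries whose "translation variants"
#' are noisy aliases of a gold concept's term (round-trip translation noise
#' modeled as character/token edits), and concept-level latent dense vectors
#' in which synonyms form packed clusters (the behavior a
#' self-aligned language-model embedder exhibits).
#'
#' `channel_mode` controls which channel carries signal:
#' * `"both"`: string and semantic channels are both informative;
#' * `"string_only"`: query-side dense vectors are replaced by fresh random
#'   unit vectors (semantic channel uninformative);
#' * `"semantic_only"`: query variants are replaced by random strings
#'   (string channel uninformative).
#'
#' @param n_concepts number of concepts (default 500).
#' @param synonyms_per_concept dictionary terms per concept (default 3).
#' @param n_queries number of labeled queries (default 400).
#' @param string_noise per-character edit rate in `[0, 1]` (default 0.15).
#' @param variant_count translation variants per query (default 2).
#' @param semantic_noise sd of the latent perturbation (default 0.3).
#' @param channel_mode `"both"`, `"string_only"`, or `"semantic_only"`.
#' @param dim latent dimension (default 64).
#' @param seed integer master seed; all generator randomness flows from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_concepts = 500, synonyms_per_concept = 3,
                             n_queries = 400, string_noise = 0.15,
                             variant_count = 2, semantic_noise = 0.3,
                             channel_mode = c("both", "string_only", "semantic_only"),
                             dim = 64, seed = 1) {
  channel_mode <- match.arg(channel_mode)
  n_concepts <- as.integer(n_concepts)
  synonyms_per_concept <- as.integer(synonyms_per_concept)
  n_queries <- as.integer(n_queries)
  variant_count <- as.integer(variant_count)
  dim <- as.integer(dim)
  seed <- as.integer(seed)
  stopifnot(
    n_concepts >= 2L, synonyms_per_concept >= 1L, n_queries >= 1L,
    string_noise >= 0, string_noise <= 1, variant_count >= 1L,
    semantic_noise >= 0, dim >= 2L, abs(seed) < 2147483000L
  )
  structure(
    list(
      n_concepts = n_concepts, synonyms_per_concept = synonyms_per_concept,
      n_queries = n_queries, string_noise = as.numeric(string_noise),
      variant_count = variant_count, semantic_noise = as.numeric(semantic_noise),
      channel_mode = channel_mode, dim = dim, seed = seed
    ),
    class = "synthetic_config"
  )
}

# 20-letter alphabet used for all pseudo-words
synth_alphabet <- function() letters[1:20]

# one pseudo-term: 2-4 words of 4-8 letters
random_term <- function() {
  n_words <- sample(2:4, 1L)
  words <- vapply(seq_len(n_words), function(i) {
    paste(sample(synth_alphabet(), sample(4:8, 1L), replace = TRUE), collapse = "")
  }, character(1))
  paste(words, collapse = " ")
}

# seeded edit perturbation: per-character substitution, adjacent-token swap,
# and short affix, each governed by `rate`; rate 0 is the identity
perturb_string <- function(text, rate) {
  if (rate <= 0) {
    return(text)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate & chars != " "
  if (any(hit)) {
    chars[hit] <- sample(synth_alphabet(), sum(hit), replace = TRUE)
  }
  toks <- strsplit(paste(chars, collapse = ""), " ", fixed = TRUE)[[1]]
  if (length(toks) >= 2L && stats::runif(1) < rate) {
    j <- sample(length(toks) - 1L, 1L)
    toks[c(j, j + 1L)] <- toks[c(j + 1L, j)]
  }
  if (stats::runif(1) < rate) {
    j <- sample(length(toks), 1L)
    affix <- paste(sample(synth_alphabet(), sample(2:3, 1L), replace = TRUE),
      collapse = ""
    )
    toks[j] <- paste0(toks[j], affix)
  }
  paste(toks, collapse = " ")
}

#' Generate a synthetic concept dictionary
#'
#' Each concept gets a random base term (pseudo-words over a 20-letter
#' alphabet) and `synonyms_per_concept` surface variants produced by seeded
#' edit operations at rate `string_noise`; all variants share the concept id.
#' With `string_noise = 0` every synonym equals its base and the dictionary
#' collapses to one entry per concept. Deterministic given the config.
#'
#' @param config a [synthetic_config()].
#' @return a [term_dictionary()].
#' @export
generate_dictionary <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    bases <- vapply(seq_len(config$n_concepts), function(i) random_term(), character(1))
    rows <- lapply(seq_len(config$n_concepts), function(i) {
      terms <- vapply(seq_len(config$synonyms_per_concept), function(j) {
        if (j == 1L) bases[i] else perturb_string(bases[i], config$string_noise)
      }, character(1))
      data.frame(
        concept_id = sprintf("C%05d", i), term = terms,
        language = "und", source = "synthetic",
        semantic_group = "Disorders", stringsAsFactors = FALSE
      )
    })
    term_dictionary(do.call(rbind, rows))
  })
}

#' Generate labeled synthetic queries
#'
#' Each query picks a concept uniformly at random; its `variant_count`
#' translation variants are independent edit perturbations (rate
#' `string_noise`) of a randomly chosen synonym of that concept -- the
#' structure a round-trip translation induces: multiple noisy aliases of one
#' gold concept. Under `channel_mode = "semantic_only"` the variants are
#' replaced by unrelated random strings. The query surface is its first
#' variant.
#'
#' @param dictionary the dictionary from [generate_dictionary()].
#' @param config a [synthetic_config()].
#' @return a labeled [query_set()] tibble.
#' @export
generate_queries <- function(dictionary, config) {
  stopifnot(inherits(dictionary, "term_dictionary"), inherits(config, "synthetic_config"))
  cids <- names(dictionary$by_concept)
  withr::with_seed(config$seed + 1L, {
    gold <- sample(cids, config$n_queries, replace = TRUE)
    variants <- lapply(seq_len(config$n_queries), function(i) {
      made <- vapply(seq_len(config$variant_count), function(v) {
        if (config$channel_mode == "semantic_only") {
          random_term()
        } else {
          pos <- concept_positions(dictionary, gold[i])
          base <- dictionary$entries$term[pos[sample.int(length(pos), 1L)]]
          perturb_string(base, config$string_noise)
        }
      }, character(1))
      unique(made)
    })
    query_set(
      query_id = sprintf("q%05d", seq_len(config$n_queries)),
      surface = vapply(variants, `[[`, character(1), 1L),
      gold_concept_ids = as.list(gold),
      translations = variants
    )
  })
}

#' Generate concept-latent dense vectors
#'
#' Draws one latent unit vector per concept, then embeds every dictionary
#' term and every query variant as `latent(concept) + N(0, semantic_noise)`,
#' l2-normalized -- synonyms cluster around their concept, distinct concepts
#' are near-orthogonal at moderate `dim`. Under
#' `channel_mode = "string_only"` query-side texts instead get fresh random
#' unit vectors (no concept signal). The table is keyed by text; a query
#' variant whose text exactly matches a dictionary term keeps the
#' dictionary-side vector, since an embedder is a function of the text.
#'
#' @param dictionary,queries generator outputs.
#' @param config a [synthetic_config()].
#' @return numeric matrix with term rownames, consumable by
#'   [vector_embedder()] / [write_dense_vectors()].
#' @export
generate_dense_vectors <- function(dictionary, queries, config) {
  stopifnot(inherits(dictionary, "term_dictionary"), inherits(config, "synthetic_config"))
  cids <- names(dictionary$by_concept)
  unit <- function(v) v / sqrt(sum(v^2))
  withr::with_seed(config$seed + 2L, {
    latents <- lapply(cids, function(id) unit(stats::rnorm(config$dim)))
    names(latents) <- cids
    keys <- character(0)
    vecs <- list()
    put <- function(key, vec) {
      if (!key %in% keys) {
        keys[[length(keys) + 1L]] <<- key
        vecs[[length(vecs) + 1L]] <<- vec
      }
    }
    ent <- dictionary$entries
    for (i in seq_len(nrow(ent))) {
      put(
        ent$term[i],
        unit(latents[[ent$concept_id[i]]] + stats::rnorm(config$dim, 0, config$semantic_noise))
      )
    }
    for (i in seq_len(nrow(queries))) {
      gold <- queries$gold_concept_ids[[i]][1]
      for (v in queries$translations[[i]]) {
        if (config$channel_mode == "string_only") {
          put(v, unit(stats::rnorm(config$dim)))
        } else {
          put(v, unit(latents[[gold]] + stats::rnorm(config$dim, 0, config$semantic_noise)))
        }
      }
    }
    m <- do.call(rbind, vecs)
    rownames(m) <- keys
    m
  })
}

#' Generate a full synthetic benchmark
#'
#' Bundles [generate_dictionary()], [generate_queries()] and
#' [generate_dense_vectors()] under one config. Regeneration from the same
#' config is bit-identical, and every query's gold id exists in the
#' dictionary by construction.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_benchmark`: list with `dictionary`,
#'   `queries`, `dense_vectors`, and a `config` echo.
#' @export
generate_benchmark <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  dictionary <- generate_dictionary(config)
  queries <- generate_queries(dictionary, config)
  dense_vectors <- generate_dense_vectors(dictionary, queries, config)
  structure(
    list(
      dictionary = dictionary, queries = queries,
      dense_vectors = dense_vectors, config = config
    ),
    class = "synthetic_benchmark"
  )
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf(
    "<synthetic_benchmark> %d concepts / %d entries, %d queries, dim %d, mode %s, seed %d\n",
    length(x$dictionary$by_concept), length(x$dictionary),
    nrow(x$queries), x$config$dim, x$config$channel_mode, x$config$seed
  ))
  invisible(x)
}

#' Write a benchmark to a directory
#'
#' Emits the file set every other pipeline stage consumes unchanged:
#' `dictionary.tsv`, `queries.jsonl`, `vectors.tsv` (dense-vector file), and
#' `config.json`.
#'
#' @param benchmark a [generate_benchmark()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "synthetic_benchmark"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_dictionary_tsv(benchmark$dictionary, file.path(dir, "dictionary.tsv"))
  write_queries_jsonl(benchmark$queries, file.path(dir, "queries.jsonl"))
  write_dense_vectors(benchmark$dense_vectors, file.path(dir, "vectors.tsv"))
  jsonlite::write_json(unclass(benchmark$config), file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
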