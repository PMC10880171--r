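#' Combiner training configuration
#'
#' Settings for the 2-parameter linear-combiner fit. The objective has only
#' `alpha` and `beta` as trainable parameters, so full-batch gradient descent
#' with closed-form gradients is used; no stochastic machinery is needed and
#' runs are deterministic.
#'
#' @param k candidate pool size mined per query (default 20).
#' @param epochs number of gradient steps (default 100).
#' @param learning_rate step size (default 0.5).
#' @param seed integer seed echoed into outputs (the fit itself is
#'   deterministic).
#' @param init_alpha,init_beta initial weights (default 1, 1).
#' @param remine_every epochs between candidate re-mining under the current
#'   parameters (default 1: re-mine each epoch, iterative hard-candidate
#'   mining).
#' @return an object of class `train_config`.
#' @export
train_config <- function(k = 20, epochs = 100, learning_rate = 0.5, seed = 1,
                         init_alpha = 1, init_beta = 1, remine_every = 1) {
  k <- as.integer(k)
  epochs <- as.integer(epochs)
  remine_every <- as.integer(remine_every)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (!is.finite(learning_rate) || learning_rate <= 0) {
    stop("learning_rate must be > 0", call. = FALSE)
  }
  if (remine_every < 1L) stop("remine_every must be >= 1", call. = FALSE)
  structure(
    list(
      k = k, epochs = epochs, learning_rate = as.numeric(learning_rate),
      seed = as.integer(seed), init_alpha = as.numeric(init_alpha),
      init_beta = as.numeric(init_beta), remine_every = remine_every
    ),
    class = "train_config"
  )
}

# top-k column indices per row of a score matrix, stable ties by column
top_k_rows <- function(m, k) {
  t(apply(m, 1L, function(r) order(-r, seq_along(r))[seq_len(k)]))
}

#' Train the linear combiner on labeled queries
#'
#' Optimizes `(alpha, beta)` of the fused score
#' `alpha * S_semantic + beta * S_string` by minimizing the
#' marginal-probability loss over mined top-k candidate pools:
#'
#' 1. start from `(init_alpha, init_beta)`;
#' 2. every `remine_every` epochs, re-mine each query's top-k pool under the
#'    current parameters and drop pools containing no gold concept (their
#'    count is reported; their loss would be unbounded);
#' 3. take one full-batch gradient step per epoch using the closed-form
#'    gradient ([marginal_loss_gradient()]).
#'
#' The per-epoch loss (evaluated before each step, under the pools current at
#' that epoch) is returned as the loss history.
#'
#' @param queries a labeled [query_set()]; every query must have at least one
#'   gold concept id present in the dictionary.
#' @param dictionary the [term_dictionary()] the score matrices are aligned
#'   to.
#' @param string_matrix,semantic_matrix numeric matrices,
#'   `nrow = nrow(queries)`, `ncol = length(dictionary)` -- per-query channel
#'   scores (already max-reduced over translation variants if applicable).
#' @param config a [train_config()].
#' @return an object of class `combiner_fit`: list with `params` (a
#'   [combiner_params()] of scheme `linear`), `loss_history`, `n_pools`,
#'   `n_dropped` (pools without a positive at the last mining), and `config`.
#' @export
train_combiner <- function(queries, dictionary, string_matrix, semantic_matrix,
                           config = train_config()) {
  stopifnot(
    inherits(dictionary, "term_dictionary"),
    inherits(config, "train_config"),
    is.matrix(string_matrix), is.matrix(semantic_matrix)
  )
  nq <- nrow(queries)
  nd <- length(dictionary)
  stopifnot(
    nrow(string_matrix) == nq, ncol(string_matrix) == nd,
    nrow(semantic_matrix) == nq, ncol(semantic_matrix) == nd
  )
  cids <- dictionary$entries$concept_id
  pos_full <- t(vapply(
    queries$gold_concept_ids,
    function(g) cids %in% g, logical(nd)
  ))
  no_gold <- rowSums(pos_full) == 0
  if (any(no_gold)) {
    stop(
      sum(no_gold), " training quer(ies) have no gold concept present in ",
      "the dictionary (first: ", queries$query_id[which(no_gold)[1]], ")",
      call. = FALSE
    )
  }
  k <- min(config$k, nd)
  if (k < config$k) {
    warning("candidate pool size truncated from ", config$k,
      " to dictionary size ", nd,
      call. = FALSE
    )
  }
  alpha <- config$init_alpha
  beta <- config$init_beta
  loss_history <- numeric(config$epochs)
  a_mat <- b_mat <- pos_mat <- NULL
  n_dropped <- NA_integer_
  for (epoch in seq_len(config$epochs)) {
    if (epoch == 1L || (epoch - 1L) %% config$remine_every == 0L) {
      comb <- alpha * semantic_matrix + beta * string_matrix
      topk <- top_k_rows(comb, k)
      flat <- cbind(rep(seq_len(nq), times = k), as.vector(topk))
      a_all <- matrix(semantic_matrix[flat], nq, k)
      b_all <- matrix(string_matrix[flat], nq, k)
      p_all <- matrix(pos_full[flat], nq, k)
      keep <- rowSums(p_all) > 0
      n_dropped <- sum(!keep)
      if (!any(keep)) {
        stop("every mined candidate pool is positive-free; ",
          "k may be too small or labels inconsistent",
          call. = FALSE
        )
      }
      a_mat <- a_all[keep, , drop = FALSE]
      b_mat <- b_all[keep, , drop = FALSE]
      pos_mat <- p_all[keep, , drop = FALSE]
    }
    s <- alpha * a_mat + beta * b_mat
    s <- s - apply(s, 1L, max)
    p <- exp(s)
    p <- p / rowSums(p)
    pprime <- rowSums(p * pos_mat)
    loss_history[epoch] <- -mean(log(pprime))
    d_alpha <- rowSums(p * pos_mat * a_mat) - pprime * rowSums(p * a_mat)
    d_beta <- rowSums(p * pos_mat * b_mat) - pprime * rowSums(p * b_mat)
    g_alpha <- -mean(d_alpha / pprime)
    g_beta <- -mean(d_beta / pprime)
    alpha <- alpha - config$learning_rate * g_alpha
    beta <- beta - config$learning_rate * g_beta
  }
  structure(
    list(
      params = combiner_params("linear", alpha = alpha, beta = beta),
      loss_history = loss_history,
      n_pools = nrow(a_mat),
      n_dropped = n_dropped,
      config = config
    ),
    class = "combiner_fit"
  )
}

#' @export
print.combiner_fit <- function(x, ...) {
  cat(sprintf(
    "<combiner_fit> alpha = %.4f, beta = %.4f; loss %.4f -> %.4f over %d epochs (%d pools, %d dropped)\n",
    x$params$alpha, x$params$beta,
    x$loss_history[1], x$loss_history[length(x$loss_history)],
    length(x$loss_history), x$n_pools, x$n_dropped
  ))
  invisible(x)
}

#' Save / read trained combiner parameters
#'
#' A small JSON key-value document storing the scheme, weights, a config
#' echo, and the loss trace; consumed by the mapping/evaluation layer.
#'
#' @param fit a [train_combiner()] result (or bare [combiner_params()]).
#' @param path file path.
#' @return `path` (write) / a list with `params` and any stored metadata
#'   (read).
#' @export
write_combiner_params <- function(fit, path) {
  if (inherits(fit, "combiner_params")) {
    fit <- list(params = fit, loss_history = numeric(0), config = NULL)
  }
  stopifnot(inherits(fit, "combiner_fit") || !is.null(fit$params))
  doc <- list(
    format = "termlink_combiner_params",
    version = 1L,
    scheme = fit$params$scheme,
    alpha = fit$params$alpha,
    beta = fit$params$beta,
    loss_history = fit$loss_history,
    config = if (is.null(fit$config)) NULL else unclass(fit$config)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_combiner_params
#' @export
read_combiner_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "termlink_combiner_params")) {
    stop("not a combiner-params file: ", path, call. = FALSE)
  }
  list(
    params = combiner_params(doc$scheme, alpha = doc$alpha, beta = doc$beta),
    loss_history = as.numeric(doc$loss_history),
    config = doc$config
  )
}
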