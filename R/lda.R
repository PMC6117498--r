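# Collapsed-Gibbs LDA and labeled-LDA.
#
# Both models share one sampler: labeled-LDA restricts each document's topic
# support to its label set, so plain LDA is the special case where every
# document allows all K topics. Under a shared seed the two then produce
# bit-identical assignment trajectories when every label set is full.

as_bow_input <- function(data, vocab, min_count = 1) {
  if (is.data.frame(data)) {
    if (!"tokens" %in% names(data)) abort("corpus has no tokens column")
    vocab <- vocab %||% build_vocabulary(data, min_count = min_count)
    list(bow = docs_to_bow(data, vocab), vocab = vocab,
         doc_ids = data$doc_id %||% as.character(seq_len(nrow(data))))
  } else {
    if (is.null(vocab)) abort("vocab must be supplied with a bag-of-words list")
    list(bow = lapply(data, as.integer), vocab = vocab,
         doc_ids = names(data) %||% as.character(seq_along(data)))
  }
}

run_gibbs <- function(bow, allowed_sets, K, V, alpha, beta, iterations,
                      burn_in, sample_lag, seed, average, check_invariants) {
  if (length(bow) == 0 || sum(lengths(bow)) == 0) {
    abort("empty corpus: no in-vocabulary tokens")
  }
  if (!is.null(seed)) set.seed(seed)
  docs0 <- lapply(bow, function(x) as.integer(x) - 1L)
  allowed0 <- lapply(allowed_sets, function(x) as.integer(x) - 1L)
  gibbs_lda_cpp(docs0, allowed0, as.integer(K), as.integer(V), alpha, beta,
                as.integer(iterations), as.integer(burn_in),
                as.integer(sample_lag), average, check_invariants)
}

new_lda_fit <- function(res, method, K, V, alpha, beta, iterations, burn_in,
                        sample_lag, seed, average, vocab, doc_ids,
                        topic_labels, bow) {
  theta <- res$theta
  phi <- res$phi
  dimnames(theta) <- list(doc_ids, topic_labels)
  dimnames(phi) <- list(topic_labels, vocab$token)
  structure(
    list(method = method, K = K, V = V, alpha = alpha, beta = beta,
         iterations = iterations, burn_in = burn_in, sample_lag = sample_lag,
         seed = seed, average = average, vocab = vocab, doc_ids = doc_ids,
         topic_labels = topic_labels, bow = bow,
         z = lapply(res$z, function(x) x + 1L),
         n_dk = res$n_dk, n_kw = res$n_kw, n_k = res$n_k,
         theta = theta, phi = phi, n_samples = res$n_samples),
    class = "lda_fit"
  )
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Standard collapsed Gibbs sampler: topic assignments are resampled from
#' `p(z_i = k | .) ~ (n_dk + alpha) (n_kw + beta) / (n_k + V beta)`, sweeping
#' documents in corpus order and tokens in sequence order so runs are
#' reproducible under `seed`. Theta and phi are Rao-Blackwellized count
#' estimates, by default averaged over post-burn-in samples taken every
#' `sample_lag` sweeps.
#'
#' @param data a review corpus tibble with `tokens`, or a list of 1-based
#'   bag-of-words index vectors (then `vocab` is required).
#' @param K number of topics (>= 2).
#' @param vocab optional [build_vocabulary()] result; built from the corpus
#'   with `min_count` when missing.
#' @param alpha symmetric document-topic prior; default `50 / K`.
#' @param beta symmetric topic-word prior; default 0.01.
#' @param iterations,burn_in,sample_lag Gibbs schedule; defaults 1000 / 500 /
#'   10.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param average average theta/phi over post-burn-in samples (default) or
#'   use the final sweep's counts.
#' @param min_count vocabulary threshold when `vocab` is built here.
#' @param check_invariants verify count conservation after every sweep
#'   (debugging aid; slows the sampler).
#' @return An object of class `"lda_fit"` with elements `theta` (M x K),
#'   `phi` (K x V), final counts, per-token assignments `z`, and the sampler
#'   settings. Methods: [tidy.lda_fit()], [glance.lda_fit()],
#'   [autoplot.lda_fit()], [top_words()].
#' @examples
#' corp <- generate_corpus(generator_config(L = 2, vocab_size = 30,
#'                                          group_sizes = c(g = 20),
#'                                          doc_length_mean = 15, seed = 1))
#' fit <- fit_lda(corp$corpus, K = 2, iterations = 50, burn_in = 25, seed = 1)
#' glance(fit)
#' @export
fit_lda <- function(data, K, vocab = NULL, alpha = 50 / K, beta = 0.01,
                    iterations = 1000, burn_in = 500, sample_lag = 10,
                    seed = NULL, average = TRUE, min_count = 1,
                    check_invariants = FALSE) {
  if (K < 2) abort("K must be >= 2")
  inp <- as_bow_input(data, vocab, min_count)
  V <- inp$vocab$V
  allowed <- rep(list(seq_len(K)), length(inp$bow))
  res <- run_gibbs(inp$bow, allowed, K, V, alpha, beta, iterations, burn_in,
                   sample_lag, seed, average, check_invariants)
  new_lda_fit(res, "lda", K, V, alpha, beta, iterations, burn_in, sample_lag,
              seed, average, inp$vocab, inp$doc_ids,
              as.character(seq_len(K)), inp$bow)
}

#' Fit labeled-LDA on a multi-labeled corpus
#'
#' Labeled-LDA is the generative model for multi-labeled corpora in which a
#' document's tokens may only be assigned topics from its label set, so
#' learned topics correspond one-to-one to the human taxonomy labels. The
#' topic set is the taxonomy (K = L); gold label sets provide the
#' supervision. With every document labeled with all L topics the restriction
#' is vacuous and the sampler trace is identical to [fit_lda()] under the
#' same seed.
#'
#' @param data a review corpus tibble with `tokens` and non-empty `labels`
#'   sets.
#' @param taxonomy a [load_taxonomy()] taxonomy; default the packaged
#'   nine-label one.
#' @param vocab,alpha,beta,iterations,burn_in,sample_lag,seed,average,min_count,check_invariants
#'   as in [fit_lda()] (`alpha` defaults to `50 / L`).
#' @return An `"lda_fit"` whose `topic_labels` are the taxonomy label ids.
#' @export
fit_labeled_lda <- function(data, taxonomy = NULL, vocab = NULL,
                            alpha = NULL, beta = 0.01, iterations = 1000,
                            burn_in = 500, sample_lag = 10, seed = NULL,
                            average = TRUE, min_count = 1,
                            check_invariants = FALSE) {
  taxonomy <- taxonomy %||% load_taxonomy()
  if (!is.data.frame(data) || !"labels" %in% names(data)) {
    abort("fit_labeled_lda needs a corpus with a labels column")
  }
  L <- n_labels(taxonomy)
  alpha <- alpha %||% (50 / L)
  validate_corpus(data, taxonomy = taxonomy)
  empty <- which(lengths(data$labels) == 0)
  if (length(empty) > 0) {
    abort(paste0("document with empty label set: ", data$doc_id[empty[1]]))
  }
  inp <- as_bow_input(data, vocab, min_count)
  allowed <- lapply(data$labels, function(ls) {
    sort(match(ls, taxonomy$label_id))
  })
  res <- run_gibbs(inp$bow, allowed, L, inp$vocab$V, alpha, beta, iterations,
                   burn_in, sample_lag, seed, average, check_invariants)
  new_lda_fit(res, "labeled_lda", L, inp$vocab$V, alpha, beta, iterations,
              burn_in, sample_lag, seed, average, inp$vocab, inp$doc_ids,
              taxonomy$label_id, inp$bow)
}

#' @export
print.lda_fit <- function(x, ...) {
  cat("<", if (x$method == "labeled_lda") "labeled-LDA" else "LDA",
      " fit> K = ", x$K, ", V = ", x$V, ", M = ", length(x$bow),
      "\n  alpha = ", signif(x$alpha, 3), ", beta = ", x$beta,
      ", iterations = ", x$iterations, " (burn-in ", x$burn_in,
      ", ", x$n_samples, " samples averaged)\n", sep = "")
  invisible(x)
}

#' Point estimates of theta and phi from sampler counts
#'
#' The Rao-Blackwellized estimates from a single count state:
#' `theta[d,k] = (n_dk + alpha) / (N_d + K alpha)` and
#' `phi[k,w] = (n_kw + beta) / (n_k + V beta)`. For an averaged fit this
#' recomputes the single-sample (final-state) estimate; rows always sum to 1
#' and entries are strictly positive. An empty document's theta row is the
#' prior, i.e. uniform `1/K`.
#'
#' @param fit an `"lda_fit"`.
#' @return List with `theta`, `phi` and `topic_labels`.
#' @export
estimate_theta_phi <- function(fit) {
  stopifnot(inherits(fit, "lda_fit"))
  N_d <- lengths(fit$bow)
  theta <- (fit$n_dk + fit$alpha) / (N_d + fit$K * fit$alpha)
  phi <- (fit$n_kw + fit$beta) /
    matrix(fit$n_k + fit$V * fit$beta, nrow = fit$K, ncol = fit$V)
  dimnames(theta) <- dimnames(fit$theta)
  dimnames(phi) <- dimnames(fit$phi)
  list(theta = theta, phi = phi, topic_labels = fit$topic_labels)
}

#' Fold-in inference for new documents
#'
#' Estimates topic distributions for unseen documents by Gibbs sampling with
#' the trained topic-word distributions held fixed
#' (`p(z_i = k) ~ (n_dk + alpha) phi[k, w]`). This is how unlabeled reviews
#' are classified after training. Documents that are empty or entirely
#' out-of-vocabulary get the uniform row, with a warning.
#'
#' @param fit an `"lda_fit"` (its `phi` and `vocab` are used).
#' @param newdata a review corpus with `tokens`, or a list of token vectors,
#'   or a bag-of-words list of 1-based indices into `fit$vocab`.
#' @param iterations,burn_in,sample_lag fold-in Gibbs schedule; defaults
#'   200 / 100 / 5.
#' @param seed optional seed.
#' @return Matrix of theta rows (documents x K), rows summing to 1.
#' @export
infer_theta <- function(fit, newdata, iterations = 200, burn_in = 100,
                        sample_lag = 5, seed = NULL) {
  stopifnot(inherits(fit, "lda_fit"))
  bow <- if (is.data.frame(newdata)) {
    docs_to_bow(newdata, fit$vocab)
  } else if (is.list(newdata) && all(vapply(newdata, is.character, logical(1)))) {
    docs_to_bow(newdata, fit$vocab)
  } else {
    lapply(newdata, as.integer)
  }
  if (!is.null(seed)) set.seed(seed)
  n_empty <- sum(lengths(bow) == 0)
  if (n_empty > 0) {
    warn(paste0(n_empty, " document(s) empty or fully out-of-vocabulary; ",
                "uniform theta returned for them"))
  }
  theta <- gibbs_foldin_cpp(lapply(bow, function(x) x - 1L), fit$phi,
                            fit$alpha, as.integer(iterations),
                            as.integer(burn_in), as.integer(sample_lag))
  colnames(theta) <- fit$topic_labels
  if (is.data.frame(newdata) && "doc_id" %in% names(newdata)) {
    rownames(theta) <- newdata$doc_id
  }
  theta
}

#' One-step collapsed conditional distribution
#'
#' The exact distribution the sampler draws a token's topic from, given the
#' count state with that token removed:
#' `p(z = k) ~ (n_dk + alpha) (n_kw + beta) / (n_k + V beta)` over the
#' allowed topic set. Exposed for verification against brute-force
#' evaluation of the collapsed posterior.
#'
#' @param n_dk_d integer topic counts of the token's document (length K).
#' @param n_kw K x V topic-word count matrix.
#' @param n_k topic total counts (length K).
#' @param word 1-based vocabulary index of the token.
#' @param alpha,beta symmetric priors.
#' @param allowed 1-based allowed topic indices; default all K.
#' @return Probability vector over `allowed`, summing to 1.
#' @export
topic_conditional <- function(n_dk_d, n_kw, n_k, word, alpha, beta,
                              allowed = NULL) {
  K <- length(n_k)
  allowed <- allowed %||% seq_len(K)
  lda_conditional_cpp(as.integer(n_dk_d), n_kw, as.integer(n_k),
                      as.integer(word) - 1L, as.integer(allowed) - 1L,
                      alpha, beta)
}

#' Top words of a topic
#'
#' @param fit an `"lda_fit"` (or anything with `phi`, `vocab`,
#'   `topic_labels`).
#' @param topic topic label id or index.
#' @param n number of words (<= V).
#' @return Character vector of the `n` highest-probability words, ties broken
#'   by vocabulary index.
#' @export
top_words <- function(fit, topic, n = 10) {
  phi <- fit$phi
  k <- if (is.character(topic)) match(topic, fit$topic_labels) else topic
  if (is.na(k) || k < 1 || k > nrow(phi)) abort("unknown topic")
  if (n > ncol(phi)) abort("n exceeds vocabulary size")
  row <- phi[k, ]
  ord <- order(-row, seq_along(row))
  fit$vocab$token[ord[seq_len(n)]]
}
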