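# Per-word perplexity and topic-number selection.

#' Per-word perplexity on held-out documents
#'
#' `exp(- sum_d log p(w_d) / sum_d N_d)` with per-word likelihood
#' `p(w) = sum_k theta_dk phi_kw`. Held-out theta rows are obtained by Gibbs
#' fold-in with phi fixed (the simplest well-defined estimator for the
#' formula) unless an explicit `theta` matrix is supplied. Perplexity is the
#' predicted effective number of equally likely words, so it is always >= 1
#' and lower is better; a uniform model over V words scores exactly V.
#'
#' @param fit an `"lda_fit"`, or a bare list with elements `phi` (K x V
#'   row-stochastic) and optionally `vocab`, `alpha`, `topic_labels` — handy
#'   for closed-form checks.
#' @param heldout held-out documents: corpus tibble, list of token vectors,
#'   or bag-of-words index list.
#' @param theta optional precomputed theta rows for the held-out documents
#'   (documents x K); skips fold-in.
#' @param iterations,burn_in,sample_lag,seed fold-in schedule passed to
#'   [infer_theta()].
#' @return A single positive number.
#' @export
per_word_perplexity <- function(fit, heldout, theta = NULL, iterations = 200,
                                burn_in = 100, sample_lag = 5, seed = NULL) {
  bare <- !inherits(fit, "lda_fit")
  if (bare) {
    fit <- structure(
      list(phi = fit$phi, vocab = fit$vocab,
           alpha = fit$alpha %||% 50 / nrow(fit$phi),
           topic_labels = fit$topic_labels %||% as.character(seq_len(nrow(fit$phi)))),
      class = "lda_fit")
  }
  bow <- if (is.data.frame(heldout) ||
             all(vapply(heldout, is.character, logical(1)))) {
    if (is.null(fit$vocab)) abort("token input needs a fit with a vocabulary")
    docs_to_bow(heldout, fit$vocab)
  } else {
    lapply(heldout, as.integer)
  }
  N <- sum(lengths(bow))
  if (N == 0) abort("zero held-out tokens")
  if (is.null(theta)) {
    theta <- suppressWarnings(
      infer_theta(fit, bow, iterations = iterations, burn_in = burn_in,
                  sample_lag = sample_lag, seed = seed))
  }
  theta <- as.matrix(theta)
  ll <- 0
  for (d in seq_along(bow)) {
    w <- bow[[d]]
    if (length(w) == 0) next
    pw <- as.numeric(theta[d, , drop = FALSE] %*% fit$phi[, w, drop = FALSE])
    ll <- ll + sum(log(pw))
  }
  exp(-ll / N)
}

#' Select the number of topics by a perplexity scan
#'
#' Splits the corpus into training and held-out documents, fits one LDA model
#' per grid value of K, and records held-out per-word perplexity. Perplexity
#' typically decreases monotonically in K and flattens past the true topic
#' count, so the recommendation is the elbow: the last grid point that still
#' improved on its predecessor by at least `threshold` (relative), i.e. the K
#' beyond which the curve decreases much more slowly. The full curve is
#' always returned, since the final choice trades predictive fit against
#' interpretability. With `threshold = 0` the rule degenerates and the
#' largest grid value is recommended.
#'
#' @param data corpus tibble or bag-of-words list (with `vocab`).
#' @param grid ascending integer vector of candidate K (>= 2 values, each
#'   >= 2).
#' @param heldout_frac fraction of documents held out; default 0.2.
#' @param threshold relative-improvement cutoff for the elbow rule; default
#'   0.05.
#' @param seed seed for the split and the fits.
#' @param vocab optional vocabulary (required for bag-of-words input).
#' @param iterations,burn_in,sample_lag Gibbs schedule per fit.
#' @param ... further arguments to [fit_lda()].
#' @return A `"perplexity_curve"`: tibble with columns `K` and `perplexity`,
#'   attributes `recommended_k`, `heldout_frac`, `threshold`, `seed`, and an
#'   [autoplot.perplexity_curve()] method.
#' @export
select_num_topics <- function(data, grid, heldout_frac = 0.2,
                              threshold = 0.05, seed = 1, vocab = NULL,
                              iterations = 300, burn_in = 150,
                              sample_lag = 5, ...) {
  grid <- sort(as.integer(grid))
  if (length(grid) < 2) abort("grid needs at least 2 candidate values of K")
  if (any(grid < 2)) abort("all grid values must be >= 2")
  inp <- as_bow_input(data, vocab)
  M <- length(inp$bow)
  set.seed(seed)
  n_hold <- max(1L, round(heldout_frac * M))
  hold <- sort(sample.int(M, n_hold))
  train_bow <- inp$bow[-hold]
  hold_bow <- inp$bow[hold]

  pp <- vapply(grid, function(K) {
    fit <- fit_lda(train_bow, K = K, vocab = inp$vocab,
                   iterations = iterations, burn_in = burn_in,
                   sample_lag = sample_lag, seed = seed + K, ...)
    per_word_perplexity(fit, hold_bow, seed = seed + K)
  }, numeric(1))

  rel_impr <- c(NA, (pp[-length(pp)] - pp[-1]) / pp[-length(pp)])
  # a worsening step counts as zero improvement, so threshold = 0 cleanly
  # degenerates to "never flat" and recommends the largest grid value
  flat_at <- which(pmax(rel_impr, 0) < threshold)[1]
  rec <- if (is.na(flat_at)) max(grid) else grid[flat_at - 1]

  curve <- tibble::tibble(K = grid, perplexity = pp,
                          rel_improvement = rel_impr)
  attr(curve, "recommended_k") <- rec
  attr(curve, "heldout_frac") <- heldout_frac
  attr(curve, "threshold") <- threshold
  attr(curve, "seed") <- seed
  attr(curve, "estimator") <- "document fold-in, phi fixed"
  class(curve) <- c("perplexity_curve", class(curve))
  curve
}

#' Recommended K from a perplexity curve
#'
#' @param curve a `"perplexity_curve"`.
#' @return The recommended number of topics (integer).
#' @export
recommended_k <- function(curve) attr(curve, "recommended_k")

#' Plot a perplexity curve
#'
#' @param object a `"perplexity_curve"` from [select_num_topics()].
#' @param ... ignored.
#' @return A ggplot: per-word perplexity against K, recommended K marked.
#' @export
autoplot.perplexity_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$K, y = .data$perplexity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = recommended_k(object), linetype = 2) +
    ggplot2::labs(x = "number of topics K", y = "per-word perplexity",
                  title = "Held-out perplexity by number of topics",
                  subtitle = paste0("recommended K = ",
                                    recommended_k(object))) +
    ggplot2::theme_minimal()
}
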