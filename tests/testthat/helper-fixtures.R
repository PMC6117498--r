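# Shared fixtures: small corpora and an independent collapsed-posterior
# oracle used against the sampler's conditional.

tiny_corpus <- function() {
  review_corpus(
    doc_id = c("r1", "r2", "r3"),
    tokens = list(c("good", "doctor", "good"),
                  c("long", "wait", "queue"),
                  c("fever", "cough")),
    labels = list("ME", c("OP", "F"), "S"),
    disease = c("influenza", "diabetes", "influenza"),
    hospital_level = c("A", "B", "C"),
    doctor_id = c("doc1", "doc1", "doc2")
  )
}

random_corpus <- function(n = 10, seed = 1) {
  set.seed(seed)
  vocab <- c(letters, "39°C", "#AGE#")
  labs <- load_taxonomy()$label_id
  review_corpus(
    doc_id = sprintf("r%03d", seq_len(n)),
    raw_text = replicate(n, paste(sample(vocab, 5, TRUE), collapse = " ")),
    tokens = lapply(seq_len(n), function(i) sample(vocab, sample(1:8, 1), TRUE)),
    labels = lapply(seq_len(n), function(i) sample(labs, sample(1:3, 1))),
    disease = sample(c("influenza", "diabetes", "liver cancer"), n, TRUE),
    hospital_level = sample(c("A", "B", "C"), n, TRUE),
    doctor_id = sample(sprintf("doc%02d", 1:4), n, TRUE)
  )
}

# Brute-force collapsed joint log P(w, z) for LDA with symmetric priors:
# product over documents of Dirichlet-multinomial terms in n_dk and over
# topics of Dirichlet-multinomial terms in n_kw. Independent of the sampler.
collapsed_log_joint <- function(z_docs, w_docs, K, V, alpha, beta) {
  ll <- 0
  for (d in seq_along(w_docs)) {
    n_dk <- tabulate(z_docs[[d]], nbins = K)
    Nd <- length(w_docs[[d]])
    ll <- ll + lgamma(K * alpha) - lgamma(Nd + K * alpha) +
      sum(lgamma(n_dk + alpha) - lgamma(alpha))
  }
  for (k in seq_len(K)) {
    n_kw <- tabulate(unlist(w_docs)[unlist(z_docs) == k], nbins = V)
    ll <- ll + lgamma(V * beta) - lgamma(sum(n_kw) + V * beta) +
      sum(lgamma(n_kw + beta) - lgamma(beta))
  }
  ll
}

# Oracle one-step conditional: enumerate the collapsed joint over the
# candidate topics of one token and normalize.
oracle_conditional <- function(z_docs, w_docs, d, i, K, V, alpha, beta,
                               allowed = seq_len(K)) {
  lp <- vapply(allowed, function(k) {
    zz <- z_docs
    zz[[d]][i] <- k
    collapsed_log_joint(zz, w_docs, K, V, alpha, beta)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p / sum(p)
}

counts_from_z <- function(z_docs, w_docs, K, V) {
  M <- length(w_docs)
  n_dk <- matrix(0L, M, K)
  n_kw <- matrix(0L, K, V)
  for (d in seq_len(M)) {
    for (i in seq_along(w_docs[[d]])) {
      n_dk[d, z_docs[[d]][i]] <- n_dk[d, z_docs[[d]][i]] + 1L
      n_kw[z_docs[[d]][i], w_docs[[d]][i]] <-
        n_kw[z_docs[[d]][i], w_docs[[d]][i]] + 1L
    }
  }
  list(n_dk = n_dk, n_kw = n_kw, n_k = rowSums(n_kw))
}

# minimal lda_fit-shaped object for estimator and fold-in tests
fake_fit <- function(phi, alpha = 0.5, vocab_tokens = NULL) {
  K <- nrow(phi)
  V <- ncol(phi)
  structure(
    list(method = "lda", K = K, V = V, alpha = alpha, beta = 0.01,
         vocab = structure(list(token = vocab_tokens %||% sprintf("t%02d", 1:V),
                                V = V), class = "vocabulary"),
         topic_labels = as.character(seq_len(K)), phi = phi,
         doc_ids = character(0), bow = list()),
    class = "lda_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
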