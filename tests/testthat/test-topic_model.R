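test_that("sampler conditionals match the brute-force collapsed posterior", {
  # 3 documents, 2 topics, 5 words
  w_docs <- list(c(1L, 2L, 3L, 1L), c(4L, 5L, 1L), c(2L, 2L, 4L))
  z_docs <- list(c(1L, 2L, 1L, 1L), c(2L, 2L, 1L), c(1L, 2L, 2L))
  K <- 2L; V <- 5L; alpha <- 0.3; beta <- 0.2
  for (d in 1:3) {
    for (i in seq_along(w_docs[[d]])) {
      # implementation side: counts with token (d, i) removed
      zz <- z_docs
      zz[[d]] <- zz[[d]][-i]
      ww <- w_docs
      ww[[d]] <- ww[[d]][-i]
      cnt <- counts_from_z(
        lapply(seq_along(zz), function(j) zz[[j]]),
        lapply(seq_along(ww), function(j) ww[[j]]), K, V)
      got <- topic_conditional(cnt$n_dk[d, ], cnt$n_kw, cnt$n_k,
                               word = w_docs[[d]][i], alpha = alpha,
                               beta = beta)
      want <- oracle_conditional(z_docs, w_docs, d, i, K, V, alpha, beta)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # labeled restriction: conditional over a reduced topic set
  got <- topic_conditional(c(2L, 1L), counts_from_z(z_docs, w_docs, K, V)$n_kw,
                           counts_from_z(z_docs, w_docs, K, V)$n_k,
                           word = 1L, alpha = alpha, beta = beta, allowed = 2L)
  expect_equal(as.numeric(got), 1)
})

test_that("gibbs counts are conserved after every sweep", {
  corpus <- generate_corpus(generator_config(L = 3, vocab_size = 25,
                                             group_sizes = c(g = 25),
                                             doc_length_mean = 12,
                                             seed = 1))$corpus
  # the sampler aborts if any sweep breaks a count identity
  fit <- fit_lda(corpus, K = 3, iterations = 30, burn_in = 10, seed = 2,
                 check_invariants = TRUE)
  cnt <- counts_from_z(fit$z, fit$bow, fit$K, fit$V)
  expect_equal(unname(fit$n_dk), cnt$n_dk)
  expect_equal(unname(fit$n_kw), cnt$n_kw)
  expect_equal(as.integer(fit$n_k), as.integer(cnt$n_k))
  expect_equal(rowSums(fit$n_dk), lengths(fit$bow))
})

test_that("labeled-LDA with full label sets is bit-identical to LDA", {
  out <- generate_corpus(generator_config(L = 4, vocab_size = 30,
                                          group_sizes = c(g = 30),
                                          doc_length_mean = 15, seed = 3))
  corpus <- out$corpus
  tax <- structure(tibble::tibble(
    label_id = c("A", "B", "C", "D"),
    name = c("A", "B", "C", "D"),
    domain = rep("physician-related", 4)), class = c("taxonomy", "tbl_df",
                                                     "tbl", "data.frame"))
  corpus$labels <- rep(list(tax$label_id), nrow(corpus))
  f1 <- fit_lda(corpus, K = 4, alpha = 50 / 4, iterations = 40, burn_in = 20,
                seed = 11)
  f2 <- fit_labeled_lda(corpus, taxonomy = tax, iterations = 40,
                        burn_in = 20, seed = 11)
  expect_identical(f1$z, f2$z)
  expect_equal(unname(f1$theta), unname(f2$theta))
  expect_equal(unname(f1$phi), unname(f2$phi))
})

test_that("single-label documents force point-mass topic support", {
  out <- generate_corpus(generator_config(
    L = 9, vocab_size = 50, labels_per_doc = 1,
    group_sizes = c(g = 20), doc_length_mean = 10, seed = 4))
  fit <- fit_labeled_lda(out$corpus, alpha = 0.01, iterations = 20,
                         burn_in = 10, seed = 5)
  for (d in seq_len(nrow(out$corpus))) {
    lab <- out$corpus$labels[[d]]
    # all token mass sits on the single allowed label
    expect_equal(unname(fit$n_dk[d, match(lab, fit$topic_labels)]),
                 length(fit$bow[[d]]))
    expect_equal(sum(fit$n_dk[d, ]), length(fit$bow[[d]]))
  }
  expect_error(
    fit_labeled_lda(dplyr::mutate(out$corpus,
                                  labels = list(character(0))),
                    iterations = 5, burn_in = 1),
    "empty label set")
})

test_that("theta and phi estimates match hand arithmetic", {
  # one document, two topics, three tokens: z = (1, 1, 2), words = (1, 2, 1)
  fit <- structure(list(
    method = "lda", K = 2L, V = 3L, alpha = 0.5, beta = 0.25,
    bow = list(c(1L, 2L, 1L)),
    n_dk = matrix(c(2L, 1L), 1, 2),
    n_kw = matrix(c(1L, 1L, 1L, 0L, 0L, 0L), 2, 3),
    n_k = c(2L, 1L),
    theta = matrix(0, 1, 2), phi = matrix(0, 2, 3),
    topic_labels = c("1", "2")), class = "lda_fit")
  est <- estimate_theta_phi(fit)
  expect_equal(as.numeric(est$theta), c((2 + .5) / (3 + 1), (1 + .5) / (3 + 1)))
  expect_equal(est$phi[1, ], c((1 + .25) / (2 + .75), (1 + .25) / (2 + .75),
                               (0 + .25) / (2 + .75)))
  expect_equal(rowSums(est$theta), 1)
  expect_equal(unname(rowSums(est$phi)), c(1, 1))

  # empty document: theta is the prior, uniform 1/K
  fit$bow <- list(integer(0))
  fit$n_dk <- matrix(c(0L, 0L), 1, 2)
  fit$n_kw <- matrix(0L, 2, 3)
  fit$n_k <- c(0L, 0L)
  est0 <- estimate_theta_phi(fit)
  expect_equal(as.numeric(est0$theta), c(0.5, 0.5))
})

test_that("a one-topic corpus yields dominant theta columns", {
  out <- generate_corpus(generator_config(
    L = 2, vocab_size = 40, beta_true = 0.1, labels_per_doc = 1,
    label_prevalence = matrix(c(1, 0), 1, 2),
    group_sizes = c(g = 60), doc_length_mean = 50, seed = 6))
  # sparse document prior, single-state estimate: averaging over samples
  # would blur a document whose dominant topic flips between draws
  fit <- fit_lda(out$corpus, K = 2, alpha = 0.01, iterations = 300,
                 burn_in = 150, seed = 7, average = FALSE)
  dominant <- apply(fit$theta, 1, max)
  expect_gte(mean(dominant > 0.8), 0.95)
})

test_that("fold-in inference recovers a document's generating topic", {
  set.seed(8)
  K <- 4; V <- 60
  phi <- matrix(rgamma(K * V, 0.1), K)
  phi <- phi / rowSums(phi)
  fit <- fake_fit(phi, alpha = 0.5)
  hits <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    k <- sample.int(K, 1)
    doc <- sample.int(V, 200, replace = TRUE, prob = phi[k, ])
    th <- infer_theta(fit, list(doc), iterations = 100, burn_in = 50,
                      seed = 100 + r)
    hits <- hits + (which.max(th[1, ]) == k)
  }
  expect_gte(hits / reps, 0.95)

  expect_warning(th0 <- infer_theta(fit, list(integer(0)), seed = 1),
                 "out-of-vocabulary")
  expect_equal(as.numeric(th0), rep(1 / K, K))
  t1 <- infer_theta(fit, list(c(1L, 2L, 3L)), seed = 5)
  t2 <- infer_theta(fit, list(c(1L, 2L, 3L)), seed = 5)
  expect_identical(t1, t2)
})

test_that("perplexity matches closed forms and hand computation", {
  V <- 50; K <- 3
  uniform <- list(phi = matrix(1 / V, K, V))
  bow <- list(c(1L, 5L, 7L), c(2L, 2L))
  expect_equal(per_word_perplexity(uniform, bow, seed = 1), V)

  sure <- list(phi = matrix(1, 2, 1))  # every word gets probability 1
  expect_equal(per_word_perplexity(sure, list(c(1L, 1L), 1L), seed = 1), 1)

  # two-document toy with fixed theta and phi: geometric-mean inverse
  # likelihood computed by hand
  phi <- matrix(c(0.6, 0.4, 0.1, 0.9), 2, 2, byrow = TRUE)
  theta <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE)
  bow2 <- list(c(1L, 2L), c(2L))
  p11 <- 0.6; p12 <- 0.4; p22 <- 0.5 * 0.4 + 0.5 * 0.9
  want <- exp(-(log(p11) + log(p12) + log(p22)) / 3)
  got <- per_word_perplexity(list(phi = phi), bow2, theta = theta)
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(per_word_perplexity(uniform, list(integer(0))), "zero held-out")
})

test_that("topic-number selection obeys the elbow rule contract", {
  out <- generate_corpus(generator_config(
    L = 3, vocab_size = 40, group_sizes = c(g = 60),
    doc_length_mean = 20, seed = 9))
  curve <- select_num_topics(out$corpus, grid = c(2, 3, 5),
                             heldout_frac = 0.25, seed = 10,
                             iterations = 60, burn_in = 30)
  expect_true(all(curve$perplexity >= 1))
  expect_equal(curve$K, c(2L, 3L, 5L))

  # threshold 0: no improvement ever qualifies, rule degenerates to max K
  c0 <- select_num_topics(out$corpus, grid = c(2, 3), threshold = 0,
                          heldout_frac = 0.25, seed = 10,
                          iterations = 40, burn_in = 20)
  expect_equal(recommended_k(c0), 3L)

  expect_error(select_num_topics(out$corpus, grid = 5), "at least 2")
  expect_error(select_num_topics(out$corpus, grid = c(1, 3)), ">= 2")
  expect_error(fit_lda(out$corpus, K = 1), "K must be >= 2")
})

test_that("top words rank by probability with index tie-breaks", {
  phi <- rbind(c(0, 1, 0, 0), c(0.25, 0.25, 0.25, 0.25))
  fit <- fake_fit(phi)
  expect_equal(top_words(fit, 1, 1), "t02")
  # exact ties resolve by vocabulary index
  expect_equal(top_words(fit, 2, 4), c("t01", "t02", "t03", "t04"))
  expect_error(top_words(fit, 1, 5), "exceeds")

  set.seed(12)
  for (i in 1:10) {
    row <- runif(8)
    f <- fake_fit(rbind(row / sum(row), row / sum(row)))
    oracle <- f$vocab$token[order(-row, seq_along(row))]
    expect_equal(top_words(f, 1, 8), oracle)
  }
})

test_that("tidy, glance and classify outputs have the promised shapes", {
  out <- generate_corpus(generator_config(L = 3, vocab_size = 25,
                                          group_sizes = c(g = 15),
                                          doc_length_mean = 10, seed = 13))
  fit <- fit_lda(out$corpus, K = 3, iterations = 30, burn_in = 15, seed = 14)
  td <- tidy(fit, "beta")
  expect_equal(nrow(td), fit$K * fit$V)
  expect_equal(sum(td$beta), fit$K, tolerance = 1e-9)
  tg <- tidy(fit, "gamma")
  expect_equal(nrow(tg), fit$K * nrow(out$corpus))
  gl <- glance(fit)
  expect_equal(gl$k, 3L)
  expect_equal(gl$n_docs, 15L)
  cl <- classify(fit)
  expect_equal(nrow(cl), 15)
  expect_true(is.list(cl$assigned))
})
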