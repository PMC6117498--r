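# Labeled-LDA synthetic corpus generator.
#
# Documents are drawn from the labeled-LDA generative process: each document
# gets a label set from its group's per-label prevalences, a topic mixture
# theta restricted to that set from a symmetric Dirichlet(alpha_true), a
# length from a count distribution, and tokens by sampling a topic from theta
# then a word from that topic's row of phi_true.

rdirichlet_mat <- function(n, alpha_vec) {
  k <- length(alpha_vec)
  x <- matrix(rgamma(n * k, shape = alpha_vec), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Configuration for the synthetic review-corpus generator
#'
#' @param L number of taxonomy labels (topics).
#' @param labels character label ids; defaults to the packaged nine-label
#'   taxonomy when `L = 9`, else `T1..TL`.
#' @param vocab character vector of vocabulary tokens; default synthetic
#'   tokens `w0001...`.
#' @param vocab_size vocabulary size when `vocab` is not given; must be >= L
#'   so topics are distinguishable.
#' @param beta_true symmetric Dirichlet concentration for topic-word rows of
#'   `phi_true`; small values give sparse, well-separated topics.
#' @param alpha_true symmetric Dirichlet concentration for the document-topic
#'   mixture over each document's label set.
#' @param label_prevalence G x L matrix of per-group per-label inclusion
#'   probabilities in \[0, 1\] (rows = groups, in `group_sizes` order).
#' @param doc_length_mean mean document length (tokens); scalar or one value
#'   per group.
#' @param doc_length_dispersion `Inf` for Poisson lengths, else the negative
#'   binomial size parameter.
#' @param labels_per_doc optional probability vector over label-set
#'   cardinalities `1..length(labels_per_doc)`; when `NULL` (default) label
#'   sets are independent Bernoulli draws from the prevalences, resampled if
#'   empty.
#' @param group_sizes named integer vector of documents per group (>= 1).
#' @param diseases disease name recorded for each group's reviews; defaults
#'   to the group names.
#' @param hospital_probs sampling probabilities for hospital levels A/B/C.
#' @param doctors_per_group optional named integer vector of distinct doctors
#'   per group; default one doctor per ten reviews.
#' @param seed integer seed used by [generate_corpus()] and [sample_phi()].
#' @return A validated config list, classed `"generator_config"`.
#' @seealso [preset_config()] for the corpus-shaped default.
#' @export
generator_config <- function(L = 9, labels = NULL, vocab = NULL,
                             vocab_size = 500, beta_true = 0.05,
                             alpha_true = 0.5, label_prevalence = NULL,
                             doc_length_mean = 60,
                             doc_length_dispersion = Inf,
                             labels_per_doc = NULL,
                             group_sizes = c(g1 = 100),
                             diseases = NULL,
                             hospital_probs = c(A = 0.5, B = 0.3, C = 0.2),
                             doctors_per_group = NULL, seed = 1) {
  if (is.null(labels)) {
    labels <- if (L == 9) load_taxonomy()$label_id else paste0("T", seq_len(L))
  }
  stopifnot(length(labels) == L)
  if (is.null(vocab)) vocab <- sprintf("w%04d", seq_len(vocab_size))
  vocab_size <- length(vocab)
  if (vocab_size < L) {
    abort("vocab_size must be >= L: topics are otherwise indistinguishable")
  }
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- paste0("g", seq_along(group_sizes))
  }
  if (any(group_sizes < 1)) abort("group_sizes must be >= 1")
  G <- length(group_sizes)
  if (is.null(label_prevalence)) {
    label_prevalence <- matrix(0.3, nrow = G, ncol = L)
  }
  label_prevalence <- as.matrix(label_prevalence)
  if (nrow(label_prevalence) != G || ncol(label_prevalence) != L) {
    abort("label_prevalence must be a (groups x L) matrix")
  }
  if (any(label_prevalence < 0 | label_prevalence > 1)) {
    abort("label_prevalence entries must be probabilities in [0, 1]")
  }
  if (!is.null(labels_per_doc)) {
    if (length(labels_per_doc) > L || any(labels_per_doc < 0) ||
        abs(sum(labels_per_doc) - 1) > 1e-8) {
      abort("labels_per_doc must be a probability vector over 1..L")
    }
  }
  doc_length_mean <- rep_len(doc_length_mean, G)
  if (is.null(diseases)) diseases <- names(group_sizes)
  diseases <- rep_len(diseases, G)
  if (is.null(doctors_per_group)) {
    doctors_per_group <- pmax(1L, round(group_sizes / 10))
  }
  structure(
    list(L = L, labels = labels, vocab = vocab, vocab_size = vocab_size,
         beta_true = beta_true, alpha_true = alpha_true,
         label_prevalence = label_prevalence,
         doc_length_mean = doc_length_mean,
         doc_length_dispersion = doc_length_dispersion,
         labels_per_doc = labels_per_doc, group_sizes = group_sizes,
         diseases = diseases, hospital_probs = hospital_probs,
         doctors_per_group = doctors_per_group, seed = seed),
    class = "generator_config"
  )
}

#' Corpus-shaped generator preset
#'
#' Default emulation of the haodf.com review-corpus shape at desk scale: nine
#' topics, a 500-token vocabulary (491 synthetic word types plus nine entity
#' placeholders), nine disease subcorpora with sizes proportional to the
#' published per-disease review counts scaled to `n_docs` documents, mean
#' lengths 0.2 times the published per-review word counts, and per-disease
#' doctor counts matching the published reviews-per-physician ratios.
#' Label prevalences plant the published direction of every group contrast:
#' symptoms more prevalent for acute (and especially mild) diseases;
#' communication skills, financing, diagnosis and pathogenesis more prevalent
#' for chronic diseases; medical competence, medical advice and financing
#' boosted for serious diseases; medical ethics, operation process, patient
#' profile and symptoms boosted for the mild disease.
#'
#' @param n_docs total corpus size; default 3000.
#' @param seed generator seed; default 7.
#' @return A `"generator_config"` (see [generator_config()]).
#' @export
preset_config <- function(n_docs = 3000, seed = 7) {
  stats <- published_review_stats()
  sizes <- round(n_docs * stats$n_reviews / sum(stats$n_reviews))
  sizes <- pmax(sizes, 1L)
  names(sizes) <- stats$disease
  lengths <- round(0.2 * stats$mean_words)
  doctors <- pmax(1L, round(sizes / stats$reviews_per_physician))
  names(doctors) <- stats$disease

  # label order: ME MC MAP CS F OP PP S DAP
  acute   <- c(.30, .30, .25, .18, .15, .25, .30, .55, .18)
  mild    <- c(.40, .25, .20, .18, .15, .35, .45, .65, .12)
  chronic <- c(.30, .30, .25, .30, .32, .25, .25, .25, .32)
  serious <- c(.28, .50, .35, .20, .20, .22, .22, .35, .50)
  prev <- rbind(
    "infertility"        = chronic,
    "infantile pneumonia" = acute,
    "infantile diarrhea" = acute,
    "influenza"          = mild,
    "hyperthyroidism"    = acute,
    "diabetes"           = chronic,
    "liver cancer"       = serious,
    "gastric cancer"     = serious,
    "hypertension"       = chronic
  )
  prev <- prev[stats$disease, , drop = FALSE]

  # alpha_true = 2: a document's nominal labels must carry detectable topic
  # mass under the 1/L rule, i.e. rarely fall below the 1/9 floor; a sparser
  # mixture prior would plant labels that no classifier could recover
  vocab <- c(sprintf("w%04d", seq_len(491)), names(entity_surface_forms()))
  generator_config(
    L = 9, vocab = vocab, beta_true = 0.05, alpha_true = 2,
    label_prevalence = prev, doc_length_mean = lengths,
    group_sizes = sizes, diseases = stats$disease,
    doctors_per_group = doctors, seed = seed
  )
}

draw_phi <- function(config) {
  phi <- rdirichlet_mat(config$L, rep(config$beta_true, config$vocab_size))
  dimnames(phi) <- list(config$labels, config$vocab)
  phi
}

#' Sample true topic-word distributions
#'
#' Draws the L rows of `phi_true`, each from a symmetric
#' Dirichlet(`beta_true`) over the vocabulary. Reproducible under the config
#' seed.
#'
#' @param config a [generator_config()].
#' @return An L x V row-stochastic matrix with label row names.
#' @export
sample_phi <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  draw_phi(config)
}

sample_label_set <- function(prev, labels_per_doc) {
  L <- length(prev)
  if (is.null(labels_per_doc)) {
    repeat {
      set <- which(runif(L) < prev)
      if (length(set) > 0) return(set)
    }
  }
  card <- sample.int(length(labels_per_doc), 1, prob = labels_per_doc)
  if (all(prev == 0)) abort("empty label-prevalence row")
  sample.int(L, min(card, sum(prev > 0)), prob = prev)
}

sample_doc_length <- function(n, mean, dispersion) {
  if (is.infinite(dispersion)) rpois(n, mean)
  else stats::rnbinom(n, size = dispersion, mu = mean)
}

#' Generate a labeled synthetic review corpus
#'
#' Runs the labeled-LDA generative process described in
#' [generator_config()]: group by group, each document samples a label set
#' (resampled if empty), a Dirichlet topic mixture over that set, a length,
#' and then per token a topic from theta and a word from `phi_true`. Disease
#' and hospital-level metadata are attached so all three packaged grouping
#' schemes apply.
#'
#' @param config a [generator_config()].
#' @return A list with `corpus` (a review-corpus tibble with gold `labels`)
#'   and `truth` (list: `phi` the true L x V topic-word matrix, `theta` the
#'   M x L true document-topic matrix with support only on each document's
#'   labels, `z` the per-token true topic indices).
#' @examples
#' out <- generate_corpus(generator_config(L = 3, vocab_size = 20,
#'                                         group_sizes = c(g1 = 5), seed = 1))
#' out$corpus
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (any(rowSums(config$label_prevalence) == 0) &&
      is.null(config$labels_per_doc)) {
    abort("empty label-prevalence row")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  phi <- draw_phi(config)

  M <- sum(config$group_sizes)
  L <- config$L
  theta_true <- matrix(0, M, L, dimnames = list(NULL, config$labels))
  tokens <- vector("list", M)
  label_sets <- vector("list", M)
  z_list <- vector("list", M)
  disease <- character(M)
  hospital <- character(M)
  doctor <- character(M)

  d <- 0L
  for (g in seq_along(config$group_sizes)) {
    n_g <- config$group_sizes[g]
    prev <- config$label_prevalence[g, ]
    lens <- pmax(1L, sample_doc_length(n_g, config$doc_length_mean[g],
                                       config$doc_length_dispersion))
    docs_g <- sample.int(config$doctors_per_group[g], n_g, replace = TRUE)
    for (i in seq_len(n_g)) {
      d <- d + 1L
      set <- sort(sample_label_set(prev, config$labels_per_doc))
      th <- drop(rdirichlet_mat(1, rep(config$alpha_true, length(set))))
      theta_true[d, set] <- th
      n_d <- lens[i]
      z <- set[sample.int(length(set), n_d, replace = TRUE, prob = th)]
      words <- character(n_d)
      for (k in unique(z)) {
        idx <- which(z == k)
        words[idx] <- config$vocab[sample.int(config$vocab_size, length(idx),
                                              replace = TRUE, prob = phi[k, ])]
      }
      tokens[[d]] <- words
      z_list[[d]] <- z
      label_sets[[d]] <- config$labels[set]
      disease[d] <- config$diseases[g]
      hospital[d] <- sample(names(config$hospital_probs), 1,
                            prob = config$hospital_probs)
      doctor[d] <- paste0(names(config$group_sizes)[g], "_doc",
                          sprintf("%03d", docs_g[i]))
    }
  }

  corpus <- review_corpus(
    doc_id = sprintf("d%05d", seq_len(M)), tokens = tokens,
    labels = label_sets, disease = disease, hospital_level = hospital,
    doctor_id = doctor
  )
  list(corpus = corpus,
       truth = list(phi = phi, theta = theta_true, z = z_list))
}

#' Entity placeholder surface-form samplers
#'
#' One sampler per placeholder; each returns surface strings that the
#' packaged entity rules (see [load_entity_rules()]) map back to the
#' placeholder, e.g. `"39.0°C"` back to `#BODY_TEMPERATURE#`.
#'
#' @return Named list of functions `n -> character(n)`.
#' @export
entity_surface_forms <- function() {
  list(
    "#BODY_TEMPERATURE#" = function(n) sprintf("%.1f°C", runif(n, 36, 41)),
    "#AGE#" = function(n) sprintf("%dyo", sample.int(90, n, replace = TRUE)),
    "#HEIGHT#" = function(n) sprintf("%dcm", sample(100:199, n, replace = TRUE)),
    "#WEIGHT#" = function(n) sprintf("%dkg", sample(40:120, n, replace = TRUE)),
    "#DATE#" = function(n) sprintf("%d-%02d-%02d",
                                   sample(2007:2015, n, replace = TRUE),
                                   sample.int(12, n, replace = TRUE),
                                   sample.int(28, n, replace = TRUE)),
    "#TIME#" = function(n) sprintf("%d:%02d", sample(8:17, n, replace = TRUE),
                                   sample(0:59, n, replace = TRUE)),
    "#MONEY#" = function(n) sprintf("¥%d", sample(10:9999, n, replace = TRUE)),
    "#PERCENT#" = function(n) sprintf("%d%%", sample.int(100, n, replace = TRUE)),
    "#NUMBER#" = function(n) as.character(sample.int(999, n, replace = TRUE))
  )
}

#' Render raw text with controlled surface noise
#'
#' Turns token vectors into `raw_text` strings while injecting, at the given
#' rates, entity surface forms in place of placeholder tokens (a
#' `#BODY_TEMPERATURE#` token may become `"39.0°C"`), synonym variants in
#' place of canonical tokens found in the thesaurus, and inserted stopwords.
#' The original `tokens` column is kept: it is the sequence the preprocessing
#' pipeline (entity rules, thesaurus, stopword list) is expected to recover,
#' which makes rendered corpora exact round-trip fixtures. At zero rates the
#' raw text is just the space-joined tokens.
#'
#' @param corpus a review corpus with `tokens`.
#' @param entity_rate,synonym_rate,stopword_rate noise rates in \[0, 1\].
#' @param thesaurus variant-to-canonical tibble; default packaged
#'   [load_thesaurus()].
#' @param stopwords character stopword inventory; default packaged list.
#' @param seed optional seed for reproducible rendering.
#' @return The corpus with a `raw_text` column added.
#' @export
render_raw_text <- function(corpus, entity_rate = 1, synonym_rate = 0,
                            stopword_rate = 0, thesaurus = NULL,
                            stopwords = NULL, seed = NULL) {
  rates <- c(entity_rate, synonym_rate, stopword_rate)
  if (any(rates < 0 | rates > 1)) abort("noise rates must lie in [0, 1]")
  if (!"tokens" %in% names(corpus)) abort("corpus has no tokens column")
  if (!is.null(seed)) set.seed(seed)
  thesaurus <- thesaurus %||% load_thesaurus()
  stopwords <- stopwords %||% load_stopwords()
  variants <- split(thesaurus$variant, thesaurus$canonical)
  surf <- entity_surface_forms()

  corpus$raw_text <- vapply(corpus$tokens, function(tok) {
    n <- length(tok)
    if (n == 0) return("")
    out <- tok
    is_ent <- tok %in% names(surf)
    rep_ent <- is_ent & runif(n) < entity_rate
    for (i in which(rep_ent)) out[i] <- surf[[tok[i]]](1)
    is_can <- tok %in% names(variants)
    rep_syn <- is_can & !is_ent & runif(n) < synonym_rate
    for (i in which(rep_syn)) {
      v <- variants[[tok[i]]]
      out[i] <- v[sample.int(length(v), 1)]
    }
    if (stopword_rate > 0) {
      ins <- runif(n) < stopword_rate
      if (any(ins)) {
        pieces <- as.list(out)
        for (i in which(ins)) {
          pieces[[i]] <- c(pieces[[i]],
                           stopwords[sample.int(length(stopwords), 1)])
        }
        out <- unlist(pieces)
      }
    }
    paste(out, collapse = " ")
  }, character(1))
  corpus
}
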