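# Topic-recovery diagnostics for simulation studies.

#' Cosine similarity between matrix rows
#'
#' @param a,b matrices with the same number of columns.
#' @return A `nrow(a)` x `nrow(b)` matrix of cosine similarities.
#' @export
row_cosine <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  num <- a %*% t(b)
  num / (sqrt(rowSums(a^2)) %o% sqrt(rowSums(b^2)))
}

#' Greedily match estimated topics to reference topics
#'
#' Pairs each estimated topic with a reference topic by repeatedly taking the
#' highest remaining cosine similarity (each side used once). Used to score
#' how well a fitted topic-word matrix recovers the generator's `phi_true`;
#' for labeled-LDA the match is usually the identity, but the matching keeps
#' the score meaningful for unlabeled fits too.
#'
#' @param phi_est estimated K x V topic-word matrix.
#' @param phi_true reference K x V matrix.
#' @return A tibble with columns `topic_est`, `topic_true`, `cosine`, one row
#'   per matched pair, plus a `mean_cosine` attribute.
#' @export
greedy_topic_match <- function(phi_est, phi_true) {
  sim <- row_cosine(phi_est, phi_true)
  est_names <- rownames(phi_est) %||% as.character(seq_len(nrow(phi_est)))
  true_names <- rownames(phi_true) %||% as.character(seq_len(nrow(phi_true)))
  n <- min(nrow(sim), ncol(sim))
  pairs <- vector("list", n)
  s <- sim
  for (i in seq_len(n)) {
    ij <- arrayInd(which.max(s), dim(s))
    pairs[[i]] <- tibble::tibble(topic_est = est_names[ij[1]],
                                 topic_true = true_names[ij[2]],
                                 cosine = sim[ij[1], ij[2]])
    s[ij[1], ] <- -Inf
    s[, ij[2]] <- -Inf
  }
  out <- dplyr::bind_rows(pairs)
  attr(out, "mean_cosine") <- mean(out$cosine)
  out
}
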