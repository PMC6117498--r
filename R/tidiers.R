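# broom-style methods for fitted topic models.

#' Tidy a fitted topic model
#'
#' @param x an `"lda_fit"`.
#' @param matrix `"beta"` for topic-word probabilities (one row per topic x
#'   term) or `"gamma"` for document-topic proportions (one row per document
#'   x topic).
#' @param ... ignored.
#' @return A tibble: `topic`, `term`, `beta`, or `document`, `topic`,
#'   `gamma`.
#' @export
tidy.lda_fit <- function(x, matrix = c("beta", "gamma"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "beta") {
    out <- tibble::tibble(
      topic = rep(x$topic_labels, times = x$V),
      term = rep(x$vocab$token, each = x$K),
      beta = as.numeric(x$phi)
    )
    dplyr::arrange(out, .data$topic, dplyr::desc(.data$beta))
  } else {
    tibble::tibble(
      document = rep(x$doc_ids, times = x$K),
      topic = rep(x$topic_labels, each = length(x$doc_ids)),
      gamma = as.numeric(x$theta)
    )
  }
}

#' One-row summary of a fitted topic model
#'
#' @param x an `"lda_fit"`.
#' @param ... ignored.
#' @return A one-row tibble with the model dimensions and sampler settings.
#' @export
glance.lda_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, k = x$K, n_docs = length(x$bow), n_terms = x$V,
    n_tokens = sum(lengths(x$bow)), alpha = x$alpha, beta = x$beta,
    iterations = x$iterations, burn_in = x$burn_in,
    n_samples_averaged = x$n_samples
  )
}

#' Plot the top words of each topic
#'
#' @param object an `"lda_fit"`.
#' @param n_terms words per topic; default 8.
#' @param ... ignored.
#' @return A ggplot of per-topic top-word probabilities, faceted by topic.
#' @export
autoplot.lda_fit <- function(object, n_terms = 8, ...) {
  top <- tidy(object, "beta") |>
    dplyr::group_by(.data$topic) |>
    dplyr::slice_max(.data$beta, n = n_terms, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(term = reorder_within_(.data$term, .data$beta, .data$topic))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$beta, y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~topic, scales = "free_y") +
    ggplot2::scale_y_discrete(labels = function(x) sub("___.*$", "", x)) +
    ggplot2::labs(x = "word probability", y = NULL) +
    ggplot2::theme_minimal()
}

# order terms within facets without depending on tidytext
reorder_within_ <- function(term, by, within) {
  key <- paste0(term, "___", within)
  stats::reorder(key, by)
}
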