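# Multi-label classification by the 1/L rule and its evaluation.

#' Threshold a topic distribution into a label set
#'
#' A topic is assigned exactly when its probability strictly exceeds `1/L`
#' (the uniform value). A uniform row therefore yields the empty set — a
#' possible, reported outcome, not an error.
#'
#' @param theta a theta matrix (documents x L) or a single row.
#' @param labels label ids (default column names of `theta`).
#' @return A list of character label sets, one per row (a single set for a
#'   vector input).
#' @examples
#' threshold_labels(c(ME = 0.5, MC = 0.3, MAP = 0.2, CS = 0, F = 0, OP = 0,
#'                    PP = 0, S = 0, DAP = 0))
#' @export
threshold_labels <- function(theta, labels = NULL) {
  single <- is.null(dim(theta))
  if (single) theta <- matrix(theta, nrow = 1,
                              dimnames = list(NULL, names(theta)))
  L <- ncol(theta)
  labels <- labels %||% colnames(theta) %||% as.character(seq_len(L))
  out <- apply(theta, 1, function(row) labels[row > 1 / L], simplify = FALSE)
  if (single) out[[1]] else out
}

#' Classify reviews into taxonomy topics
#'
#' Applies the `1/L` rule to document-topic distributions: either the
#' training documents of a labeled-LDA fit, or new documents folded in
#' against the trained phi.
#'
#' @param fit an `"lda_fit"`.
#' @param newdata optional corpus of unlabeled reviews; when missing the
#'   fit's own training theta is used.
#' @param ... passed to [infer_theta()] for new data.
#' @return A tibble with `doc_id` and an `assigned` list-column of label
#'   sets.
#' @export
classify <- function(fit, newdata = NULL, ...) {
  stopifnot(inherits(fit, "lda_fit"))
  if (is.null(newdata)) {
    theta <- fit$theta
    ids <- fit$doc_ids
  } else {
    theta <- infer_theta(fit, newdata, ...)
    ids <- if (is.data.frame(newdata)) newdata$doc_id else
      as.character(seq_len(nrow(theta)))
  }
  tibble::tibble(doc_id = ids,
                 assigned = threshold_labels(theta, fit$topic_labels))
}

#' Per-label confusion counts for multi-label assignments
#'
#' Binary confusion per label over the shared document universe: a label is a
#' true positive for a document when both assigned and gold. Aggregated over
#' labels, `tp + fp + fn + tn` equals documents x labels.
#'
#' @param predicted tibble with `doc_id` and `assigned` list-column (from
#'   [classify()]).
#' @param gold tibble with `doc_id` and `labels` list-column (e.g. an
#'   annotated corpus).
#' @param labels the label universe; default the union of observed labels.
#' @return A tibble with columns `label`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predicted, gold, labels = NULL) {
  if (!setequal(predicted$doc_id, gold$doc_id) ||
      anyDuplicated(predicted$doc_id) || anyDuplicated(gold$doc_id)) {
    abort("predicted and gold must cover the same set of doc_ids exactly once")
  }
  gold <- gold[match(predicted$doc_id, gold$doc_id), ]
  labels <- labels %||%
    sort(unique(c(unlist(predicted$assigned), unlist(gold$labels))))
  pred_sets <- predicted$assigned
  gold_sets <- gold$labels
  rows <- lapply(labels, function(lab) {
    p <- vapply(pred_sets, function(s) lab %in% s, logical(1))
    g <- vapply(gold_sets, function(s) lab %in% s, logical(1))
    tibble::tibble(label = lab, tp = sum(p & g), fp = sum(p & !g),
                   fn = sum(!p & g), tn = sum(!p & !g))
  })
  dplyr::bind_rows(rows)
}

#' Precision, recall and F from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`; an undefined
#' denominator yields `NA` (the undefined marker), which averaging excludes
#' rather than treating as zero. `f_score` is the harmonic mean
#' `2PR / (P + R)`, 0 when `P + R = 0`, `NA` when either input is `NA`.
#'
#' @param counts a [confusion_counts()] tibble (or any data frame with `tp`,
#'   `fp`, `fn`).
#' @return For `precision_score`/`recall_score`: numeric vector. For
#'   `f_score`: numeric vector from precision/recall inputs.
#' @name classification-metrics
NULL

#' @rdname classification-metrics
#' @export
precision_score <- function(counts) {
  ifelse(counts$tp + counts$fp == 0, NA_real_,
         counts$tp / (counts$tp + counts$fp))
}

#' @rdname classification-metrics
#' @export
recall_score <- function(counts) {
  ifelse(counts$tp + counts$fn == 0, NA_real_,
         counts$tp / (counts$tp + counts$fn))
}

#' @rdname classification-metrics
#' @param precision,recall numeric vectors in \[0, 1\] (or `NA`).
#' @export
f_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall), NA_real_,
         ifelse(precision + recall == 0, 0,
                2 * precision * recall / (precision + recall)))
}

#' Evaluate multi-label classification by group
#'
#' Scores assignments against gold label sets, grouped by a metadata field
#' (typically disease). Per group, precision and recall are micro-averaged
#' over labels (counts pooled). Two F aggregations are reported because both
#' are in circulation: `f_micro`, the harmonic mean of the micro P and R, and
#' `f_macro_topics`, the arithmetic mean of per-label F-scores within the
#' group. A final `average` row holds the arithmetic mean of the per-group
#' values, excluding undefined (`NA`) entries.
#'
#' @param predicted tibble with `doc_id` and `assigned` (see [classify()]).
#' @param gold a corpus tibble with `doc_id`, `labels`, and the grouping
#'   field.
#' @param by grouping field name; default `"disease"`.
#' @param labels label universe; default observed union.
#' @return A tibble with columns `group`, `n_docs`, `precision`, `recall`,
#'   `f_micro`, `f_macro_topics`, the last row being the macro `average`.
#' @export
evaluate_classification <- function(predicted, gold, by = "disease",
                                    labels = NULL) {
  if (!by %in% names(gold)) abort(paste0("grouping field not present: ", by))
  labels <- labels %||%
    sort(unique(c(unlist(predicted$assigned), unlist(gold$labels))))
  pred <- predicted[match(gold$doc_id, predicted$doc_id), ]
  groups <- split(seq_len(nrow(gold)), gold[[by]])
  keep <- vapply(groups, function(idx) {
    sum(lengths(gold$labels[idx])) > 0
  }, logical(1))
  if (any(!keep)) {
    warn(paste0("group(s) without gold labels excluded: ",
                paste(names(groups)[!keep], collapse = ", ")))
    groups <- groups[keep]
  }
  per_group <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    cc <- confusion_counts(pred[idx, ], gold[idx, c("doc_id", "labels")],
                           labels = labels)
    micro <- dplyr::summarise(cc, tp = sum(.data$tp), fp = sum(.data$fp),
                              fn = sum(.data$fn))
    p <- precision_score(micro)
    r <- recall_score(micro)
    per_label_f <- f_score(precision_score(cc), recall_score(cc))
    tibble::tibble(
      group = g, n_docs = length(idx), precision = p, recall = r,
      f_micro = f_score(p, r),
      f_macro_topics = mean(per_label_f, na.rm = TRUE)
    )
  })
  out <- dplyr::bind_rows(per_group)
  avg <- tibble::tibble(
    group = "average", n_docs = sum(out$n_docs),
    precision = mean(out$precision, na.rm = TRUE),
    recall = mean(out$recall, na.rm = TRUE),
    f_micro = mean(out$f_micro, na.rm = TRUE),
    f_macro_topics = mean(out$f_macro_topics, na.rm = TRUE)
  )
  dplyr::bind_rows(out, avg)
}
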