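#' Construct a review corpus tibble
#'
#' A corpus is an ordinary tibble with one row per review and list-columns for
#' variable-length fields. Required columns are `doc_id` and at least one of
#' `raw_text` or `tokens`; optional columns are `pos_tags` (parallel to
#' `tokens`), `labels` (a set of taxonomy label ids per review), `disease`,
#' `hospital_level` (`"A"`, `"B"` or `"C"`) and `doctor_id`. All corpus-taking
#' functions in the package accept any data frame with these columns.
#'
#' @param doc_id character vector of document ids.
#' @param raw_text optional character vector of raw review text.
#' @param tokens optional list of character token vectors.
#' @param pos_tags optional list of part-of-speech tag vectors, each parallel
#'   to the corresponding `tokens` entry.
#' @param labels optional list of character label-id vectors (the review's
#'   topic label set).
#' @param disease,hospital_level,doctor_id optional character metadata.
#' @return A tibble with one row per review, validated with
#'   [validate_corpus()].
#' @examples
#' review_corpus(
#'   doc_id = c("r1", "r2"),
#'   tokens = list(c("good", "doctor"), c("long", "wait")),
#'   disease = c("influenza", "diabetes")
#' )
#' @export
review_corpus <- function(doc_id, raw_text = NULL, tokens = NULL,
                          pos_tags = NULL, labels = NULL, disease = NULL,
                          hospital_level = NULL, doctor_id = NULL) {
  n <- length(doc_id)
  corpus <- tibble::tibble(doc_id = as.character(doc_id))
  if (!is.null(raw_text)) corpus$raw_text <- as.character(raw_text)
  if (!is.null(tokens)) corpus$tokens <- tokens
  if (!is.null(pos_tags)) corpus$pos_tags <- pos_tags
  if (!is.null(labels)) corpus$labels <- labels
  if (!is.null(disease)) corpus$disease <- as.character(disease)
  if (!is.null(hospital_level)) corpus$hospital_level <- as.character(hospital_level)
  if (!is.null(doctor_id)) corpus$doctor_id <- as.character(doctor_id)
  validate_corpus(corpus)
}

#' Validate a review corpus
#'
#' Checks the corpus invariants: every review has `raw_text` or `tokens`;
#' `pos_tags`, when present, is parallel to `tokens`; `hospital_level` is one
#' of A/B/C when given. Optionally checks that all labels belong to a taxonomy.
#'
#' @param corpus a data frame of reviews (see [review_corpus()]).
#' @param taxonomy optional taxonomy (see [load_taxonomy()]); when supplied,
#'   every review label must be one of its label ids.
#' @return The corpus, invisibly unchanged, as a tibble.
#' @export
validate_corpus <- function(corpus, taxonomy = NULL) {
  corpus <- tibble::as_tibble(corpus)
  if (!"doc_id" %in% names(corpus)) abort("corpus must have a doc_id column")
  has_text <- if ("raw_text" %in% names(corpus)) {
    !is.na(corpus$raw_text)
  } else {
    rep(FALSE, nrow(corpus))
  }
  has_tok <- if ("tokens" %in% names(corpus)) {
    !vapply(corpus$tokens, is.null, logical(1))
  } else {
    rep(FALSE, nrow(corpus))
  }
  bad <- which(!(has_text | has_tok))
  if (length(bad) > 0) {
    abort(paste0("review ", bad[1], " (doc_id ", corpus$doc_id[bad[1]],
                 "): missing field, needs raw_text or tokens"))
  }
  if ("pos_tags" %in% names(corpus) && "tokens" %in% names(corpus)) {
    nt <- lengths(corpus$tokens)
    np <- lengths(corpus$pos_tags)
    has_tags <- !vapply(corpus$pos_tags, is.null, logical(1))
    bad <- which(has_tags & np != nt)
    if (length(bad) > 0) {
      abort(paste0("review ", bad[1], ": pos_tags length ", np[bad[1]],
                   " != tokens length ", nt[bad[1]]))
    }
  }
  if ("hospital_level" %in% names(corpus)) {
    lv <- corpus$hospital_level
    if (any(!is.na(lv) & !lv %in% c("A", "B", "C"))) {
      abort("hospital_level must be one of A, B, C")
    }
  }
  if (!is.null(taxonomy) && "labels" %in% names(corpus)) {
    known <- taxonomy$label_id
    stray <- setdiff(unique(unlist(corpus$labels)), known)
    if (length(stray) > 0) {
      abort(paste0("labels not in taxonomy: ", paste(stray, collapse = ", ")))
    }
  }
  corpus
}

#' Per-document token counts
#'
#' @param corpus a review corpus with a `tokens` column.
#' @return Integer vector of token counts, one per review.
#' @export
doc_lengths <- function(corpus) {
  if (!"tokens" %in% names(corpus)) abort("corpus has no tokens column")
  lengths(corpus$tokens)
}

# fields serialized to/from disk, in canonical order
corpus_fields <- c("doc_id", "raw_text", "tokens", "pos_tags", "labels",
                   "disease", "hospital_level", "doctor_id")

#' Read a review corpus from JSONL or CSV
#'
#' The canonical on-disk format is JSONL: one JSON object per line with fields
#' `doc_id`, and any of `raw_text`, `tokens` (array), `pos_tags` (array),
#' `labels` (array), `disease`, `hospital_level`, `doctor_id`. The CSV dialect
#' stores `tokens`, `pos_tags` and `labels` as space-joined strings.
#' Input order is preserved.
#'
#' @param path file to read.
#' @param dialect `"jsonl"` (default) or `"csv"`.
#' @return A validated corpus tibble.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, dialect = c("jsonl", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) abort("empty corpus file")
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(
        jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
        error = function(e) abort(paste0("line ", i, ": malformed JSON: ",
                                         conditionMessage(e)))
      )
      if (is.null(rec$doc_id)) {
        abort(paste0("line ", i, ": missing field doc_id"))
      }
      if (is.null(rec$raw_text) && is.null(rec$tokens)) {
        abort(paste0("line ", i, ": missing field, needs raw_text or tokens"))
      }
      rec
    })
    get_chr <- function(field) {
      vapply(recs, function(r) {
        v <- r[[field]]
        if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)[1]
      }, character(1))
    }
    get_list <- function(field) {
      present <- vapply(recs, function(r) !is.null(r[[field]]), logical(1))
      if (!any(present)) return(NULL)
      lapply(recs, function(r) {
        if (is.null(r[[field]])) NULL else as.character(r[[field]])
      })
    }
    corpus <- tibble::tibble(doc_id = get_chr("doc_id"))
    raw <- get_chr("raw_text")
    if (any(!is.na(raw))) corpus$raw_text <- raw
    for (f in c("tokens", "pos_tags", "labels")) {
      col <- get_list(f)
      if (!is.null(col)) corpus[[f]] <- col
    }
    for (f in c("disease", "hospital_level", "doctor_id")) {
      col <- get_chr(f)
      if (any(!is.na(col))) corpus[[f]] <- col
    }
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                   na.strings = "")
    if (!"doc_id" %in% names(df)) abort("csv corpus must have a doc_id column")
    corpus <- tibble::as_tibble(df)
    corpus$doc_id <- as.character(corpus$doc_id)
    split_col <- function(x) {
      lapply(x, function(s) if (is.na(s)) NULL else strsplit(s, " ", fixed = TRUE)[[1]])
    }
    for (f in c("tokens", "pos_tags", "labels")) {
      if (f %in% names(corpus)) corpus[[f]] <- split_col(corpus[[f]])
    }
  }
  keep <- intersect(corpus_fields, names(corpus))
  validate_corpus(corpus[keep])
}

#' Write a review corpus to JSONL or CSV
#'
#' @param corpus a review corpus tibble.
#' @param path output file.
#' @param dialect `"jsonl"` (default) or `"csv"` (list-columns space-joined).
#' @return `path`, invisibly.
#' @seealso [read_corpus()]
#' @export
write_corpus <- function(corpus, path, dialect = c("jsonl", "csv")) {
  dialect <- match.arg(dialect)
  corpus <- validate_corpus(corpus)
  fields <- intersect(corpus_fields, names(corpus))
  if (dialect == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      rec <- list()
      for (f in fields) {
        v <- corpus[[f]][[i]]
        if (is.null(v) || (length(v) == 1 && is.na(v))) next
        rec[[f]] <- if (f %in% c("tokens", "pos_tags", "labels")) as.list(v) else v
      }
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- corpus[fields]
    for (f in c("tokens", "pos_tags", "labels")) {
      if (f %in% names(df)) {
        df[[f]] <- vapply(df[[f]], function(v) {
          if (is.null(v)) NA_character_ else paste(v, collapse = " ")
        }, character(1))
      }
    }
    write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Descriptive corpus summary by group
#'
#' Per-group review counts and shares, distinct doctor counts, reviews per
#' doctor and mean review length, in the shape of the published descriptive
#' table for the haodf.com physician-review corpus. Displayed values follow
#' that table's rounding (share to 2 decimals, reviews per doctor to 1,
#' mean length to integer).
#'
#' @param corpus a review corpus.
#' @param by name of the grouping column, default `"disease"`.
#' @return A tibble with columns `group`, `n_reviews`, `share_pct`,
#'   `n_doctors`, `reviews_per_doctor`, `mean_length`. `reviews_per_doctor` is
#'   `NA` when a group has no doctor ids; `mean_length` is `NA` without
#'   tokens. Shares sum to 100 up to rounding.
#' @examples
#' corpus <- review_corpus(
#'   doc_id = c("a", "b", "c"),
#'   tokens = list(c("x", "y"), "z", c("u", "v", "w")),
#'   disease = c("influenza", "influenza", "diabetes"),
#'   doctor_id = c("d1", "d2", "d3")
#' )
#' corpus_summary(corpus, by = "disease")
#' @export
corpus_summary <- function(corpus, by = "disease") {
  if (!by %in% names(corpus)) abort(paste0("grouping field not present: ", by))
  corpus <- tibble::as_tibble(corpus)
  corpus$.len <- if ("tokens" %in% names(corpus)) lengths(corpus$tokens) else NA_integer_
  total <- nrow(corpus)
  out <- corpus |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::summarise(
      n_reviews = dplyr::n(),
      n_doctors = if ("doctor_id" %in% names(corpus)) {
        dplyr::n_distinct(.data$doctor_id[!is.na(.data$doctor_id)])
      } else {
        NA_integer_
      },
      mean_length = round(mean(.data$.len)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      share_pct = round(100 * .data$n_reviews / total, 2),
      reviews_per_doctor = ifelse(
        is.na(.data$n_doctors) | .data$n_doctors == 0,
        NA_real_,
        round(.data$n_reviews / .data$n_doctors, 1)
      )
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_reviews)) |>
    dplyr::select("group", "n_reviews", "share_pct", "n_doctors",
                  "reviews_per_doctor", "mean_length")
  out
}

#' Published descriptive statistics of a large physician-review corpus
#'
#' Reference per-disease descriptive statistics (review counts and shares,
#' doctor counts, reviews per physician, mean review length in words) for a
#' 122,716-review corpus of Chinese physician reviews from haodf.com covering
#' the nine most-reviewed diseases. Doctor counts are per disease, so their
#' total exceeds the number of globally unique doctors.
#'
#' @return A tibble with columns `disease`, `n_reviews`, `pct_reviews`,
#'   `n_doctors`, `pct_doctors`, `reviews_per_physician`, `mean_words`.
#' @export
published_review_stats <- function() {
  tibble::as_tibble(read.csv(rm_extdata("review_stats.csv"),
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8"))
}

#' Published per-disease classification benchmark scores
#'
#' Reference precision, recall and F-score of the labeled-LDA topic classifier
#' on a 200-review blind test set, per disease. Useful as a benchmark shape
#' for [evaluate_classification()] output and for checking average-row
#' aggregation.
#'
#' @return A tibble with columns `disease`, `precision`, `recall`, `f_score`.
#' @export
published_classification_scores <- function() {
  tibble::as_tibble(read.csv(rm_extdata("classification_scores.csv"),
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8"))
}

#' Published group-contrast effect-size triples
#'
#' Reference (delta-u, Cohen d, t) triples for per-topic contrasts between
#' patient groups (acute vs chronic, mild vs serious disease) reported for the
#' haodf.com corpus, used with [t_from_printed_summary()] to check the internal
#' consistency of printed summary statistics.
#'
#' @return A tibble with columns `comparison`, `label`, `group1`, `group2`,
#'   `delta_u`, `cohen_d`, `t`.
#' @export
published_effect_triples <- function() {
  tibble::as_tibble(read.csv(rm_extdata("effect_triples.csv"),
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8"))
}
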