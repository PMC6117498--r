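# Text preprocessing: segmentation hook, part-of-speech filtering, stopword
# removal, entity placeholder substitution and synonym canonicalization.
#
# The full pipeline order is segment -> pos_filter -> remove_stopwords ->
# replace_entities -> replace_synonyms. Entities are normalized before
# synonyms so that the surface variants of an entity never depend on
# thesaurus coverage; entity rules are the more specific of the two.

#' Segment raw text into tokens
#'
#' The tokenizer is a pluggable hook: any function taking one string and
#' returning either a character vector of tokens or a list with `tokens` and
#' parallel `pos_tags`. The default splits on whitespace, which keeps the
#' pipeline language-agnostic; a real segmenter (for unsegmented languages
#' such as Chinese) plugs in unchanged.
#'
#' @param raw_text a single string.
#' @param tokenizer optional hook; default whitespace splitter.
#' @return A list with `tokens` (character) and `pos_tags` (character or
#'   `NULL`).
#' @examples
#' segment("good doctor")$tokens
#' @export
segment <- function(raw_text, tokenizer = NULL) {
  if (is.null(tokenizer)) {
    tokens <- strsplit(trimws(raw_text), "\\s+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    return(list(tokens = tokens, pos_tags = NULL))
  }
  out <- tokenizer(raw_text)
  if (is.character(out)) return(list(tokens = out, pos_tags = NULL))
  if (!is.list(out) || is.null(out$tokens)) {
    abort("tokenizer hook must return a character vector or list(tokens, pos_tags)")
  }
  if (!is.null(out$pos_tags) && length(out$pos_tags) != length(out$tokens)) {
    abort("tokenizer hook returned pos_tags of different length than tokens")
  }
  list(tokens = out$tokens, pos_tags = out$pos_tags)
}

#' Filter tokens by part-of-speech tag
#'
#' Keeps the subsequence of tokens whose tag is in `keep`; the default keeps
#' content words (nouns, verbs, adjectives, adverbs).
#'
#' @param tokens character tokens.
#' @param pos_tags parallel character tags.
#' @param keep tags to retain.
#' @return The retained tokens, order preserved.
#' @export
pos_filter <- function(tokens, pos_tags,
                       keep = c("noun", "verb", "adjective", "adverb")) {
  if (is.null(pos_tags)) {
    abort(paste0("pos_tags missing: supply a tagging tokenizer or disable ",
                 "part-of-speech filtering"))
  }
  if (length(pos_tags) != length(tokens)) {
    abort("pos_tags must be parallel to tokens")
  }
  tokens[pos_tags %in% keep]
}

#' Remove stopwords
#'
#' @param tokens character tokens.
#' @param stopwords character stoplist; exact, case-sensitive match.
#' @return Tokens with stoplist members removed, order preserved.
#' @export
remove_stopwords <- function(tokens, stopwords) {
  tokens[!tokens %in% stopwords]
}

#' Load the packaged stopword list
#'
#' @param path plain-text file, one stopword per line; default the packaged
#'   minimal English list.
#' @return Character vector of stopwords.
#' @export
load_stopwords <- function(path = NULL) {
  path <- path %||% rm_extdata("stopwords.txt")
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x[nzchar(trimws(x))]
}

#' Load a synonym thesaurus
#'
#' A thesaurus maps surface variants to canonical tokens. The mapping must be
#' functional (one canonical per variant) and idempotent: canonicals are not
#' themselves variants, so applying the replacement twice equals applying it
#' once.
#'
#' @param path TSV file `variant <TAB> canonical`; default the packaged
#'   synthetic thesaurus.
#' @return A tibble with columns `variant`, `canonical`.
#' @export
load_thesaurus <- function(path = NULL) {
  path <- path %||% rm_extdata("thesaurus.tsv")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) abort(paste0("thesaurus line ", bad[1], ": expected 2 fields"))
  map <- tibble::tibble(variant = vapply(parts, `[`, "", 1),
                        canonical = vapply(parts, `[`, "", 2))
  if (anyDuplicated(map$variant)) {
    abort(paste0("thesaurus variant mapped twice: ",
                 map$variant[duplicated(map$variant)][1]))
  }
  loops <- intersect(map$variant, map$canonical)
  if (length(loops) > 0) {
    abort(paste0("thesaurus not idempotent, canonical is also a variant: ",
                 loops[1]))
  }
  map
}

#' Replace synonyms by their canonical form
#'
#' @param tokens character tokens.
#' @param thesaurus tibble from [load_thesaurus()] (or any data frame with
#'   `variant` and `canonical` columns).
#' @return Tokens with each mapped variant replaced by its canonical; length
#'   preserved; idempotent.
#' @examples
#' thes <- tibble::tibble(variant = c("a", "c"), canonical = c("b", "b"))
#' replace_synonyms(c("a", "c", "d"), thes)
#' @export
replace_synonyms <- function(tokens, thesaurus) {
  idx <- match(tokens, thesaurus$variant)
  hit <- !is.na(idx)
  tokens[hit] <- thesaurus$canonical[idx[hit]]
  tokens
}

#' Load entity substitution rules
#'
#' Ordered regular-expression rules mapping whole tokens to entity
#' placeholders such as `#BODY_TEMPERATURE#` (both "39°C" and "40°C" become
#' the same symbol, pooling sparse surface forms into one type). The packaged
#' default covers the digit-patterned entities (temperature, age, height,
#' weight, date, time, money, percent, number); person/location/organization
#' recognition is supported through user-supplied gazetteer rules (literal
#' alternation patterns).
#'
#' @param path TSV file `pattern <TAB> placeholder`, one rule per line,
#'   earlier rules win.
#' @return A tibble with columns `pattern`, `placeholder`, order preserved.
#' @export
load_entity_rules <- function(path = NULL) {
  path <- path %||% rm_extdata("entity_rules.tsv")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) abort(paste0("entity rule line ", bad[1], ": expected 2 fields"))
  rules <- tibble::tibble(pattern = vapply(parts, `[`, "", 1),
                          placeholder = vapply(parts, `[`, "", 2))
  for (i in seq_len(nrow(rules))) {
    ok <- tryCatch({ grepl(rules$pattern[i], "x", perl = TRUE); TRUE },
                   error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) abort(paste0("malformed entity pattern on line ", i, ": ",
                          rules$pattern[i]))
  }
  rules
}

#' Replace entity tokens by placeholders
#'
#' Applies the ordered rules token-wise; the first matching rule wins, tokens
#' already equal to a placeholder are never rewritten, and unmatched tokens
#' pass through unchanged. Length is preserved and re-application is a no-op
#' on the placeholders.
#'
#' @param tokens character tokens.
#' @param rules tibble from [load_entity_rules()].
#' @return Tokens with matched entities replaced by their placeholder.
#' @examples
#' replace_entities(c("39°C", "fever"), load_entity_rules())
#' @export
replace_entities <- function(tokens, rules) {
  out <- tokens
  done <- tokens %in% rules$placeholder
  for (i in seq_len(nrow(rules))) {
    hit <- !done & grepl(rules$pattern[i], out, perl = TRUE)
    out[hit] <- rules$placeholder[i]
    done <- done | hit
  }
  out
}

#' Run the full preprocessing pipeline on a corpus
#'
#' segment -> part-of-speech filter (only when the tokenizer supplies tags)
#' -> stopword removal -> entity placeholder substitution -> synonym
#' canonicalization. Deterministic; the result replaces the `tokens` column.
#'
#' @param corpus a review corpus with `raw_text`.
#' @param tokenizer optional segmentation hook (see [segment()]).
#' @param stopwords stoplist; default packaged.
#' @param rules entity rules; default packaged.
#' @param thesaurus synonym thesaurus; default packaged.
#' @param pos_keep tags to keep when tags are available; `NULL` (default)
#'   skips part-of-speech filtering unless the tokenizer returns tags.
#' @return The corpus with preprocessed `tokens` (and `pos_tags` dropped).
#' @export
preprocess_corpus <- function(corpus, tokenizer = NULL, stopwords = NULL,
                              rules = NULL, thesaurus = NULL,
                              pos_keep = NULL) {
  if (!"raw_text" %in% names(corpus)) abort("corpus has no raw_text column")
  stopwords <- stopwords %||% load_stopwords()
  rules <- rules %||% load_entity_rules()
  thesaurus <- thesaurus %||% load_thesaurus()
  corpus <- tibble::as_tibble(corpus)
  corpus$tokens <- lapply(corpus$raw_text, function(txt) {
    seg <- segment(txt, tokenizer)
    tok <- seg$tokens
    if (!is.null(seg$pos_tags)) {
      tok <- pos_filter(tok, seg$pos_tags,
                        keep = pos_keep %||% c("noun", "verb", "adjective",
                                               "adverb"))
    } else if (!is.null(pos_keep)) {
      abort("pos_keep given but tokenizer supplies no tags; disable filtering")
    }
    tok <- remove_stopwords(tok, stopwords)
    tok <- replace_entities(tok, rules)
    replace_synonyms(tok, thesaurus)
  })
  corpus$pos_tags <- NULL
  validate_corpus(corpus)
}

#' Build a vocabulary from a corpus
#'
#' Indexes tokens whose corpus frequency is at least `min_count`, in order of
#' first appearance; deterministic.
#'
#' @param corpus a review corpus with `tokens`, or a list of token vectors.
#' @param min_count minimum corpus frequency; default 1.
#' @return A `"vocabulary"`: list with `token` (character, index order) and
#'   `V` (size).
#' @export
build_vocabulary <- function(corpus, min_count = 1) {
  token_lists <- if (is.data.frame(corpus)) corpus$tokens else corpus
  all_tokens <- unlist(token_lists, use.names = FALSE)
  uniq <- unique(all_tokens)
  counts <- tabulate(match(all_tokens, uniq), nbins = length(uniq))
  keep <- uniq[counts >= min_count]
  if (length(keep) == 0) abort("empty vocabulary after min_count filtering")
  structure(list(token = keep, V = length(keep)), class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> V =", x$V, "\n")
  cat("  ", paste(head(x$token, 8), collapse = ", "),
      if (x$V > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Convert documents to bag-of-words index sequences
#'
#' Out-of-vocabulary tokens are dropped; in-vocabulary order is preserved
#' (the Gibbs sampler is order-insensitive, but a fixed order makes runs
#' reproducible). Documents that become empty are retained with length 0.
#'
#' @param corpus a review corpus with `tokens`, or a list of token vectors.
#' @param vocab a [build_vocabulary()] result.
#' @return List of integer index vectors (1-based into `vocab$token`).
#' @export
docs_to_bow <- function(corpus, vocab) {
  token_lists <- if (is.data.frame(corpus)) corpus$tokens else corpus
  lapply(token_lists, function(tok) {
    idx <- match(tok, vocab$token)
    idx[!is.na(idx)]
  })
}
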