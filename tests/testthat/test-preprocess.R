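test_that("segmentation splits text and validates tokenizer hooks", {
  expect_equal(segment("good doctor")$tokens, c("good", "doctor"))
  expect_equal(segment("  good   doctor ")$tokens, c("good", "doctor"))
  expect_equal(segment("")$tokens, character(0))

  tagger <- function(txt) {
    tok <- strsplit(txt, " ")[[1]]
    list(tokens = tok, pos_tags = rep("noun", length(tok)))
  }
  out <- segment("a b", tagger)
  expect_equal(out$pos_tags, c("noun", "noun"))
  bad <- function(txt) list(tokens = c("a", "b"), pos_tags = "noun")
  expect_error(segment("a b", bad), "different length")
})

test_that("part-of-speech filtering keeps content-word subsequences", {
  tok <- c("doctor", "the", "explained", "clearly", "le")
  tags <- c("noun", "particle", "verb", "adverb", "particle")
  expect_equal(pos_filter(tok, tags), c("doctor", "explained", "clearly"))
  expect_equal(pos_filter(tok, rep("noun", 5)), tok)
  expect_equal(pos_filter(tok, rep("particle", 5)), character(0))
  expect_error(pos_filter(tok, NULL), "disable")
  expect_error(pos_filter(tok, tags[1:2]), "parallel")
})

test_that("stopword removal equals the order-preserving set difference", {
  expect_equal(remove_stopwords(c("a", "b"), character(0)), c("a", "b"))
  expect_equal(remove_stopwords(c("a", "b"), c("a", "b")), character(0))
  set.seed(42)
  for (i in 1:20) {
    tok <- sample(letters[1:6], 12, replace = TRUE)
    stop <- sample(letters[1:6], 3)
    oracle <- tok[!(tok %in% stop)]  # brute-force filter
    expect_equal(remove_stopwords(tok, stop), oracle)
  }
})

test_that("synonym replacement is functional, idempotent and length-safe", {
  thes <- tibble::tibble(variant = c("a", "c"), canonical = c("b", "b"))
  expect_equal(replace_synonyms(c("a", "c", "d"), thes), c("b", "b", "d"))
  set.seed(7)
  thes2 <- load_thesaurus()
  for (i in 1:10) {
    tok <- sample(c(thes2$variant[1:10], letters), 15, replace = TRUE)
    once <- replace_synonyms(tok, thes2)
    expect_length(once, length(tok))
    expect_equal(replace_synonyms(once, thes2), once)
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\tc"), path)
  expect_error(load_thesaurus(path), "idempotent")
})

test_that("entity rules pool surface variants into one placeholder", {
  rules <- load_entity_rules()
  expect_equal(replace_entities(c("39°C", "40°C"), rules),
               c("#BODY_TEMPERATURE#", "#BODY_TEMPERATURE#"))
  expect_equal(replace_entities("38.5°C", rules), "#BODY_TEMPERATURE#")
  expect_equal(replace_entities(c("fever", "w0001"), rules),
               c("fever", "w0001"))
  expect_equal(replace_entities(c("12yo", "170cm", "60kg", "2014-05-02",
                                  "9:30", "¥120", "15%", "42"), rules),
               c("#AGE#", "#HEIGHT#", "#WEIGHT#", "#DATE#", "#TIME#",
                 "#MONEY#", "#PERCENT#", "#NUMBER#"))
  # placeholders are stable under re-application
  once <- replace_entities(c("39°C", "12yo"), rules)
  expect_equal(replace_entities(once, rules), once)
  # earlier rule wins: "42" matches only NUMBER, "42yo" only AGE, and a
  # custom overlapping rule set resolves by order
  overlap <- tibble::tibble(pattern = c("^4[0-9]$", "^[0-9]+$"),
                            placeholder = c("#AGE#", "#NUMBER#"))
  expect_equal(replace_entities(c("42", "7"), overlap),
               c("#AGE#", "#NUMBER#"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("([bad\t#X#", path)
  expect_error(load_entity_rules(path), "malformed")
})

test_that("vocabulary building matches a counting oracle", {
  corpus <- review_corpus(
    doc_id = c("a", "b"),
    tokens = list(c("x", "y", "x"), c("y", "z"))
  )
  v1 <- build_vocabulary(corpus, min_count = 1)
  expect_equal(v1$token, c("x", "y", "z"))  # first-appearance order
  v2 <- build_vocabulary(corpus, min_count = 2)
  expect_equal(v2$token, c("x", "y"))
  expect_error(build_vocabulary(corpus, min_count = 10), "empty vocabulary")

  set.seed(13)
  for (i in 1:10) {
    toks <- lapply(1:5, function(j) sample(letters[1:8], 10, replace = TRUE))
    mc <- sample(1:3, 1)
    vocab <- build_vocabulary(toks, min_count = mc)
    counts <- table(unlist(toks))
    expect_setequal(vocab$token, names(counts)[counts >= mc])
  }
})

test_that("bag-of-words conversion conserves in-vocabulary tokens", {
  corpus <- review_corpus(
    doc_id = c("a", "b", "c"),
    tokens = list(c("x", "y", "q"), c("q", "q"), c("y", "x"))
  )
  vocab <- build_vocabulary(list(c("x", "y")), min_count = 1)
  bow <- docs_to_bow(corpus, vocab)
  expect_equal(bow[[1]], c(1L, 2L))
  expect_equal(bow[[2]], integer(0))  # fully out-of-vocabulary, retained
  expect_equal(vocab$token[bow[[3]]], c("y", "x"))
  in_vocab <- sum(unlist(corpus$tokens) %in% vocab$token)
  expect_equal(sum(lengths(bow)), in_vocab)
})

test_that("rendered corpora round-trip exactly through the pipeline", {
  cfg <- preset_config(n_docs = 60, seed = 21)
  out <- generate_corpus(cfg)
  noisy <- render_raw_text(out$corpus, entity_rate = 1, synonym_rate = 0.4,
                           stopword_rate = 0.25, seed = 22)
  clean <- preprocess_corpus(noisy)
  expect_identical(clean$tokens, out$corpus$tokens)

  # a single injected temperature comes back as one placeholder token
  doc <- review_corpus("t1", tokens = list(c("w0005", "#BODY_TEMPERATURE#",
                                             "w0006")))
  rendered <- render_raw_text(doc, entity_rate = 1, seed = 23)
  expect_true(grepl("°C", rendered$raw_text))
  back <- preprocess_corpus(rendered)
  expect_equal(back$tokens[[1]],
               c("w0005", "#BODY_TEMPERATURE#", "w0006"))
  expect_equal(sum(back$tokens[[1]] == "#BODY_TEMPERATURE#"), 1)
})

test_that("pipeline never increases token count", {
  set.seed(31)
  corpus <- random_corpus(n = 12, seed = 31)
  clean <- preprocess_corpus(corpus)
  raw_lens <- vapply(corpus$raw_text,
                     function(t) length(segment(t)$tokens), integer(1))
  expect_true(all(lengths(clean$tokens) <= raw_lens))
})
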