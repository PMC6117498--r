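taxonomy_domains <- c("physician-related", "system-related", "patient-related")

#' Load a topic taxonomy from YAML
#'
#' A taxonomy file lists labels with `id`, `name` and `domain`
#' (physician-related, system-related or patient-related). The packaged
#' default is the nine-topic patient-experience taxonomy: medical ethics (ME),
#' medical competence (MC), medical advice and prescription (MAP),
#' communication skills (CS), financing (F), operation process (OP), patient
#' profile (PP), symptoms (S), and diagnosis and pathogenesis (DAP).
#'
#' @param path YAML file; default is the packaged nine-label taxonomy.
#' @return A tibble with columns `label_id`, `name`, `domain` and attribute
#'   `L` (label count), classed `"taxonomy"`.
#' @examples
#' tax <- load_taxonomy()
#' n_labels(tax)
#' table(tax$domain)
#' @export
load_taxonomy <- function(path = NULL) {
  path <- path %||% rm_extdata("taxonomy.yaml")
  spec <- yaml::read_yaml(path)
  labels <- spec$labels
  if (is.null(labels) || length(labels) == 0) {
    abort("taxonomy file lists no labels")
  }
  ids <- vapply(labels, function(x) as.character(x$id %||% NA_character_),
                character(1))
  if (anyNA(ids)) abort("taxonomy label without id")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate label id: ", ids[duplicated(ids)][1]))
  }
  domains <- vapply(labels, function(x) as.character(x$domain %||% NA_character_),
                    character(1))
  if (anyNA(domains)) {
    abort(paste0("label without domain: ", ids[is.na(domains)][1]))
  }
  bad <- setdiff(unique(domains), taxonomy_domains)
  if (length(bad) > 0) {
    abort(paste0("unknown domain: ", bad[1], " (expected one of ",
                 paste(taxonomy_domains, collapse = ", "), ")"))
  }
  nms <- vapply(labels, function(x) as.character(x$name %||% x$id), character(1))
  tax <- tibble::tibble(label_id = ids, name = nms, domain = domains)
  attr(tax, "L") <- nrow(tax)
  class(tax) <- c("taxonomy", class(tax))
  tax
}

#' Number of labels in a taxonomy
#'
#' @param taxonomy a taxonomy tibble from [load_taxonomy()].
#' @return Integer label count L.
#' @export
n_labels <- function(taxonomy) nrow(taxonomy)

#' Load a patient-grouping scheme
#'
#' A grouping scheme maps a review metadata field (disease name or hospital
#' level) to one of two patient groups. The three packaged schemes follow the
#' published groupings for the haodf.com corpus:
#' * `acute_vs_chronic` — influenza, infantile pneumonia, infantile diarrhea
#'   and hyperthyroidism are acute; hypertension, diabetes and infertility are
#'   chronic.
#' * `mild_vs_serious` — influenza is mild; liver cancer and gastric cancer
#'   are serious.
#' * `high_vs_low_hospital` — A-level hospitals are high; B- and C-level are
#'   low.
#' Keys are matched case-insensitively after trimming; reviews whose key is
#' not mapped receive no group.
#'
#' @param scheme one of the packaged scheme names above, or a path to a YAML
#'   file with fields `name`, `field` and `groups` (group -> list of keys).
#' @return A list with `name`, `field` and a `mapping` tibble (`key`,
#'   `group`), classed `"grouping_scheme"`.
#' @examples
#' sch <- load_grouping_scheme("acute_vs_chronic")
#' sch$mapping
#' @export
load_grouping_scheme <- function(scheme) {
  packaged <- c("acute_vs_chronic", "mild_vs_serious", "high_vs_low_hospital")
  path <- if (scheme %in% packaged) {
    rm_extdata(paste0("scheme_", scheme, ".yaml"))
  } else {
    scheme
  }
  spec <- yaml::read_yaml(path)
  if (is.null(spec$groups) || length(spec$groups) == 0) {
    abort("grouping scheme lists no groups")
  }
  mapping <- dplyr::bind_rows(lapply(names(spec$groups), function(g) {
    tibble::tibble(key = tolower(trimws(as.character(spec$groups[[g]]))),
                   group = g)
  }))
  if (anyDuplicated(mapping$key)) {
    abort(paste0("key mapped to two groups: ",
                 mapping$key[duplicated(mapping$key)][1]))
  }
  structure(
    list(name = spec$name %||% scheme, field = spec$field %||% "disease",
         mapping = mapping, groups = names(spec$groups)),
    class = "grouping_scheme"
  )
}

#' Assign patient groups to reviews
#'
#' Adds a `group` column to the corpus by looking up the scheme's field
#' (case-insensitive, trimmed). Reviews with unmapped keys get `NA`, never a
#' wrong group, so each scheme partitions the mapped reviews.
#'
#' @param corpus a review corpus.
#' @param scheme a `grouping_scheme` from [load_grouping_scheme()], or a
#'   packaged scheme name.
#' @return The corpus with a `group` character column.
#' @examples
#' corpus <- review_corpus("r1", tokens = list("ok"), disease = "Influenza")
#' assign_group(corpus, "acute_vs_chronic")$group
#' @export
assign_group <- function(corpus, scheme) {
  if (is.character(scheme)) scheme <- load_grouping_scheme(scheme)
  field <- scheme$field
  if (!field %in% names(corpus)) {
    abort(paste0("corpus has no ", field, " column required by scheme ",
                 scheme$name))
  }
  key <- tolower(trimws(corpus[[field]]))
  idx <- match(key, scheme$mapping$key)
  corpus$group <- scheme$mapping$group[idx]
  corpus
}
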