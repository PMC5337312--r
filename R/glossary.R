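normalize_term <- function(x) tolower(trimws(x))

#' Build a terminology glossary from a graph's entities
#'
#' The glossary is the metathesaurus that maps surface terms (canonical
#' names and synonyms) to typed entities; lookup is case-insensitive after
#' whitespace normalization.
#'
#' @param graph A `med_kg`.
#' @return A tibble with columns `term`, `entity_id`, `concept`.
#' @export
#' @examples
#' glossary_build(kg_demo_graph())
glossary_build <- function(graph) {
  stopifnot(inherits(graph, "med_kg"))
  ent <- graph$entities
  out <- tibble(
    term = unlist(ent$synonyms, use.names = FALSE),
    entity_id = rep(ent$entity_id, lengths(ent$synonyms)),
    concept = rep(ent$concept, lengths(ent$synonyms))
  )
  out %>%
    mutate(term = normalize_term(.data$term)) %>%
    distinct() %>%
    arrange(.data$term, .data$entity_id)
}

validate_glossary <- function(glossary, graph = NULL) {
  gl <- as_tibble(glossary)
  need <- c("term", "entity_id", "concept")
  if (!all(need %in% names(gl))) {
    kgc_abort("glossary needs term, entity_id, concept columns",
              "kgchains_format_error")
  }
  if (!is.null(graph)) {
    missing_ids <- setdiff(gl$entity_id, graph$entities$entity_id)
    if (length(missing_ids)) {
      kgc_abort(paste0("glossary maps term(s) to unknown entities: ",
                       paste(head(missing_ids, 5), collapse = ", ")),
                "kgchains_schema_error")
    }
  }
  gl
}

#' Read / write a glossary as TSV
#'
#' The on-disk format has columns `term`, `entity_id`, `concept_class`.
#'
#' @param path File path.
#' @return `read_glossary()` returns the glossary tibble (columns `term`,
#'   `entity_id`, `concept`); `write_glossary()` returns `path` invisibly.
#' @export
read_glossary <- function(path) {
  if (!file.exists(path)) {
    kgc_abort(paste0("no such file: ", path), "kgchains_io_error")
  }
  gl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("term", "entity_id", "concept_class") %in% names(gl))) {
    kgc_abort("glossary TSV needs term, entity_id, concept_class columns",
              "kgchains_format_error")
  }
  gl %>%
    rename(concept = "concept_class") %>%
    mutate(term = normalize_term(.data$term)) %>%
    distinct() %>%
    arrange(.data$term, .data$entity_id)
}

#' @rdname read_glossary
#' @param glossary A glossary tibble.
#' @export
write_glossary <- function(glossary, path) {
  gl <- validate_glossary(glossary)
  readr::write_tsv(gl %>% rename(concept_class = "concept"), path,
                   progress = FALSE)
  invisible(path)
}

#' Look up terms in a glossary
#'
#' @param glossary A glossary tibble.
#' @param terms Character vector of surface terms.
#' @return Character vector of entity ids (`NA` where unknown); when a
#'   normalized term maps to several entities the lexicographically smallest
#'   entity id wins, for determinism.
#' @export
glossary_lookup <- function(glossary, terms) {
  gl <- validate_glossary(glossary) %>%
    arrange(.data$term, .data$entity_id) %>%
    distinct(.data$term, .keep_all = TRUE)
  gl$entity_id[match(normalize_term(terms), gl$term)]
}

#' Read / write seed facts as TSV
#'
#' Seed facts are expert-asserted true relation instances used to bootstrap
#' pattern confidence.  Columns: `relation`, `subject_id`, `object_id`.
#'
#' @param path File path.
#' @return `read_seed_facts()` returns a tibble with columns `schema`,
#'   `subject`, `object`; `write_seed_facts()` returns `path` invisibly.
#' @export
read_seed_facts <- function(path) {
  if (!file.exists(path)) {
    kgc_abort(paste0("no such file: ", path), "kgchains_io_error")
  }
  sf <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("relation", "subject_id", "object_id") %in% names(sf))) {
    kgc_abort("seed TSV needs relation, subject_id, object_id columns",
              "kgchains_format_error")
  }
  sf %>%
    select(schema = "relation", subject = "subject_id",
           object = "object_id") %>%
    distinct() %>%
    arrange(.data$schema, .data$subject, .data$object)
}

#' @rdname read_seed_facts
#' @param seeds A tibble with columns `schema`, `subject`, `object`.
#' @export
write_seed_facts <- function(seeds, path) {
  sf <- as_tibble(seeds)
  readr::write_tsv(
    sf %>% select(relation = "schema", subject_id = "subject",
                  object_id = "object"),
    path, progress = FALSE)
  invisible(path)
}
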