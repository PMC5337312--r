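#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data := %||%
#' @importFrom dplyr %>% filter mutate select arrange group_by ungroup summarise
#'   distinct bind_rows left_join anti_join semi_join inner_join across n
#'   row_number pull rename slice if_else first
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median predict setNames
#' @importFrom utils head tail
NULL

kgc_abort <- function(message, class, ...) {
  abort(message, class = c(class, "kgchains_error"), ...)
}

#' Concept classes of the medical knowledge model
#'
#' The closed set of concept classes an entity may belong to.  Four of them
#' (bodily part, symptom, disease, treatment) carry the three study relations;
#' the remainder cover the other terminology domains of the model.
#'
#' @return A character vector of class names.
#' @export
#' @examples
#' concept_classes()
concept_classes <- function() {
  c("BODILY_PART", "SYMPTOM", "DISEASE", "TREATMENT",
    "CLINICAL_HISTORY", "LABORATORY_TEST", "DRUG", "DEPARTMENT")
}

#' Relation schemas of the knowledge graph
#'
#' The three typed binary relations the graph stores: symptoms are located in
#' bodily parts, symptoms (clinical manifestations) cause diseases
#' (diagnoses), and diseases correspond to treatments.
#'
#' @return A tibble with columns `schema`, `domain` and `range`.
#' @export
#' @examples
#' relation_schemas()
relation_schemas <- function() {
  tibble(
    schema = c("LOCATED_IN", "CAUSE", "CORRESPONDED_TO"),
    domain = c("SYMPTOM", "SYMPTOM", "DISEASE"),
    range  = c("BODILY_PART", "DISEASE", "TREATMENT")
  )
}

schema_row <- function(schema) {
  s <- relation_schemas()
  row <- s[s$schema == schema, ]
  if (nrow(row) != 1L) {
    kgc_abort(paste0("unknown relation schema: ", schema),
              "kgchains_schema_error")
  }
  row
}

#' Turn a canonical name into a stable entity identifier
#'
#' Lower-cases, trims, and replaces runs of non-alphanumeric characters with
#' a single underscore, giving deterministic identifiers (and RDF IRIs)
#' across runs.
#'
#' @param x Character vector of names.
#' @return Character vector of slugs.
#' @export
#' @examples
#' slugify("Lung Inflammation")
slugify <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

empty_entities <- function() {
  tibble(
    entity_id = character(), canonical_name = character(),
    concept = character(), synonyms = list(), description = character()
  )
}

empty_relations <- function() {
  tibble(
    schema = character(), subject = character(), object = character(),
    confidence = double(), provenance = list()
  )
}

empty_provenance <- function() {
  tibble(document_id = character(), sentence_index = integer())
}

#' Create an empty knowledge graph
#'
#' A knowledge graph holds a table of typed entities (the vertices) and a
#' table of typed binary relations (the edges, the relation set S).
#'
#' @return An object of class `med_kg`.
#' @export
#' @examples
#' kg <- kg_new()
#' kg_size(kg)
kg_new <- function() {
  structure(
    list(entities = empty_entities(), relations = empty_relations()),
    class = "med_kg"
  )
}

#' @exportS3Method base::print
print.med_kg <- function(x, ...) {
  cat("<med_kg> ", nrow(x$entities), " entities, ",
      nrow(x$relations), " relations\n", sep = "")
  if (nrow(x$entities)) {
    tab <- table(x$entities$concept)
    cat("  entities: ",
        paste0(names(tab), "=", as.integer(tab), collapse = ", "), "\n",
        sep = "")
  }
  if (nrow(x$relations)) {
    tab <- table(x$relations$schema)
    cat("  relations: ",
        paste0(names(tab), "=", as.integer(tab), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Number of relations in the graph
#'
#' @param graph A `med_kg`.
#' @return Integer count of stored triples (the cardinality of S).
#' @export
kg_size <- function(graph) {
  stopifnot(inherits(graph, "med_kg"))
  nrow(graph$relations)
}

#' Add entities to a knowledge graph
#'
#' @param graph A `med_kg`.
#' @param entities A data frame with columns `canonical_name` and `concept`;
#'   optional `entity_id` (defaults to [slugify()] of the name), `synonyms`
#'   (list column of character vectors; the canonical name is always
#'   included) and `description`.
#' @return The updated `med_kg`.
#' @export
#' @examples
#' kg <- kg_add_entities(kg_new(), tibble::tibble(
#'   canonical_name = c("lung", "inflammation"),
#'   concept = c("BODILY_PART", "SYMPTOM")
#' ))
kg_add_entities <- function(graph, entities) {
  stopifnot(inherits(graph, "med_kg"))
  ent <- as_tibble(entities)
  if (!all(c("canonical_name", "concept") %in% names(ent))) {
    kgc_abort("entities need canonical_name and concept columns",
              "kgchains_format_error")
  }
  if (any(!nzchar(ent$canonical_name))) {
    kgc_abort("canonical_name must be non-empty", "kgchains_format_error")
  }
  bad <- setdiff(unique(ent$concept), concept_classes())
  if (length(bad)) {
    kgc_abort(paste0("unknown concept class(es): ", paste(bad, collapse = ", ")),
              "kgchains_type_error")
  }
  if (!"entity_id" %in% names(ent)) ent$entity_id <- slugify(ent$canonical_name)
  if (!"description" %in% names(ent)) ent$description <- ""
  if (!"synonyms" %in% names(ent)) ent$synonyms <- vector("list", nrow(ent))
  ent$synonyms <- purrr::map2(ent$synonyms, ent$canonical_name,
                              function(s, cn) sort(unique(c(cn, s))))
  ent <- ent[, names(empty_entities())]
  out <- bind_rows(graph$entities, ent)
  if (anyDuplicated(out$entity_id)) {
    kgc_abort("duplicate entity_id within graph", "kgchains_schema_error")
  }
  graph$entities <- out
  graph
}

kg_check_endpoints <- function(graph, rel) {
  missing_ids <- setdiff(unique(c(rel$subject, rel$object)),
                         graph$entities$entity_id)
  if (length(missing_ids)) {
    kgc_abort(paste0("unknown endpoint entity: ",
                     paste(missing_ids, collapse = ", ")),
              "kgchains_schema_error")
  }
  concept_of <- setNames(graph$entities$concept, graph$entities$entity_id)
  sch <- relation_schemas()
  dom <- setNames(sch$domain, sch$schema)
  ran <- setNames(sch$range, sch$schema)
  bad_schema <- setdiff(unique(rel$schema), sch$schema)
  if (length(bad_schema)) {
    kgc_abort(paste0("unknown relation schema: ",
                     paste(bad_schema, collapse = ", ")),
              "kgchains_schema_error")
  }
  bad <- concept_of[rel$subject] != dom[rel$schema] |
    concept_of[rel$object] != ran[rel$schema]
  if (any(bad)) {
    i <- which(bad)[1L]
    kgc_abort(
      paste0("domain/range violation for ", rel$schema[i], "(",
             rel$subject[i], " [", concept_of[[rel$subject[i]]], "] -> ",
             rel$object[i], " [", concept_of[[rel$object[i]]], "]); schema ",
             "requires ", dom[[rel$schema[i]]], " -> ", ran[[rel$schema[i]]]),
      "kgchains_type_error")
  }
  invisible(TRUE)
}

normalize_provenance <- function(p) {
  if (is.null(p) || (is.data.frame(p) && nrow(p) == 0L)) {
    return(empty_provenance())
  }
  d <- as.character(p[["document_id"]])
  s <- as.integer(p[["sentence_index"]])
  if (length(d) > 1L) {
    o <- order(d, s, method = "radix")
    d <- d[o]
    s <- s[o]
    keep <- !duplicated(paste(d, s, sep = "\r"))
    d <- d[keep]
    s <- s[keep]
  }
  tibble::new_tibble(list(document_id = d, sentence_index = s),
                     nrow = length(d))
}

#' Add relations to a knowledge graph
#'
#' Relations are validated against the schema table: the subject's concept
#' class must equal the schema's domain and the object's its range.
#' Re-adding an existing (schema, subject, object) triple merges provenance
#' and keeps the maximum confidence, because the same fact is legitimately
#' harvested from many sentences.
#'
#' @param graph A `med_kg` whose entities include all endpoints.
#' @param relations A data frame with columns `schema`, `subject`, `object`;
#'   optional `confidence` (default 1) and `provenance` (list column of data
#'   frames with `document_id`, `sentence_index`).
#' @return The updated `med_kg`; each triple is present exactly once.
#' @export
kg_add_relations <- function(graph, relations) {
  stopifnot(inherits(graph, "med_kg"))
  rel <- as_tibble(relations)
  if (nrow(rel) == 0L) return(graph)
  if (!all(c("schema", "subject", "object") %in% names(rel))) {
    kgc_abort("relations need schema, subject, object columns",
              "kgchains_format_error")
  }
  if (!"confidence" %in% names(rel)) rel$confidence <- 1
  if (any(rel$confidence < 0 | rel$confidence > 1)) {
    kgc_abort("confidence must lie in [0, 1]", "kgchains_format_error")
  }
  if (!"provenance" %in% names(rel)) {
    rel$provenance <- vector("list", nrow(rel))
  }
  rel$provenance <- purrr::map(rel$provenance, normalize_provenance)
  kg_check_endpoints(graph, rel)
  rel <- rel[, names(empty_relations())]
  all_rel <- bind_rows(graph$relations, rel)
  key <- paste(all_rel$schema, all_rel$subject, all_rel$object, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    merged <- all_rel[dup, ] %>%
      group_by(.data$schema, .data$subject, .data$object) %>%
      summarise(
        confidence = max(.data$confidence),
        provenance = list(normalize_provenance(bind_rows(.data$provenance))),
        .groups = "drop"
      )
    all_rel <- bind_rows(all_rel[!dup, ], merged)
  }
  graph$relations <- arrange(all_rel, .data$schema, .data$subject,
                             .data$object)
  graph
}

#' @rdname kg_add_relations
#' @param schema,subject,object Scalars describing a single relation.
#' @param confidence Confidence in `[0, 1]` (default 1).
#' @param provenance Optional data frame of supporting sentences
#'   (`document_id`, `sentence_index`).
#' @export
#' @examples
#' kg <- kg_demo_graph()
#' kg_size(kg)
kg_add_relation <- function(graph, schema, subject, object,
                            confidence = 1, provenance = NULL) {
  kg_add_relations(graph, tibble(
    schema = schema, subject = subject, object = object,
    confidence = confidence, provenance = list(provenance)
  ))
}

#' Typed neighbors of an entity
#'
#' Forward traversal returns objects of matching relations whose subject is
#' the entity; inverse traversal returns subjects whose object is the entity
#' (e.g. retrieving the symptoms located in a given bodily part traverses
#' LOCATED_IN inversely).
#'
#' @param graph A `med_kg`.
#' @param entity_id Entity identifier present in the graph.
#' @param schema One of the names in [relation_schemas()].
#' @param direction `"forward"` or `"inverse"`.
#' @return Sorted character vector of neighbor entity ids (no duplicates).
#' @export
#' @examples
#' kg_neighbors(kg_demo_graph(), "lung", "LOCATED_IN", "inverse")
kg_neighbors <- function(graph, entity_id, schema,
                         direction = c("forward", "inverse")) {
  stopifnot(inherits(graph, "med_kg"))
  direction <- match.arg(direction)
  schema_row(schema)
  if (!entity_id %in% graph$entities$entity_id) {
    kgc_abort(paste0("entity not in graph: ", entity_id),
              "kgchains_schema_error")
  }
  rel <- graph$relations[graph$relations$schema == schema, ]
  out <- if (direction == "forward") {
    rel$object[rel$subject == entity_id]
  } else {
    rel$subject[rel$object == entity_id]
  }
  sort(unique(out))
}

#' The worked-example toy graph
#'
#' A six-entity graph encoding the classic junction motif: inflammation is
#' located in lung, skin and mouth, but only lung inflammation causes
#' pneumonia, which corresponds to one treatment.  Used throughout the
#' documentation and tests.
#'
#' @return A `med_kg`.
#' @export
kg_demo_graph <- function() {
  kg_new() %>%
    kg_add_entities(tibble(
      canonical_name = c("lung", "skin", "mouth", "inflammation",
                         "pneumonia", "treatment x"),
      concept = c("BODILY_PART", "BODILY_PART", "BODILY_PART",
                  "SYMPTOM", "DISEASE", "TREATMENT")
    )) %>%
    kg_add_relations(tibble(
      schema = c("LOCATED_IN", "LOCATED_IN", "LOCATED_IN",
                 "CAUSE", "CORRESPONDED_TO"),
      subject = c("inflammation", "inflammation", "inflammation",
                  "inflammation", "pneumonia"),
      object = c("lung", "skin", "mouth", "pneumonia", "treatment_x")
    ))
}
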