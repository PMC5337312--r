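#' Base IRI used for RDF export
#'
#' The project uses a single fixed namespace so that entity and predicate
#' IRIs are deterministic across runs.
#'
#' @return A string.
#' @export
kg_base_iri <- function() "http://kgchains.example.org/kg/"

RDF_TYPE_IRI <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

pred_iri <- function(schema) {
  paste0(kg_base_iri(), "relation/", tolower(schema))
}

class_iri <- function(concept) {
  paste0(kg_base_iri(), "class/", tolower(concept))
}

entity_iri <- function(entity_id) {
  paste0(kg_base_iri(), "entity/", entity_id)
}

#' Export a knowledge graph as RDF N-Triples
#'
#' Writes one triple per relation plus one `rdf:type` triple per entity, in
#' deterministic lexicographic order, UTF-8, one triple per line.  Entity
#' IRIs are built from the stable entity-id slugs, so the same graph always
#' serializes to the same bytes.
#'
#' @param graph A `med_kg`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".nt")
#' kg_export_ntriples(kg_demo_graph(), f)
#' readLines(f)[1:3]
kg_export_ntriples <- function(graph, path) {
  stopifnot(inherits(graph, "med_kg"))
  type_lines <- if (nrow(graph$entities)) {
    sprintf("<%s> <%s> <%s> .",
            entity_iri(graph$entities$entity_id),
            RDF_TYPE_IRI,
            class_iri(graph$entities$concept))
  } else character()
  rel_lines <- if (nrow(graph$relations)) {
    sprintf("<%s> <%s> <%s> .",
            entity_iri(graph$relations$subject),
            pred_iri(graph$relations$schema),
            entity_iri(graph$relations$object))
  } else character()
  lines <- sort(c(type_lines, rel_lines), method = "radix")
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) {
                    kgc_abort(paste0("cannot open for writing: ", path),
                              "kgchains_io_error")
                  })
  on.exit(close(con))
  if (length(lines)) {
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

parse_nt_line <- function(line) {
  m <- regmatches(line,
                  regexec("^<([^>]*)>\\s+<([^>]*)>\\s+<([^>]*)>\\s+\\.\\s*$",
                          line))[[1]]
  if (length(m) != 4L) {
    kgc_abort(paste0("malformed N-Triples line: ", line),
              "kgchains_format_error")
  }
  m[2:4]
}

iri_tail <- function(iri, prefix) {
  ifelse(startsWith(iri, prefix), substring(iri, nchar(prefix) + 1L), NA)
}

#' Import a knowledge graph from RDF N-Triples
#'
#' Reads a file written by [kg_export_ntriples()] (or any N-Triples file
#' using the same namespace) and reconstructs an isomorphic graph: entity
#' ids from the IRI slugs, concept classes from the `rdf:type` triples, and
#' one relation per relation triple.
#'
#' @param path Input file path.
#' @return A `med_kg`.
#' @export
kg_import_ntriples <- function(path) {
  if (!file.exists(path)) {
    kgc_abort(paste0("no such file: ", path), "kgchains_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  g <- kg_new()
  if (!length(lines)) return(g)
  parts <- t(vapply(lines, parse_nt_line, character(3), USE.NAMES = FALSE))
  triples <- tibble(s = parts[, 1], p = parts[, 2], o = parts[, 3])
  is_type <- triples$p == RDF_TYPE_IRI
  ent <- triples[is_type, ]
  cls_map <- setNames(concept_classes(), tolower(concept_classes()))
  ids <- iri_tail(ent$s, paste0(kg_base_iri(), "entity/"))
  cls <- cls_map[iri_tail(ent$o, paste0(kg_base_iri(), "class/"))]
  if (anyNA(ids) || anyNA(cls)) {
    kgc_abort("type triple outside the kgchains namespace",
              "kgchains_format_error")
  }
  g <- kg_add_entities(g, tibble(entity_id = ids, canonical_name = ids,
                                 concept = unname(cls)))
  rel <- triples[!is_type, ]
  if (nrow(rel)) {
    sch_map <- setNames(relation_schemas()$schema,
                        tolower(relation_schemas()$schema))
    schema <- sch_map[iri_tail(rel$p, paste0(kg_base_iri(), "relation/"))]
    subj <- iri_tail(rel$s, paste0(kg_base_iri(), "entity/"))
    obj <- iri_tail(rel$o, paste0(kg_base_iri(), "entity/"))
    if (anyNA(schema) || anyNA(subj) || anyNA(obj)) {
      kgc_abort("relation triple outside the kgchains namespace",
                "kgchains_format_error")
    }
    g <- kg_add_relations(g, tibble(schema = unname(schema),
                                    subject = subj, object = obj))
  }
  g
}
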