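step_entry_class <- function(schema, traversal) {
  s <- schema_row(schema)
  if (traversal == "forward") s$domain else s$range
}

step_exit_class <- function(schema, traversal) {
  s <- schema_row(schema)
  if (traversal == "forward") s$range else s$domain
}

#' Build and validate a schema path
#'
#' A schema path is the typed route an inference chain follows: an ordered
#' list of (relation schema, traversal direction) pairs whose concept
#' classes chain correctly — each step's entry class must equal the
#' previous step's exit class.
#'
#' @param schema Character vector of schema names.
#' @param traversal Character vector (`"forward"`/`"inverse"`), recycled.
#' @return A tibble with columns `schema`, `traversal` (class
#'   `kgc_schema_path`).
#' @export
#' @examples
#' # bodily part => symptoms => diseases => treatments
#' schema_path(c("LOCATED_IN", "CAUSE", "CORRESPONDED_TO"),
#'             c("inverse", "forward", "forward"))
schema_path <- function(schema, traversal) {
  sp <- tibble(schema = schema,
               traversal = rep(traversal, length.out = length(schema)))
  if (nrow(sp) < 1L) {
    kgc_abort("schema path needs at least one step", "kgchains_schema_error")
  }
  if (!all(sp$traversal %in% c("forward", "inverse"))) {
    kgc_abort("traversal must be forward or inverse",
              "kgchains_schema_error")
  }
  for (i in seq_len(nrow(sp))) {
    schema_row(sp$schema[i])
    if (i > 1L) {
      prev_exit <- step_exit_class(sp$schema[i - 1L], sp$traversal[i - 1L])
      entry <- step_entry_class(sp$schema[i], sp$traversal[i])
      if (prev_exit != entry) {
        kgc_abort(paste0("schema path broken at step ", i, ": ", prev_exit,
                         " does not match ", entry),
                  "kgchains_schema_error")
      }
    }
  }
  class(sp) <- c("kgc_schema_path", class(sp))
  sp
}

#' The canonical bodily-part-to-treatment schema path
#'
#' @param n_relations Chain length in relations: 2 (bodily part, symptom,
#'   disease) or 3 (adding the treatment step, the default evaluation unit).
#' @return A `kgc_schema_path`.
#' @export
default_schema_path <- function(n_relations = 3L) {
  if (!n_relations %in% 2:3) {
    kgc_abort("default path supports 2 or 3 relations",
              "kgchains_config_error")
  }
  schema_path(
    c("LOCATED_IN", "CAUSE", "CORRESPONDED_TO")[seq_len(n_relations)],
    c("inverse", "forward", "forward")[seq_len(n_relations)]
  )
}

empty_chains <- function() {
  tibble(chain_id = integer(), entity_path = list(), steps = list(),
         label = character())
}

relation_lookup <- function(graph) {
  rel <- graph$relations
  setNames(rel$provenance,
           paste(rel$schema, rel$subject, rel$object, sep = "\r"))
}

#' Enumerate inference chains by typed graph traversal
#'
#' Forward chaining: all simple paths (no repeated entity) from `start`
#' that follow the schema path, found by depth-first traversal with
#' neighbors visited in lexicographic entity-id order, so the result order
#' is deterministic across runs.  Each step records the underlying relation
#' (subject/object as stored) together with its traversal direction and
#' provenance.
#'
#' @param graph A `med_kg`.
#' @param start Entity id whose concept class equals the schema path's
#'   entry class.
#' @param path A `kgc_schema_path` (see [schema_path()]).
#' @param max_chains Result cap; enumeration stops there and the result
#'   carries attribute `truncated = TRUE` (junction fan-out is
#'   combinatorial).
#' @return A chains tibble: `chain_id`, `entity_path` (list of id vectors),
#'   `steps` (list of tibbles with `schema`, `traversal`, `subject`,
#'   `object`, `provenance`), `label` (`"unlabeled"`).
#' @export
#' @examples
#' enumerate_chains(kg_demo_graph(), "lung", default_schema_path(2))
enumerate_chains <- function(graph, start, path, max_chains = 10000L) {
  stopifnot(inherits(graph, "med_kg"))
  if (!inherits(path, "kgc_schema_path")) {
    path <- schema_path(path$schema, path$traversal)
  }
  if (!start %in% graph$entities$entity_id) {
    kgc_abort(paste0("entity not in graph: ", start),
              "kgchains_schema_error")
  }
  start_cls <- graph$entities$concept[graph$entities$entity_id == start]
  entry <- step_entry_class(path$schema[1L], path$traversal[1L])
  if (start_cls != entry) {
    kgc_abort(paste0("start entity class ", start_cls,
                     " does not match schema path entry class ", entry),
              "kgchains_schema_error")
  }
  acc <- new.env(parent = emptyenv())
  acc$paths <- list()
  acc$truncated <- FALSE
  n_steps <- nrow(path)
  walk <- function(ep) {
    if (acc$truncated) return(invisible())
    depth <- length(ep)
    if (depth == n_steps + 1L) {
      if (length(acc$paths) >= max_chains) {
        acc$truncated <- TRUE
        return(invisible())
      }
      acc$paths[[length(acc$paths) + 1L]] <- ep
      return(invisible())
    }
    nxt <- kg_neighbors(graph, ep[depth], path$schema[depth],
                        path$traversal[depth])
    for (v in nxt) {
      if (v %in% ep) next  # simple paths only
      walk(c(ep, v))
    }
  }
  walk(start)
  chains_from_paths(graph, acc$paths, path, truncated = acc$truncated)
}

chains_from_paths <- function(graph, entity_paths, path,
                              truncated = FALSE) {
  if (!length(entity_paths)) {
    out <- empty_chains()
    attr(out, "truncated") <- truncated
    return(out)
  }
  prov <- relation_lookup(graph)
  steps_of <- function(ep) {
    tibble(
      schema = path$schema,
      traversal = path$traversal,
      subject = ifelse(path$traversal == "forward",
                       ep[-length(ep)], ep[-1L]),
      object = ifelse(path$traversal == "forward", ep[-1L],
                      ep[-length(ep)])
    ) %>%
      mutate(provenance = unname(
        prov[paste(.data$schema, .data$subject, .data$object, sep = "\r")]))
  }
  out <- tibble(
    chain_id = seq_along(entity_paths),
    entity_path = entity_paths,
    steps = purrr::map(entity_paths, steps_of),
    label = "unlabeled"
  )
  attr(out, "truncated") <- truncated
  out
}

reverse_schema_path <- function(path) {
  schema_path(rev(path$schema),
              rev(ifelse(path$traversal == "forward", "inverse", "forward")))
}

#' Backward chaining from a goal entity
#'
#' Equivalent to enumerating chains over the reversed schema path starting
#' at the goal, with each resulting chain re-reversed, so the set of
#' backward chains is exactly the set of reversed forward chains.
#'
#' @param graph A `med_kg`.
#' @param goal Entity id whose concept class equals the schema path's exit
#'   class.
#' @inheritParams enumerate_chains
#' @return A chains tibble whose `entity_path`s run goal-first.
#' @export
backward_chains <- function(graph, goal, path, max_chains = 10000L) {
  if (!inherits(path, "kgc_schema_path")) {
    path <- schema_path(path$schema, path$traversal)
  }
  rev_path <- reverse_schema_path(path)
  out <- enumerate_chains(graph, goal, rev_path, max_chains = max_chains)
  out$entity_path <- purrr::map(out$entity_path, rev)
  out$steps <- purrr::map(out$steps, function(st) {
    st[rev(seq_len(nrow(st))), ] %>%
      mutate(schema = path$schema, traversal = path$traversal)
  })
  out
}

#' Fan-out of a junction entity
#'
#' The number of chain continuations through an entity along one schema and
#' traversal direction; a fan-out above 1 marks an n-to-1 / 1-to-n junction
#' whose chains are ambiguous and require pruning.
#'
#' @inheritParams kg_neighbors
#' @param traversal `"forward"` or `"inverse"`.
#' @return Integer fan-out (equals the number of typed neighbors).
#' @export
#' @examples
#' junction_fanout(kg_demo_graph(), "inflammation", "LOCATED_IN", "forward")
junction_fanout <- function(graph, entity_id, schema,
                            traversal = c("forward", "inverse")) {
  traversal <- match.arg(traversal)
  length(kg_neighbors(graph, entity_id, schema, traversal))
}

chain_to_list <- function(entity_path, steps, label) {
  list(
    entity_path = as.list(entity_path),
    steps = unname(purrr::pmap(
      steps,
      function(schema, traversal, subject, object, provenance) {
        list(relation = list(schema = schema, subject = subject,
                             object = object),
             traversal = traversal,
             provenance = if (is.null(provenance) || nrow(provenance) == 0L)
               list()
             else unname(purrr::map2(
               provenance$document_id, provenance$sentence_index,
               function(d, s) list(document_id = d, sentence_index = s))))
      })),
    label = label
  )
}

#' Write / read chains as JSON Lines
#'
#' One chain per line:
#' `{"entity_path": [...], "steps": [{"relation": ..., "traversal": ...,
#' "provenance": [...]}], "label": ...}`.
#'
#' @param chains A chains tibble.
#' @param path File path.
#' @return `write_chains()` returns `path` invisibly; `read_chains()` a
#'   chains tibble.
#' @export
write_chains <- function(chains, path) {
  lines <- purrr::pmap_chr(
    chains %>% select("entity_path", "steps", "label"),
    function(entity_path, steps, label) {
      jsonlite::toJSON(chain_to_list(entity_path, steps, label),
                       auto_unbox = TRUE, digits = NA)
    })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_chains
#' @export
read_chains <- function(path) {
  if (!file.exists(path)) {
    kgc_abort(paste0("no such file: ", path), "kgchains_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_chains())
  # base lapply so the abort class survives (purrr would re-wrap it)
  parsed <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l, simplifyVector = FALSE),
             error = function(e) {
               kgc_abort(paste0("malformed chain JSONL line: ",
                                conditionMessage(e)),
                        "kgchains_format_error")
             })
  })
  tibble(
    chain_id = seq_along(parsed),
    entity_path = purrr::map(parsed,
                             ~ as.character(unlist(.x$entity_path))),
    steps = purrr::map(parsed, function(ch) {
      tibble(
        schema = purrr::map_chr(ch$steps, ~ .x$relation$schema),
        traversal = purrr::map_chr(ch$steps, "traversal"),
        subject = purrr::map_chr(ch$steps, ~ .x$relation$subject),
        object = purrr::map_chr(ch$steps, ~ .x$relation$object),
        provenance = purrr::map(ch$steps, function(st) {
          if (!length(st$provenance)) return(empty_provenance())
          tibble(
            document_id = purrr::map_chr(st$provenance, "document_id"),
            sentence_index = purrr::map_int(
              st$provenance, ~ as.integer(.x$sentence_index)))
        })
      )
    }),
    label = purrr::map_chr(parsed, "label")
  )
}
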