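# Independent reference implementations used as oracles by the property
# tests.  They are deliberately written with different algorithms and data
# structures than the package code they check.

# --- breadth-first search over an undirected token tree ------------------

# edges: tibble/data.frame with `head`, `dep` (0-based); returns the token
# path from a to b inclusive, via plain BFS with predecessor tracking.
bfs_tree_path <- function(heads, deps, n_tok, a, b) {
  adj <- vector("list", n_tok)
  for (i in seq_along(heads)) {
    h <- heads[i] + 1L
    d <- deps[i] + 1L
    adj[[h]] <- c(adj[[h]], d)
    adj[[d]] <- c(adj[[d]], h)
  }
  prev <- rep(NA_integer_, n_tok)
  seen <- rep(FALSE, n_tok)
  queue <- a + 1L
  seen[a + 1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    if (v == b + 1L) break
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  path <- b + 1L
  while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
  path - 1L
}

# --- random labelled trees ----------------------------------------------

# a uniform-ish random tree on n nodes: each node beyond the first attaches
# to a uniformly chosen earlier node, under a random relabelling.
random_tree_edges <- function(n) {
  stopifnot(n >= 2L)
  lab <- sample.int(n) - 1L
  parent_pos <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
  tibble::tibble(head = lab[parent_pos], dep = lab[2:n], label = "dep")
}

# --- single-sentence corpus builder -------------------------------------

# builds a one-document, one-sentence med_corpus from a token vector and an
# edge table (defaults to the head-final chain parse).
one_sentence_corpus <- function(tokens, edges = NULL, doc = "d1") {
  n <- length(tokens)
  if (is.null(edges)) edges <- kgchains::chain_parse(n)
  kgchains::med_corpus(
    documents = tibble::tibble(document_id = doc, n_sentences = 1L),
    tokens = tibble::tibble(document_id = doc, sentence_index = 0L,
                            token_index = seq_len(n) - 1L,
                            surface = tokens, pos = "XX"),
    dep_edges = tibble::tibble(document_id = doc, sentence_index = 0L,
                               head = edges$head, dep = edges$dep,
                               label = "dep"),
    entity_mentions = tibble::tibble(document_id = character(),
                                     sentence_index = integer(),
                                     entity_id = character(),
                                     start = integer(), end = integer())
  )
}

# --- brute-force typed path enumeration ---------------------------------

# all simple entity paths from `start` following the schema path, found by
# exhaustive recursion over the raw relations table (no kg_neighbors).
brute_force_paths <- function(graph, start, path) {
  rel <- graph$relations
  n_steps <- nrow(path)
  out <- list()
  recur <- function(ep) {
    depth <- length(ep)
    if (depth == n_steps + 1L) {
      out[[length(out) + 1L]] <<- ep
      return(invisible())
    }
    sch <- path$schema[depth]
    if (path$traversal[depth] == "forward") {
      nxt <- rel$object[rel$schema == sch & rel$subject == ep[depth]]
    } else {
      nxt <- rel$subject[rel$schema == sch & rel$object == ep[depth]]
    }
    for (v in sort(unique(nxt))) {
      if (!v %in% ep) recur(c(ep, v))
    }
  }
  recur(start)
  out
}

# a random well-typed med_kg over the three study schemas.
random_typed_graph <- function(n_entities = 20L, n_relations = 30L) {
  cls <- sample(c("BODILY_PART", "SYMPTOM", "DISEASE", "TREATMENT"),
                n_entities, replace = TRUE)
  # guarantee every class appears at least once
  cls[1:4] <- c("BODILY_PART", "SYMPTOM", "DISEASE", "TREATMENT")
  ids <- sprintf("e%02d", seq_len(n_entities))
  g <- kgchains::kg_add_entities(
    kgchains::kg_new(),
    tibble::tibble(entity_id = ids, canonical_name = ids, concept = cls))
  sch <- kgchains::relation_schemas()
  rows <- purrr::map(seq_len(n_relations), function(i) {
    r <- sch[sample.int(3L, 1L), ]
    subj <- sample(ids[cls == r$domain], 1L)
    obj <- sample(ids[cls == r$range], 1L)
    tibble::tibble(schema = r$schema, subject = subj, object = obj)
  })
  kgchains::kg_add_relations(g, dplyr::distinct(dplyr::bind_rows(rows)))
}

# --- brute-force weighted consistency optimum ---------------------------

# exhaustive subset search for the maximum-weight feasible candidate set
# under dedup + optional per-schema functional constraints.
brute_force_consistency_weight <- function(candidates, constraints = list()) {
  cand <- as.data.frame(candidates)
  n <- nrow(cand)
  stopifnot(n <= 20L)
  fun <- constraints$functional
  if (is.null(fun)) fun <- character()
  feasible <- function(idx) {
    sub <- cand[idx, , drop = FALSE]
    triple <- paste(sub$schema, sub$subject, sub$object)
    if (anyDuplicated(triple)) return(FALSE)
    for (sch in names(fun)) {
      s2 <- sub[sub$schema == sch, , drop = FALSE]
      if (identical(unname(fun[sch]), "at_most_one_object")) {
        if (anyDuplicated(s2$subject)) return(FALSE)
      } else if (identical(unname(fun[sch]), "at_most_one_subject")) {
        if (anyDuplicated(s2$object)) return(FALSE)
      }
    }
    TRUE
  }
  best <- 0
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (!length(idx)) next
    if (feasible(idx)) best <- max(best, sum(cand$confidence[idx]))
  }
  best
}

# --- misc ----------------------------------------------------------------

# a tiny generator config that keeps unit tests fast; passes audit.
small_generator_config <- function(..., seed = 1L) {
  kgchains::generator_config(
    n_bodily_parts = 4L, n_symptoms = 22L, n_diseases = 4L,
    n_treatments = 22L, n_meaningful_chains = 12L,
    n_meaningless_chains = 12L, seed = seed, ...)
}

# enough labeled chains for the penalized classifiers to fit a
# non-degenerate model; noise-free by default.
medium_generator_config <- function(..., seed = 1L) {
  kgchains::generator_config(
    n_bodily_parts = 4L, n_symptoms = 78L, n_diseases = 4L,
    n_treatments = 78L, n_meaningful_chains = 40L,
    n_meaningless_chains = 40L, p_signal = 1, p_noise = 0,
    seed = seed, ...)
}

provenance_of <- function(doc, sent) {
  tibble::tibble(document_id = doc, sentence_index = as.integer(sent))
}
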