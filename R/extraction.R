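as_concept_map <- function(x) {
  if (inherits(x, "med_kg")) {
    return(x$entities %>% select("entity_id", "concept"))
  }
  x <- as_tibble(x)
  if (all(c("entity_id", "concept") %in% names(x))) {
    return(x %>% distinct(.data$entity_id, .data$concept))
  }
  kgc_abort("need a med_kg or a tibble with entity_id and concept columns",
            "kgchains_format_error")
}

# Parent-pointer path between two tokens of one sentence's dependency tree.
path_in_tree <- function(heads, deps, n_tok, a, b) {
  parent <- rep(NA_integer_, n_tok)
  parent[deps + 1L] <- heads
  climb <- function(v) {
    out <- integer(0)
    steps <- 0L
    while (!is.na(v)) {
      out <- c(out, v)
      v <- parent[v + 1L]
      steps <- steps + 1L
      if (steps > n_tok) {
        kgc_abort("dependency parse is cyclic or disconnected",
                  "kgchains_parse_error")
      }
    }
    out
  }
  pa <- climb(a)
  pb <- climb(b)
  hit <- match(pa, pb)
  i <- which(!is.na(hit))[1L]
  if (is.na(i)) {
    kgc_abort("dependency parse is disconnected", "kgchains_parse_error")
  }
  j <- hit[i]
  c(pa[seq_len(i)], if (j > 1L) rev(pb[seq_len(j - 1L)]))
}

sent_key <- function(d, s) paste(d, s, sep = "\r")

# One row per (sentence, domain mention, range mention) pair for a schema,
# with the lifted shortest-dependency-path signature.
gather_occurrences <- function(corpus, schema, concepts) {
  stopifnot(inherits(corpus, "med_corpus"))
  row <- schema_row(schema)
  cmap <- as_concept_map(concepts)
  men <- corpus$entity_mentions %>%
    left_join(cmap, by = "entity_id")
  dom <- men %>% filter(.data$concept == row$domain)
  ran <- men %>% filter(.data$concept == row$range)
  pairs <- inner_join(
    dom %>% select("document_id", "sentence_index",
                   subject = "entity_id", s_start = "start", s_end = "end"),
    ran %>% select("document_id", "sentence_index",
                   object = "entity_id", o_start = "start", o_end = "end"),
    by = c("document_id", "sentence_index"),
    relationship = "many-to-many"
  ) %>%
    filter(.data$s_start != .data$o_start)
  if (nrow(pairs) == 0L) {
    return(tibble(schema = character(), signature = character(),
                  subject = character(), object = character(),
                  document_id = character(), sentence_index = integer()))
  }
  keys <- sent_key(pairs$document_id, pairs$sentence_index)
  tok_split <- split(corpus$tokens,
                     sent_key(corpus$tokens$document_id,
                              corpus$tokens$sentence_index))
  edge_split <- split(corpus$dep_edges,
                      sent_key(corpus$dep_edges$document_id,
                               corpus$dep_edges$sentence_index))
  sigs <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    k <- keys[i]
    tok <- tok_split[[k]]
    tok <- tok[order(tok$token_index), ]
    ed <- edge_split[[k]]
    n_tok <- nrow(tok)
    head_a <- pairs$s_end[i] - 1L
    head_b <- pairs$o_end[i] - 1L
    path <- path_in_tree(if (is.null(ed)) integer() else ed$head,
                         if (is.null(ed)) integer() else ed$dep,
                         n_tok, head_a, head_b)
    words <- tok$surface[path + 1L]
    words[1L] <- "<DOMAIN>"
    words[length(words)] <- "<RANGE>"
    sigs[i] <- paste(words, collapse = " ")
  }
  tibble(schema = schema, signature = sigs,
         subject = pairs$subject, object = pairs$object,
         document_id = pairs$document_id,
         sentence_index = pairs$sentence_index) %>%
    arrange(.data$signature, .data$subject, .data$object,
            .data$document_id, .data$sentence_index)
}

#' Mine lifted dependency-path patterns for a relation schema
#'
#' Every sentence containing a (domain-typed, range-typed) mention pair
#' contributes one pattern occurrence: the token surfaces along the shortest
#' dependency path between the two mention heads, with the entity positions
#' replaced by `<DOMAIN>` and `<RANGE>` placeholders.  Occurrences are
#' grouped by signature.
#'
#' @param corpus A `med_corpus` with entity mentions.
#' @param schema A relation schema name.
#' @param concepts A `med_kg` or a tibble mapping `entity_id` to `concept`.
#' @return A tibble with columns `schema`, `signature`, `support` (number of
#'   occurrences), `pair_count` (distinct entity pairs) and `occurrences`
#'   (nested tibble of subject, object, document_id, sentence_index).
#' @export
gather_patterns <- function(corpus, schema, concepts) {
  occ <- gather_occurrences(corpus, schema, concepts)
  occ %>%
    tidyr::nest(occurrences = c("subject", "object", "document_id",
                                "sentence_index")) %>%
    mutate(
      support = purrr::map_int(.data$occurrences, nrow),
      pair_count = purrr::map_int(
        .data$occurrences,
        ~ nrow(distinct(.x, .data$subject, .data$object)))
    ) %>%
    select("schema", "signature", "support", "pair_count", "occurrences") %>%
    arrange(.data$schema, .data$signature)
}

#' Score patterns against a seed-fact set
#'
#' A pattern's confidence is the fraction of its distinct entity pairs that
#' are seed facts: `seed_hits / pair_count` (0 when the pattern matched no
#' pair).  Seed co-occurrence is the only supervision the bootstrapping
#' loop uses.
#'
#' @param patterns Output of [gather_patterns()].
#' @param seeds Tibble with columns `schema`, `subject`, `object`.
#' @return `patterns` with `seed_hits` and `confidence` columns added.
#' @export
score_patterns <- function(patterns, seeds) {
  seeds <- as_tibble(seeds) %>%
    distinct(.data$schema, .data$subject, .data$object)
  patterns %>%
    mutate(
      seed_hits = purrr::map2_int(
        .data$occurrences, .data$schema,
        function(occ, sch) {
          pr <- distinct(occ, .data$subject, .data$object)
          nrow(semi_join(pr %>% mutate(schema = sch), seeds,
                         by = c("schema", "subject", "object")))
        }),
      confidence = if_else(.data$pair_count > 0L,
                           .data$seed_hits / .data$pair_count, 0)
    )
}

#' Bootstrapped fact harvesting
#'
#' Iterative pattern-based harvesting: patterns are scored against the
#' current seed set, patterns at or above the confidence threshold are
#' accepted, every entity pair matched by an accepted pattern is emitted as
#' a fact candidate, and newly harvested facts are promoted to seeds for
#' the next iteration.  Stops early when an iteration yields no new facts.
#'
#' @param corpus A `med_corpus` with entity mentions.
#' @param schema Relation schema name.
#' @param seeds Seed facts tibble (`schema`, `subject`, `object`); must be
#'   non-empty for this schema.
#' @param concepts A `med_kg` or `entity_id`/`concept` tibble.
#' @param confidence_threshold Acceptance threshold in `(0, 1]`.
#' @param max_iterations Maximum number of bootstrap iterations.
#' @return A tibble of fact candidates: `schema`, `subject`, `object`,
#'   `confidence` (best accepted pattern confidence), `iteration` (1-based
#'   iteration of first emission) and `provenance` (list of supporting
#'   sentences).
#' @export
harvest <- function(corpus, schema, seeds, concepts,
                    confidence_threshold = 0.5, max_iterations = 3L) {
  if (confidence_threshold <= 0 || confidence_threshold > 1) {
    kgc_abort("confidence_threshold must lie in (0, 1]",
              "kgchains_config_error")
  }
  if (max_iterations < 1L) {
    kgc_abort("max_iterations must be >= 1", "kgchains_config_error")
  }
  seeds <- as_tibble(seeds) %>%
    filter(.data$schema == !!schema) %>%
    distinct(.data$schema, .data$subject, .data$object)
  if (nrow(seeds) == 0L) {
    kgc_abort("empty seed set for schema", "kgchains_config_error")
  }
  occ <- gather_occurrences(corpus, schema, concepts)
  pair_by_sig <- occ %>% distinct(.data$signature, .data$subject,
                                  .data$object)
  pc <- pair_by_sig %>% dplyr::count(.data$signature, name = "pair_count")
  facts <- tibble(schema = character(), subject = character(),
                  object = character(), confidence = double(),
                  iteration = integer())
  current_seeds <- seeds
  for (it in seq_len(max_iterations)) {
    hits <- pair_by_sig %>%
      semi_join(current_seeds, by = c("subject", "object")) %>%
      dplyr::count(.data$signature, name = "seed_hits")
    conf <- pc %>%
      left_join(hits, by = "signature") %>%
      mutate(seed_hits = dplyr::coalesce(.data$seed_hits, 0L),
             confidence = .data$seed_hits / .data$pair_count)
    accepted <- conf %>% filter(.data$confidence >= confidence_threshold)
    if (nrow(accepted) == 0L) break
    emitted <- pair_by_sig %>%
      semi_join(accepted, by = "signature") %>%
      left_join(accepted %>% select("signature", "confidence"),
                by = "signature") %>%
      group_by(.data$subject, .data$object) %>%
      summarise(confidence = max(.data$confidence), .groups = "drop") %>%
      mutate(schema = !!schema, iteration = it)
    new_facts <- anti_join(emitted, facts, by = c("subject", "object"))
    if (nrow(new_facts) == 0L) break
    facts <- bind_rows(facts, new_facts %>%
                         select("schema", "subject", "object",
                                "confidence", "iteration"))
    current_seeds <- bind_rows(
      current_seeds,
      new_facts %>% select("schema", "subject", "object")) %>%
      distinct()
  }
  prov <- occ %>%
    distinct(.data$subject, .data$object, .data$document_id,
             .data$sentence_index) %>%
    tidyr::nest(provenance = c("document_id", "sentence_index"))
  facts %>%
    left_join(prov, by = c("subject", "object")) %>%
    mutate(provenance = purrr::map(.data$provenance, normalize_provenance)) %>%
    arrange(.data$iteration, .data$subject, .data$object)
}

#' Consistency filtering of fact candidates
#'
#' Treats each candidate as a soft clause weighted by its confidence and
#' applies hard constraints: at most one candidate per (schema, subject,
#' object) triple (dedup), plus optional per-schema functional constraints.
#' The weighted constraint problem is solved greedily, scanning candidates
#' in descending weight (ties broken lexicographically) and keeping each
#' candidate that violates no constraint — optimal whenever the constraints
#' are per-key, as dedup and functionality are.
#'
#' @param candidates Tibble with columns `schema`, `subject`, `object`,
#'   `confidence`.
#' @param constraints Optional list; `constraints$functional` is a named
#'   character vector mapping schema names to `"at_most_one_object"` or
#'   `"at_most_one_subject"`.
#' @return The retained subset of `candidates`.
#' @export
consistency_filter <- function(candidates, constraints = list()) {
  cand <- as_tibble(candidates)
  if (nrow(cand) == 0L) return(cand)
  fun <- constraints$functional %||% character()
  ordered <- cand %>%
    arrange(dplyr::desc(.data$confidence), .data$schema, .data$subject,
            .data$object)
  keep <- logical(nrow(ordered))
  seen_triple <- character()
  seen_subj <- character()
  seen_obj <- character()
  for (i in seq_len(nrow(ordered))) {
    sch <- ordered$schema[i]
    triple <- paste(sch, ordered$subject[i], ordered$object[i], sep = "\r")
    if (triple %in% seen_triple) next
    mode <- fun[sch]
    if (!is.na(mode) && length(mode)) {
      if (identical(unname(mode), "at_most_one_object")) {
        skey <- paste(sch, ordered$subject[i], sep = "\r")
        if (skey %in% seen_subj) next
        seen_subj <- c(seen_subj, skey)
      } else if (identical(unname(mode), "at_most_one_subject")) {
        okey <- paste(sch, ordered$object[i], sep = "\r")
        if (okey %in% seen_obj) next
        seen_obj <- c(seen_obj, okey)
      }
    }
    seen_triple <- c(seen_triple, triple)
    keep[i] <- TRUE
  }
  ordered[keep, ]
}

#' Random sample of candidates for manual verification
#'
#' Uniform sample without replacement, reproducible under the given seed.
#' Mirrors the practice of spot-checking a fixed number of harvested facts
#' per relation by hand.
#'
#' @param candidates Tibble of fact candidates.
#' @param k Sample size.
#' @param seed Integer RNG seed.
#' @return A tibble of `k` sampled rows (all rows, with a warning, when
#'   `k` exceeds the number of candidates).
#' @export
sample_for_verification <- function(candidates, k, seed) {
  cand <- as_tibble(candidates)
  if (k > nrow(cand)) {
    warn(paste0("requested ", k, " facts but only ", nrow(cand),
                " candidates; returning all"))
    return(cand)
  }
  idx <- withr::with_seed(seed, sample.int(nrow(cand), k))
  cand[idx, ]
}

#' Apply manual fact overrides to a candidate set
#'
#' A lightweight expert-feedback channel: a TSV (or tibble) of `add` /
#' `remove` directives is applied after harvesting and filtering.  `remove`
#' drops the matching (schema, subject, object) triple; `add` appends the
#' triple (confidence defaults to 1, iteration 0, empty provenance) unless
#' it is already present.  Removals are applied before additions, so an
#' override file can replace a triple's confidence by removing and
#' re-adding it.
#'
#' @param facts A facts tibble (`schema`, `subject`, `object`,
#'   `confidence`, `iteration`, `provenance`).
#' @param overrides A tibble with columns `action` (`"add"`/`"remove"`),
#'   `schema`, `subject`, `object` and optional `confidence`, or the path
#'   of a TSV with columns `action`, `relation`, `subject_id`, `object_id`
#'   (optional `confidence`).
#' @return The adjusted facts tibble.
#' @export
apply_fact_overrides <- function(facts, overrides) {
  if (is.character(overrides) && length(overrides) == 1L) {
    if (!file.exists(overrides)) {
      kgc_abort(paste0("no such file: ", overrides), "kgchains_io_error")
    }
    ov <- readr::read_tsv(overrides,
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    need <- c("action", "relation", "subject_id", "object_id")
    if (!all(need %in% names(ov))) {
      kgc_abort(paste0("override TSV needs columns: ",
                       paste(need, collapse = ", ")),
                "kgchains_format_error")
    }
    ov <- ov %>%
      rename(schema = "relation", subject = "subject_id",
             object = "object_id")
    if ("confidence" %in% names(ov)) {
      ov$confidence <- as.numeric(ov$confidence)
    }
    overrides <- ov
  }
  ov <- as_tibble(overrides)
  if (!all(c("action", "schema", "subject", "object") %in% names(ov))) {
    kgc_abort("overrides need action, schema, subject, object columns",
              "kgchains_format_error")
  }
  if (!all(ov$action %in% c("add", "remove"))) {
    kgc_abort("override action must be add or remove",
              "kgchains_format_error")
  }
  if (!"confidence" %in% names(ov)) ov$confidence <- NA_real_
  out <- as_tibble(facts)
  rem <- ov %>% filter(.data$action == "remove")
  if (nrow(rem)) {
    out <- anti_join(out, rem, by = c("schema", "subject", "object"))
  }
  add <- ov %>%
    filter(.data$action == "add") %>%
    mutate(confidence = dplyr::coalesce(.data$confidence, 1)) %>%
    anti_join(out, by = c("schema", "subject", "object"))
  if (nrow(add)) {
    out <- bind_rows(out, tibble(
      schema = add$schema, subject = add$subject, object = add$object,
      confidence = add$confidence, iteration = 0L,
      provenance = rep(list(empty_provenance()), nrow(add))
    ))
  }
  out %>% arrange(.data$schema, .data$subject, .data$object)
}

#' Read / write harvested facts as TSV
#'
#' Columns: `relation`, `subject_id`, `object_id`, `confidence`,
#' `iteration`, `provenance` (semicolon-separated `doc:sent` pairs).
#'
#' @param facts Harvest output tibble.
#' @param path File path.
#' @return `write_facts()` returns `path` invisibly; `read_facts()` the
#'   facts tibble.
#' @export
write_facts <- function(facts, path) {
  f <- as_tibble(facts) %>%
    mutate(provenance_str = purrr::map_chr(
      .data$provenance,
      function(p) {
        if (is.null(p) || nrow(p) == 0L) return("")
        paste(paste0(p$document_id, ":", p$sentence_index),
              collapse = ";")
      })) %>%
    select(relation = "schema", subject_id = "subject",
           object_id = "object", "confidence", "iteration",
           provenance = "provenance_str")
  readr::write_tsv(f, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_facts
#' @export
read_facts <- function(path) {
  if (!file.exists(path)) {
    kgc_abort(paste0("no such file: ", path), "kgchains_io_error")
  }
  f <- readr::read_tsv(path, col_types = readr::cols(
    relation = "c", subject_id = "c", object_id = "c",
    confidence = "d", iteration = "i", provenance = "c"), progress = FALSE)
  f %>%
    mutate(provenance = purrr::map(.data$provenance, function(p) {
      if (is.na(p) || !nzchar(p)) return(empty_provenance())
      parts <- strsplit(strsplit(p, ";", fixed = TRUE)[[1]], ":",
                        fixed = TRUE)
      tibble(document_id = purrr::map_chr(parts, 1),
             sentence_index = as.integer(purrr::map_chr(parts, 2)))
    })) %>%
    select(schema = "relation", subject = "subject_id",
           object = "object_id", "confidence", "iteration", "provenance")
}
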