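#' Configuration for the synthetic study-set generator
#'
#' The generator emulates the study conditions of the pruning evaluation: a
#' ground-truth graph over bodily parts, symptoms, diseases and treatments
#' with n-to-1 / 1-to-n junctions; one relation-bearing supporting sentence
#' per ground-truth relation, flanked by filler sentences; and a balanced
#' labeled study set of 3-relation inference chains (default 100 meaningful
#' + 100 meaningless) whose surrounding context carries a co-mention signal
#' at controllable probabilities.  For each relation of a labeled chain,
#' the flanking context co-mentions a chain entity that is *not* part of
#' the relation itself — the chain's disease for the LOCATED_IN step, and
#' the chain's bodily part for the CAUSE and CORRESPONDED_TO steps — with
#' probability `p_signal` when the chain is meaningful and `p_noise` (a
#' spurious co-mention) when it is meaningless.  Because diseases and
#' bodily parts are shared pools, these co-mention terms recur across
#' chains, which is what lets a bag-of-words classifier generalize from
#' training chains to held-out ones.
#'
#' @param n_bodily_parts,n_symptoms,n_diseases,n_treatments Pool sizes of
#'   synthetic entities (the fixed worked-example subgraph — lung, skin,
#'   mouth, inflammation, pneumonia, treatment-x — is added on top).
#'   Diseases and bodily parts are shared pools (several symptoms cause
#'   the same disease, an n-to-1 junction; several symptoms are located in
#'   the same part), so their terms recur across labeled chains; symptoms
#'   and treatments are per-chain.  The small default pools keep enough
#'   labeled chains behind every shared term for a term-level classifier
#'   to estimate its weight from the training folds.
#' @param fanout_located_in Bodily parts per symptom (>= 2 when meaningless
#'   chains are requested); creates the 1-to-n LOCATED_IN junctions.
#' @param templates_per_schema Number of sentence templates per relation
#'   schema in the synthetic grammar.
#' @param p_signal,p_noise Context co-mention probabilities
#'   (`0 <= p_noise <= p_signal <= 1`); the defaults 0.95/0.05 define the
#'   study-set regime used in the package's evaluation.
#' @param n_meaningful_chains,n_meaningless_chains Labeled chain counts
#'   (defaults 100/100).
#' @param context_pad_sentences Filler sentences on each side of every
#'   supporting sentence; must be at least the context range N the pruning
#'   classifier will use.
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @return A list of class `kgc_generator_config`.
#' @export
generator_config <- function(n_bodily_parts = 6L, n_symptoms = 198L,
                             n_diseases = 6L, n_treatments = 198L,
                             fanout_located_in = 3L,
                             templates_per_schema = 3L,
                             p_signal = 0.95, p_noise = 0.05,
                             n_meaningful_chains = 100L,
                             n_meaningless_chains = 100L,
                             context_pad_sentences = 3L, seed = 1L) {
  cfg <- list(
    n_bodily_parts = as.integer(n_bodily_parts),
    n_symptoms = as.integer(n_symptoms),
    n_diseases = as.integer(n_diseases),
    n_treatments = as.integer(n_treatments),
    fanout_located_in = as.integer(fanout_located_in),
    templates_per_schema = as.integer(templates_per_schema),
    p_signal = as.numeric(p_signal), p_noise = as.numeric(p_noise),
    n_meaningful_chains = as.integer(n_meaningful_chains),
    n_meaningless_chains = as.integer(n_meaningless_chains),
    context_pad_sentences = as.integer(context_pad_sentences),
    seed = as.integer(seed)
  )
  if (cfg$p_noise < 0 || cfg$p_signal > 1 || cfg$p_noise > cfg$p_signal) {
    kgc_abort("need 0 <= p_noise <= p_signal <= 1",
              "kgchains_config_error")
  }
  if (cfg$fanout_located_in < 1L || cfg$templates_per_schema < 1L) {
    kgc_abort("invalid generator sizes", "kgchains_config_error")
  }
  if (cfg$context_pad_sentences < 1L) {
    kgc_abort(paste0("context_pad_sentences must be >= 1 (each supporting ",
                     "sentence needs flanking room for its context ",
                     "co-mention)"),
              "kgchains_config_error")
  }
  if (cfg$n_meaningless_chains > 0L && cfg$fanout_located_in < 2L) {
    kgc_abort("meaningless chains require LOCATED_IN fan-out >= 2",
              "kgchains_config_error")
  }
  n_dedicated <- max(0L, cfg$n_meaningful_chains - 1L) +
    max(0L, cfg$n_meaningless_chains - 1L)
  if (cfg$n_symptoms < n_dedicated || cfg$n_treatments < n_dedicated) {
    kgc_abort("n_symptoms and n_treatments must cover the requested chains",
              "kgchains_config_error")
  }
  if (cfg$n_bodily_parts < cfg$fanout_located_in) {
    kgc_abort("too few bodily parts for the requested fan-out",
              "kgchains_config_error")
  }
  if (cfg$n_diseases < 1L) {
    kgc_abort("need at least one disease", "kgchains_config_error")
  }
  structure(cfg, class = "kgc_generator_config")
}

nonsense_words <- function(n, n_syllables, forbidden = character()) {
  if (n == 0L) return(character())
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(cons, vow, paste0))
  draw <- function(m) {
    mat <- matrix(sample(syll, m * n_syllables, replace = TRUE),
                  nrow = m)
    apply(mat, 1L, paste0, collapse = "")
  }
  words <- character(0)
  while (length(words) < n) {
    cand <- setdiff(unique(draw(2L * (n - length(words)) + 4L)), forbidden)
    words <- unique(c(words, cand))
  }
  words[seq_len(n)]
}

schema_cues <- function(templates_per_schema) {
  base <- list(
    LOCATED_IN = list(c("located", "in"), c("found", "in"),
                      c("arises", "in")),
    CAUSE = list("causes", "induces", "provokes"),
    CORRESPONDED_TO = list(c("treated", "by"), c("managed", "with"),
                           c("responds", "to"))
  )
  lapply(setNames(names(base), names(base)), function(sch) {
    cues <- base[[sch]]
    k <- templates_per_schema
    if (k <= length(cues)) return(cues[seq_len(k)])
    extra <- lapply((length(cues) + 1L):k,
                    function(i) paste0("cue", tolower(sch), i))
    c(cues, extra)
  })
}

demo_entities <- function() {
  tibble(
    canonical_name = c("lung", "skin", "mouth", "inflammation",
                       "pneumonia", "treatment-x"),
    concept = c("BODILY_PART", "BODILY_PART", "BODILY_PART", "SYMPTOM",
                "DISEASE", "TREATMENT")
  )
}

#' Generate a synthetic study bundle
#'
#' Produces a mutually consistent glossary, ground-truth knowledge graph,
#' dependency-parsed corpus, seed-fact set and labeled chain study set (see
#' [generator_config()] for the knobs).  Every ground-truth relation has
#' at least one supporting sentence built from a head-final template
#' grammar; the worked-example subgraph (inflammation located in lung, skin
#' and mouth; only lung inflammation causes pneumonia) is always embedded
#' and contributes one meaningful and one meaningless chain, each with its
#' own supporting segment for the relations the two chains share.  The bundle is
#' byte-identical across runs with the same seed.
#'
#' @param config A [generator_config()].
#' @return A list of class `kg_bundle` with elements `config`, `graph`,
#'   `glossary`, `corpus`, `seeds`, `chains`.
#' @export
generate_bundle <- function(config = generator_config()) {
  stopifnot(inherits(config, "kgc_generator_config"))
  withr::with_seed(config$seed, generate_bundle_impl(config))
}

generate_bundle_impl <- function(cfg) {
  cues <- schema_cues(cfg$templates_per_schema)
  cue_words <- unique(unlist(cues))

  parts <- nonsense_words(cfg$n_bodily_parts, 3L, forbidden = cue_words)
  stems <- nonsense_words(cfg$n_symptoms + cfg$n_diseases +
                            cfg$n_treatments, 3L,
                          forbidden = c(cue_words, parts))
  symptoms <- paste0(stems[seq_len(cfg$n_symptoms)], "algia")
  diseases <- paste0(stems[cfg$n_symptoms + seq_len(cfg$n_diseases)],
                     "osis")
  treatments <- paste0(
    stems[cfg$n_symptoms + cfg$n_diseases + seq_len(cfg$n_treatments)],
    "inib")
  filler_vocab <- nonsense_words(50L, 2L, forbidden = cue_words)

  entities <- bind_rows(
    demo_entities(),
    tibble(canonical_name = parts, concept = "BODILY_PART"),
    tibble(canonical_name = symptoms, concept = "SYMPTOM"),
    tibble(canonical_name = diseases, concept = "DISEASE"),
    tibble(canonical_name = treatments, concept = "TREATMENT")
  ) %>%
    mutate(entity_id = slugify(.data$canonical_name))
  surface_of <- setNames(entities$canonical_name, entities$entity_id)

  all_parts <- c("lung", "skin", "mouth", parts)
  disease_pool <- sample(c("pneumonia", diseases))

  # one family per labeled chain; the demo family carries one chain of
  # each label and shares its CAUSE/CORRESPONDED_TO relations between them
  has_demo <- cfg$n_meaningful_chains >= 1L && cfg$n_meaningless_chains >= 1L
  n_ded_m <- cfg$n_meaningful_chains - as.integer(has_demo)
  n_ded_ml <- cfg$n_meaningless_chains - as.integer(has_demo)
  n_ded <- n_ded_m + n_ded_ml
  ded <- tibble(
    family = seq_len(n_ded),
    symptom = symptoms[seq_len(n_ded)],
    disease = disease_pool[(seq_len(n_ded) - 1L) %% length(disease_pool) +
                             1L],
    treatment = treatments[seq_len(n_ded)],
    sites = purrr::map(seq_len(n_ded),
                       ~ sample(all_parts, cfg$fanout_located_in)),
    label = rep(c("meaningful", "meaningless"), c(n_ded_m, n_ded_ml))
  )
  fam <- bind_rows(
    if (has_demo) tibble(
      family = 0L, symptom = "inflammation", disease = "pneumonia",
      treatment = "treatment-x", sites = list(c("lung", "skin", "mouth")),
      label = "both"),
    ded
  ) %>%
    mutate(
      document_id = sprintf("doc_%04d", row_number()),
      symptom = slugify(.data$symptom),
      disease = slugify(.data$disease),
      treatment = slugify(.data$treatment),
      sites = purrr::map(.data$sites, slugify)
    )

  # segments: one per ground-truth relation, in fixed order per family
  pad <- cfg$context_pad_sentences
  seg_len <- 2L * pad + 1L
  segments <- fam %>%
    mutate(seg = purrr::pmap(
      list(.data$symptom, .data$disease, .data$treatment, .data$sites,
           .data$label),
      function(s, d, t, sites, label) {
        # a LOCATED_IN context co-mentions the chain's disease at p_signal
        # only when the edge is the true site of a meaningful chain
        loc <- tibble(
          schema = "LOCATED_IN", subject = s, object = sites,
          ctx = purrr::map(seq_along(sites), function(i) {
            p <- if (i == 1L && label %in% c("meaningful", "both"))
              "p_signal" else "p_noise"
            setNames(p, d)
          })
        )
        # CAUSE / CORRESPONDED_TO contexts co-mention the chain's bodily
        # part; the demo family carries one supporting segment per labeled
        # chain so each chain has its own context
        tail_segs <- if (label == "both") {
          tibble(
            schema = rep(c("CAUSE", "CORRESPONDED_TO"), each = 2L),
            subject = rep(c(s, d), each = 2L),
            object = rep(c(d, t), each = 2L),
            ctx = rep(list(setNames("p_signal", sites[1L]),
                           setNames("p_noise", sites[2L])), 2L)
          )
        } else {
          chain_site <- if (label == "meaningless") sites[2L] else sites[1L]
          p <- if (label == "meaningful") "p_signal" else "p_noise"
          tibble(schema = c("CAUSE", "CORRESPONDED_TO"),
                 subject = c(s, d), object = c(d, t),
                 ctx = list(setNames(p, chain_site),
                            setNames(p, chain_site)))
        }
        bind_rows(loc, tail_segs)
      })) %>%
    select("family", "document_id", "label", "seg") %>%
    tidyr::unnest("seg") %>%
    group_by(.data$document_id) %>%
    mutate(seg_idx = row_number()) %>%
    ungroup() %>%
    mutate(
      support_sent = (.data$seg_idx - 1L) * seg_len + pad,
      template = purrr::map_int(
        .data$schema,
        ~ sample.int(cfg$templates_per_schema, 1L))
    )

  # support sentences
  support <- segments %>%
    mutate(tokens = purrr::pmap(
      list(.data$schema, .data$subject, .data$object, .data$template),
      function(sch, s, o, k) {
        c(surface_of[[s]], cues[[sch]][[k]], surface_of[[o]])
      }))

  # filler sentences, then plant context co-mentions into them
  fillers <- segments %>%
    select("document_id", "support_sent") %>%
    tidyr::crossing(offset = c(-seq_len(pad), seq_len(pad))) %>%
    mutate(sentence_index = .data$support_sent + .data$offset) %>%
    select("document_id", "sentence_index") %>%
    arrange(.data$document_id, .data$sentence_index)
  n_fill <- nrow(fillers)
  fill_mat <- matrix(sample(filler_vocab, 4L * n_fill, replace = TRUE),
                     nrow = n_fill)
  fillers$tokens <- lapply(seq_len(n_fill), function(i) fill_mat[i, ])

  plants <- segments %>%
    select("document_id", "support_sent", "ctx") %>%
    mutate(ctx = purrr::map(.data$ctx, ~ tibble(entity = names(.x),
                                                prob = unname(.x)))) %>%
    tidyr::unnest("ctx") %>%
    mutate(
      p = if_else(.data$prob == "p_signal", cfg$p_signal, cfg$p_noise),
      planted = stats::runif(n()) < .data$p,
      pos = sample.int(5L, n(), replace = TRUE) - 1L
    ) %>%
    group_by(.data$document_id, .data$support_sent) %>%
    # one flank sentence per co-mention, so insertions never collide
    mutate(offset = sample(c(-seq_len(pad), seq_len(pad)), n())) %>%
    ungroup() %>%
    filter(.data$planted) %>%
    mutate(sentence_index = .data$support_sent + .data$offset)

  if (nrow(plants)) {
    key <- paste(fillers$document_id, fillers$sentence_index, sep = "\r")
    pkey <- paste(plants$document_id, plants$sentence_index, sep = "\r")
    idx <- match(pkey, key)
    for (i in seq_len(nrow(plants))) {
      tok <- fillers$tokens[[idx[i]]]
      fillers$tokens[[idx[i]]] <- append(tok, surface_of[[plants$entity[i]]],
                                         after = plants$pos[i])
    }
  }

  # assemble corpus tables
  support_tok <- support %>%
    select("document_id", sentence_index = "support_sent", "tokens")
  all_sent <- bind_rows(
    support_tok %>% mutate(kind = "support"),
    fillers %>% mutate(kind = "filler")
  ) %>%
    arrange(.data$document_id, .data$sentence_index)
  lens <- lengths(all_sent$tokens)
  tokens <- tibble(
    document_id = rep(all_sent$document_id, lens),
    sentence_index = rep(all_sent$sentence_index, lens),
    token_index = unlist(lapply(lens, seq_len)) - 1L,
    surface = unlist(all_sent$tokens),
    pos = NA_character_
  )
  ent_surfaces <- unname(surface_of)
  tokens$pos <- ifelse(tokens$surface %in% ent_surfaces, "NN",
                       ifelse(tokens$surface %in% cue_words, "VB", "XX"))
  dep_edges <- tibble(
    document_id = rep(all_sent$document_id, pmax(lens - 1L, 0L)),
    sentence_index = rep(all_sent$sentence_index, pmax(lens - 1L, 0L)),
    head = unlist(lapply(lens, function(n) if (n > 1L) 1:(n - 1L)
                         else integer())),
    dep = unlist(lapply(lens, function(n) if (n > 1L) 0:(n - 2L)
                        else integer())),
    label = "dep"
  )
  id_of_surface <- setNames(entities$entity_id, entities$canonical_name)
  mentions <- bind_rows(
    support %>%
      mutate(n_tok = lengths(.data$tokens)) %>%
      select("document_id", sentence_index = "support_sent", "subject",
             "object", "n_tok") %>%
      tidyr::pivot_longer(c("subject", "object"),
                          values_to = "entity_id") %>%
      mutate(start = if_else(.data$name == "subject", 0L,
                             .data$n_tok - 1L),
             end = .data$start + 1L) %>%
      select("document_id", "sentence_index", "entity_id", "start", "end"),
    if (nrow(plants)) plants %>%
      select("document_id", "sentence_index", entity_id = "entity",
             start = "pos") %>%
      mutate(end = .data$start + 1L)
  ) %>%
    arrange(.data$document_id, .data$sentence_index, .data$start)
  documents <- all_sent %>%
    dplyr::count(.data$document_id, name = "n_sentences") %>%
    arrange(.data$document_id)
  corpus <- med_corpus(documents, tokens, dep_edges, mentions)

  # ground-truth graph with provenance
  graph <- kg_new() %>%
    kg_add_entities(entities %>% select("entity_id", "canonical_name",
                                        "concept")) %>%
    kg_add_relations(segments %>%
                       mutate(provenance = purrr::map2(
                         .data$document_id, .data$support_sent,
                         function(d, s) tibble::new_tibble(
                           list(document_id = d,
                                sentence_index = as.integer(s)),
                           nrow = 1L))) %>%
                       select("schema", "subject", "object", "provenance"))

  glossary <- glossary_build(graph)

  # seed facts: spread evenly over the (schema, template) grid so every
  # pattern signature gets a comparable share of seed support
  seed_counts <- c(LOCATED_IN = 22L, CAUSE = 22L, CORRESPONDED_TO = 20L)
  seeds <- segments %>%
    group_by(.data$schema) %>%
    dplyr::group_modify(function(df, key) {
      n_target <- min(seed_counts[[key$schema]], nrow(df))
      shuffled <- df[sample.int(nrow(df)), ]
      interleaved <- shuffled %>%
        group_by(.data$template) %>%
        mutate(.rank = row_number()) %>%
        ungroup() %>%
        arrange(.data$.rank, .data$template)
      interleaved[seq_len(n_target), ]
    }) %>%
    ungroup() %>%
    select("schema", "subject", "object") %>%
    distinct() %>%
    arrange(.data$schema, .data$subject, .data$object)

  # labeled study chains
  chain_rows <- fam %>%
    mutate(chains = purrr::pmap(
      list(.data$symptom, .data$disease, .data$treatment, .data$sites,
           .data$label),
      function(s, d, t, sites, label) {
        if (label == "both") {
          tibble(path = list(c(sites[1L], s, d, t), c(sites[2L], s, d, t)),
                 label = c("meaningful", "meaningless"))
        } else {
          site <- if (label == "meaningless") sites[2L] else sites[1L]
          tibble(path = list(c(site, s, d, t)), label = label)
        }
      })) %>%
    select("chains") %>%
    tidyr::unnest("chains")
  chains <- chains_from_paths(graph, chain_rows$path,
                              default_schema_path(3L))
  chains$label <- chain_rows$label
  if (has_demo) {
    # the demo family's CAUSE / CORRESPONDED_TO relations are shared by
    # its two chains but each chain has its own supporting segment; point
    # each chain's provenance at its own segment
    demo_doc <- fam$document_id[fam$family == 0L]
    seg_sent <- function(seg) (seg - 1L) * seg_len + pad
    demo_segs <- list(c(1L, 4L, 6L), c(2L, 5L, 7L))
    for (ci in 1:2) {
      st <- chains$steps[[ci]]
      st$provenance <- purrr::map(demo_segs[[ci]], function(g) {
        tibble(document_id = demo_doc, sentence_index = seg_sent(g))
      })
      chains$steps[[ci]] <- st
    }
  }

  structure(
    list(config = cfg, graph = graph, glossary = glossary, corpus = corpus,
         seeds = seeds, chains = chains),
    class = "kg_bundle"
  )
}

#' @exportS3Method base::print
print.kg_bundle <- function(x, ...) {
  cat("<kg_bundle> seed ", x$config$seed, ": ",
      nrow(x$graph$entities), " entities, ", kg_size(x$graph),
      " relations, ", sum(x$corpus$documents$n_sentences), " sentences, ",
      nrow(x$chains), " labeled chains (",
      sum(x$chains$label == "meaningful"), " meaningful / ",
      sum(x$chains$label == "meaningless"), " meaningless)\n", sep = "")
  invisible(x)
}

bundle_context_hits <- function(bundle) {
  cfg <- bundle$config
  pad <- cfg$context_pad_sentences
  corpus <- bundle$corpus
  ctx_entities <- function(path) {
    list(path[3L], path[1L], path[1L])
  }
  lab_of <- bundle$chains$label
  tok_by_sent <- split(corpus$tokens$surface,
                       sent_key(corpus$tokens$document_id,
                                corpus$tokens$sentence_index))
  doc_len <- setNames(corpus$documents$n_sentences,
                      corpus$documents$document_id)
  surf <- setNames(bundle$graph$entities$canonical_name,
                   bundle$graph$entities$entity_id)
  rows <- purrr::map2(bundle$chains$steps, seq_len(nrow(bundle$chains)),
                      function(st, ci) {
    ctx <- ctx_entities(bundle$chains$entity_path[[ci]])
    purrr::map(seq_len(nrow(st)), function(i) {
      prov <- st$provenance[[i]]
      win <- unlist(purrr::map2(prov$document_id, prov$sentence_index,
                                function(d, s) {
        idx <- seq.int(max(0L, s - pad),
                       min(doc_len[[d]] - 1L, s + pad))
        unlist(tok_by_sent[sent_key(d, idx)], use.names = FALSE)
      }))
      tibble(chain_id = ci, step_idx = i, label = lab_of[ci],
             entity = ctx[[i]],
             present = surf[ctx[[i]]] %in% win)
    }) %>% bind_rows()
  })
  bind_rows(rows)
}

#' Audit a generated bundle against its invariants
#'
#' Verifies: exact labeled class counts; glossary coverage of every graph
#' entity; at least one LOCATED_IN junction with fan-out >= 3 (the
#' worked-example motif); every relation carries provenance; every labeled
#' chain is a valid typed path whose relations all exist in the graph; the
#' empirical context co-mention rates of the labeled chains lie within 3
#' binomial standard deviations of `p_signal` / `p_noise`.
#'
#' @param bundle A `kg_bundle`.
#' @return Invisibly, a tibble of audit measurements; aborts with an
#'   `kgchains_audit_error` naming the first violated invariant.
#' @export
audit_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "kg_bundle"))
  cfg <- bundle$config
  fail <- function(msg) kgc_abort(paste0("audit failure: ", msg),
                                  "kgchains_audit_error")
  n_m <- sum(bundle$chains$label == "meaningful")
  n_ml <- sum(bundle$chains$label == "meaningless")
  if (n_m != cfg$n_meaningful_chains || n_ml != cfg$n_meaningless_chains) {
    fail(paste0("class counts ", n_m, "/", n_ml, " differ from configured ",
                cfg$n_meaningful_chains, "/", cfg$n_meaningless_chains))
  }
  uncovered <- setdiff(bundle$graph$entities$entity_id,
                       bundle$glossary$entity_id)
  if (length(uncovered)) {
    fail(paste0("glossary does not cover entity ", uncovered[1]))
  }
  fanouts <- bundle$graph$relations %>%
    filter(.data$schema == "LOCATED_IN") %>%
    dplyr::count(.data$subject)
  if (cfg$fanout_located_in >= 3L && (nrow(fanouts) == 0L ||
                                      max(fanouts$n) < 3L)) {
    fail("no LOCATED_IN junction with fan-out >= 3")
  }
  no_prov <- purrr::map_lgl(bundle$graph$relations$provenance,
                            ~ nrow(.x) == 0L)
  if (any(no_prov)) fail("relation without provenance")
  rel_keys <- paste(bundle$graph$relations$schema,
                    bundle$graph$relations$subject,
                    bundle$graph$relations$object, sep = "\r")
  for (i in seq_len(nrow(bundle$chains))) {
    st <- bundle$chains$steps[[i]]
    ep <- bundle$chains$entity_path[[i]]
    if (anyDuplicated(ep)) fail(paste0("chain ", i, " repeats an entity"))
    if (!all(paste(st$schema, st$subject, st$object, sep = "\r") %in%
             rel_keys)) {
      fail(paste0("chain ", i, " uses a relation missing from the graph"))
    }
  }
  hits <- bundle_context_hits(bundle)
  rates <- hits %>%
    group_by(.data$label) %>%
    summarise(rate = mean(.data$present), n = n(), .groups = "drop") %>%
    mutate(expected = if_else(.data$label == "meaningful", cfg$p_signal,
                              cfg$p_noise),
           sigma = sqrt(.data$expected * (1 - .data$expected) / .data$n))
  bad <- abs(rates$rate - rates$expected) > 3 * rates$sigma + 1e-12
  if (any(bad)) {
    i <- which(bad)[1L]
    fail(sprintf("co-mention rate %.3f for %s chains outside 3 sigma of %.3f",
                 rates$rate[i], rates$label[i], rates$expected[i]))
  }
  invisible(rates)
}

#' Write a bundle's artifacts to a directory
#'
#' Emits the documented external formats: `glossary.tsv`, `corpus.json`,
#' `seeds.tsv`, `chains.jsonl` and `graph.nt`.
#'
#' @param bundle A `kg_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "kg_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_glossary(bundle$glossary, file.path(dir, "glossary.tsv"))
  save_corpus(bundle$corpus, file.path(dir, "corpus.json"))
  write_seed_facts(bundle$seeds, file.path(dir, "seeds.tsv"))
  write_chains(bundle$chains, file.path(dir, "chains.jsonl"))
  kg_export_ntriples(bundle$graph, file.path(dir, "graph.nt"))
  invisible(dir)
}
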