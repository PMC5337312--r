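#' Construct a corpus of dependency-parsed documents
#'
#' A corpus holds pre-tokenized, sentence-split, dependency-parsed text in
#' three flat tables.  Tokenization and parsing are the producer's job (the
#' synthetic generator or an external preprocessor); this keeps the pipeline
#' language-agnostic.  All indices are 0-based; mention spans are half-open
#' `[start, end)`.
#'
#' @param documents Tibble with columns `document_id`, `n_sentences`.
#' @param tokens Tibble with columns `document_id`, `sentence_index`,
#'   `token_index`, `surface`, `pos`.
#' @param dep_edges Tibble with columns `document_id`, `sentence_index`,
#'   `head`, `dep`, `label`; per sentence the edges must form a
#'   single-rooted tree over the token indices.
#' @param entity_mentions Tibble with columns `document_id`,
#'   `sentence_index`, `entity_id`, `start`, `end`; spans must be in bounds
#'   and non-overlapping within a sentence.
#' @return An object of class `med_corpus`.
#' @export
med_corpus <- function(documents, tokens, dep_edges, entity_mentions) {
  corp <- structure(
    list(
      documents = as_tibble(documents),
      tokens = as_tibble(tokens),
      dep_edges = as_tibble(dep_edges),
      entity_mentions = as_tibble(entity_mentions)
    ),
    class = "med_corpus"
  )
  validate_corpus(corp)
  corp
}

#' @exportS3Method base::print
print.med_corpus <- function(x, ...) {
  cat("<med_corpus> ", nrow(x$documents), " documents, ",
      sum(x$documents$n_sentences), " sentences, ",
      nrow(x$tokens), " tokens, ",
      nrow(x$entity_mentions), " entity mentions\n", sep = "")
  invisible(x)
}

empty_corpus <- function() {
  med_corpus(
    documents = tibble(document_id = character(), n_sentences = integer()),
    tokens = tibble(document_id = character(), sentence_index = integer(),
                    token_index = integer(), surface = character(),
                    pos = character()),
    dep_edges = tibble(document_id = character(), sentence_index = integer(),
                       head = integer(), dep = integer(), label = character()),
    entity_mentions = tibble(document_id = character(),
                             sentence_index = integer(),
                             entity_id = character(), start = integer(),
                             end = integer())
  )
}

corpus_fail <- function(msg, doc = NULL, sent = NULL) {
  where <- if (!is.null(doc)) {
    paste0(" [document ", doc,
           if (!is.null(sent)) paste0(", sentence ", sent), "]")
  } else ""
  kgc_abort(paste0(msg, where), "kgchains_format_error")
}

# Parent-pointer doubling over the whole corpus at once: after
# ceil(log2(max sentence length)) + 1 squarings every acyclic chain has hit
# the root (NA); surviving pointers mean a cycle.
check_dep_trees <- function(tokens, dep_edges) {
  if (nrow(tokens) == 0L) return(invisible(TRUE))
  key <- function(d, s, i) paste(d, s, i, sep = "\r")
  tok_key <- key(tokens$document_id, tokens$sentence_index,
                 tokens$token_index)
  n_tok <- tokens %>%
    dplyr::count(.data$document_id, .data$sentence_index, name = "n_tokens")
  n_edge <- dep_edges %>%
    dplyr::count(.data$document_id, .data$sentence_index, name = "n_edges")
  cmp <- left_join(n_tok, n_edge,
                   by = c("document_id", "sentence_index")) %>%
    mutate(n_edges = dplyr::coalesce(.data$n_edges, 0L))
  bad <- cmp$n_edges != cmp$n_tokens - 1L
  if (any(bad)) {
    i <- which(bad)[1L]
    corpus_fail("dep_edges must have exactly n_tokens - 1 edges (one root)",
                cmp$document_id[i], cmp$sentence_index[i])
  }
  dep_key <- key(dep_edges$document_id, dep_edges$sentence_index,
                 dep_edges$dep)
  head_key <- key(dep_edges$document_id, dep_edges$sentence_index,
                  dep_edges$head)
  if (anyDuplicated(dep_key)) {
    i <- which(duplicated(dep_key))[1L]
    corpus_fail("token has more than one head",
                dep_edges$document_id[i], dep_edges$sentence_index[i])
  }
  if (!all(dep_key %in% tok_key) || !all(head_key %in% tok_key)) {
    j <- which(!(dep_key %in% tok_key) | !(head_key %in% tok_key))[1L]
    corpus_fail("dep edge refers to a token index out of range",
                dep_edges$document_id[j], dep_edges$sentence_index[j])
  }
  parent <- match(head_key, tok_key)[match(tok_key, dep_key)]
  max_len <- max(n_tok$n_tokens)
  reach <- parent
  for (k in seq_len(ceiling(log2(max(2, max_len))) + 1L)) {
    reach <- reach[reach]  # square the pointer; NA (root reached) propagates
    if (all(is.na(reach))) break
  }
  if (!all(is.na(reach))) {
    i <- which(!is.na(reach))[1L]
    corpus_fail("cyclic dep_edges", tokens$document_id[i],
                tokens$sentence_index[i])
  }
  invisible(TRUE)
}

validate_corpus <- function(corp) {
  docs <- corp$documents
  if (anyDuplicated(docs$document_id)) {
    corpus_fail("duplicate document_id")
  }
  tok <- corp$tokens
  if (nrow(tok)) {
    unknown <- setdiff(unique(tok$document_id), docs$document_id)
    if (length(unknown)) corpus_fail("tokens for unknown document", unknown[1])
    by_sent <- tok %>%
      group_by(.data$document_id, .data$sentence_index) %>%
      summarise(ok = all(sort(.data$token_index) ==
                           seq_len(n()) - 1L), .groups = "drop")
    if (!all(by_sent$ok)) {
      i <- which(!by_sent$ok)[1L]
      corpus_fail("token indices must be contiguous from 0",
                  by_sent$document_id[i], by_sent$sentence_index[i])
    }
    by_doc <- tok %>%
      distinct(.data$document_id, .data$sentence_index) %>%
      group_by(.data$document_id) %>%
      summarise(n_sent = n(),
                ok = all(sort(.data$sentence_index) == seq_len(n()) - 1L),
                .groups = "drop")
    if (!all(by_doc$ok)) {
      corpus_fail("sentence indices must be contiguous from 0",
                  by_doc$document_id[which(!by_doc$ok)[1L]])
    }
    chk <- left_join(docs, by_doc, by = "document_id")
    bad <- !is.na(chk$n_sent) & chk$n_sent != chk$n_sentences
    if (any(bad)) {
      corpus_fail("documents$n_sentences disagrees with tokens",
                  chk$document_id[which(bad)[1L]])
    }
  }
  check_dep_trees(tok, corp$dep_edges)
  men <- corp$entity_mentions
  if (nrow(men)) {
    lens <- tok %>%
      dplyr::count(.data$document_id, .data$sentence_index,
                   name = "n_tokens")
    m <- left_join(men, lens, by = c("document_id", "sentence_index"))
    bad <- is.na(m$n_tokens) | m$start < 0L | m$end > m$n_tokens |
      m$start >= m$end
    if (any(bad)) {
      i <- which(bad)[1L]
      corpus_fail("entity mention span out of bounds",
                  men$document_id[i], men$sentence_index[i])
    }
    ov <- men %>%
      arrange(.data$document_id, .data$sentence_index, .data$start) %>%
      group_by(.data$document_id, .data$sentence_index) %>%
      mutate(overlaps = .data$start < dplyr::lag(.data$end,
                                                 default = -1L)) %>%
      ungroup()
    if (any(ov$overlaps)) {
      i <- which(ov$overlaps)[1L]
      corpus_fail("overlapping entity mentions",
                  ov$document_id[i], ov$sentence_index[i])
    }
  }
  invisible(corp)
}

#' Head-final chain dependency parse
#'
#' Convenience parse used by the synthetic grammar: token i depends on token
#' i + 1 and the last token is the root, so the shortest dependency path
#' between the first and last token traverses the whole sentence.
#'
#' @param n Number of tokens.
#' @return A tibble with columns `head`, `dep`, `label`.
#' @export
chain_parse <- function(n) {
  if (n < 1L) kgc_abort("sentence needs at least one token",
                        "kgchains_format_error")
  if (n == 1L) return(tibble(head = integer(), dep = integer(),
                             label = character()))
  tibble(head = 1:(n - 1L), dep = 0:(n - 2L), label = "dep")
}

#' Dictionary-based entity recognition
#'
#' Annotates every sentence with entity mentions by greedy longest-match
#' left-to-right dictionary matching over token n-grams.  At each position
#' the longest glossary match wins; equal-length candidates are broken by
#' the lexicographically smallest entity id.  Matching is case-insensitive.
#' Existing mentions are replaced.
#'
#' @param corpus A `med_corpus`.
#' @param glossary A glossary tibble (see [glossary_build()]).
#' @return The corpus with `entity_mentions` repopulated.
#' @export
recognize_entities <- function(corpus, glossary) {
  stopifnot(inherits(corpus, "med_corpus"))
  gl <- validate_glossary(glossary)
  if (nrow(gl) == 0L) {
    kgc_abort("glossary is empty", "kgchains_config_error")
  }
  gl <- gl %>%
    mutate(term = normalize_term(.data$term),
           term_len = stringr::str_count(.data$term, stringr::fixed(" ")) +
             1L) %>%
    arrange(.data$term, .data$entity_id) %>%
    distinct(.data$term, .keep_all = TRUE)
  tok <- corpus$tokens %>%
    arrange(.data$document_id, .data$sentence_index, .data$token_index) %>%
    mutate(norm = normalize_term(.data$surface))
  cands <- vector("list", length(unique(gl$term_len)))
  for (j in seq_along(sort(unique(gl$term_len)))) {
    l <- sort(unique(gl$term_len))[j]
    gram <- tok$norm
    if (l > 1L) {
      parts <- lapply(0:(l - 1L), function(k) {
        if (k == 0L) tok$norm else
          c(tok$norm[-seq_len(k)], rep(NA_character_, k))
      })
      same_sent <- rep(TRUE, nrow(tok))
      for (k in 1:(l - 1L)) {
        nxt_doc <- c(tok$document_id[-seq_len(k)], rep(NA, k))
        nxt_sent <- c(tok$sentence_index[-seq_len(k)], rep(NA, k))
        same_sent <- same_sent & !is.na(nxt_doc) &
          nxt_doc == tok$document_id & nxt_sent == tok$sentence_index
      }
      gram <- do.call(paste, parts)
      gram[!same_sent] <- NA_character_
    }
    hit <- match(gram, gl$term[gl$term_len == l])
    idx <- which(!is.na(hit))
    if (length(idx)) {
      sub <- gl[gl$term_len == l, ]
      cands[[j]] <- tibble(
        document_id = tok$document_id[idx],
        sentence_index = tok$sentence_index[idx],
        start = tok$token_index[idx],
        len = l,
        entity_id = sub$entity_id[hit[idx]]
      )
    }
  }
  cands <- bind_rows(cands)
  mentions <- if (nrow(cands) == 0L) {
    empty_corpus()$entity_mentions
  } else {
    cands %>%
      arrange(.data$document_id, .data$sentence_index, .data$start,
              dplyr::desc(.data$len), .data$entity_id) %>%
      group_by(.data$document_id, .data$sentence_index) %>%
      dplyr::group_modify(function(df, key) {
        cursor <- 0L
        keep <- logical(nrow(df))
        for (i in seq_len(nrow(df))) {
          if (df$start[i] >= cursor) {
            keep[i] <- TRUE
            cursor <- df$start[i] + df$len[i]
          }
        }
        df[keep, ]
      }) %>%
      ungroup() %>%
      mutate(end = .data$start + .data$len) %>%
      select("document_id", "sentence_index", "entity_id", "start", "end") %>%
      arrange(.data$document_id, .data$sentence_index, .data$start)
  }
  corpus$entity_mentions <- mentions
  validate_corpus(corpus)
  corpus
}

#' Shortest path in a sentence's dependency tree
#'
#' Returns the unique undirected shortest path between the head tokens of
#' two mention spans (in a tree the shortest path is unique).  The head of a
#' span is its last token.
#'
#' @param corpus A `med_corpus`.
#' @param document_id,sentence_index Sentence coordinates.
#' @param span_a,span_b Half-open integer spans `c(start, end)` of the two
#'   mentions.
#' @return Integer vector of 0-based token indices from `span_a`'s head to
#'   `span_b`'s head, endpoints included.
#' @export
shortest_dep_path <- function(corpus, document_id, sentence_index,
                              span_a, span_b) {
  stopifnot(inherits(corpus, "med_corpus"))
  edges <- corpus$dep_edges %>%
    filter(.data$document_id == !!document_id,
           .data$sentence_index == !!sentence_index)
  n_tok <- sum(corpus$tokens$document_id == document_id &
                 corpus$tokens$sentence_index == sentence_index)
  if (n_tok == 0L) {
    kgc_abort("no such sentence", "kgchains_format_error")
  }
  head_a <- span_a[2] - 1L
  head_b <- span_b[2] - 1L
  if (head_a < 0L || head_a >= n_tok || head_b < 0L || head_b >= n_tok) {
    kgc_abort("mention span outside sentence", "kgchains_format_error")
  }
  if (head_a == head_b) return(head_a)
  path_in_tree(edges$head, edges$dep, n_tok, head_a, head_b)
}

#' Save / load a corpus as JSON
#'
#' The on-disk format nests documents, sentences, tokens, dependency edges
#' and entity mentions; [load_corpus()] re-validates every structural
#' invariant and reports the offending document/sentence on failure.
#'
#' @param corpus A `med_corpus`.
#' @param path File path.
#' @return `save_corpus()` returns `path` invisibly; `load_corpus()` returns
#'   a `med_corpus`.
#' @export
save_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "med_corpus"))
  sent_key <- function(df) split(df, paste(df$document_id, df$sentence_index,
                                           sep = "\r"))
  toks <- sent_key(corpus$tokens)
  deps <- sent_key(corpus$dep_edges)
  mens <- sent_key(corpus$entity_mentions)
  docs <- lapply(seq_len(nrow(corpus$documents)), function(i) {
    did <- corpus$documents$document_id[i]
    nsent <- corpus$documents$n_sentences[i]
    sentences <- lapply(seq_len(nsent) - 1L, function(s) {
      k <- paste(did, s, sep = "\r")
      t <- toks[[k]]
      t <- t[order(t$token_index), ]
      d <- deps[[k]]
      m <- mens[[k]]
      list(
        tokens = unname(purrr::map2(t$surface, t$pos,
                                    function(a, b) list(surface = a, pos = b))),
        dep_edges = if (is.null(d) || nrow(d) == 0L) list() else
          unname(purrr::pmap(list(d$head, d$dep, d$label),
                             function(h, dp, l) list(h, dp, l))),
        entity_mentions = if (is.null(m) || nrow(m) == 0L) list() else
          unname(purrr::pmap(list(m$entity_id, m$start, m$end),
                             function(e, s1, e1) list(e, s1, e1)))
      )
    })
    list(document_id = did, sentences = sentences)
  })
  jsonlite::write_json(list(documents = docs), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_corpus
#' @export
load_corpus <- function(path) {
  if (!file.exists(path)) {
    kgc_abort(paste0("no such file: ", path), "kgchains_io_error")
  }
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    kgc_abort(paste0("malformed corpus JSON: ",
                                     conditionMessage(e)),
                              "kgchains_format_error")
                  })
  docs <- raw$documents
  documents <- tibble(
    document_id = purrr::map_chr(docs, "document_id"),
    n_sentences = purrr::map_int(docs, ~ length(.x$sentences))
  )
  per_doc <- purrr::map(docs, function(d) {
    sents <- d$sentences
    tok <- purrr::imap(sents, function(s, i) {
      tibble(
        document_id = d$document_id, sentence_index = i - 1L,
        token_index = seq_along(s$tokens) - 1L,
        surface = purrr::map_chr(s$tokens, "surface"),
        pos = purrr::map_chr(s$tokens, "pos")
      )
    })
    dep <- purrr::imap(sents, function(s, i) {
      if (!length(s$dep_edges)) return(NULL)
      tibble(
        document_id = d$document_id, sentence_index = i - 1L,
        head = purrr::map_int(s$dep_edges, ~ as.integer(.x[[1]])),
        dep = purrr::map_int(s$dep_edges, ~ as.integer(.x[[2]])),
        label = purrr::map_chr(s$dep_edges, ~ as.character(.x[[3]]))
      )
    })
    men <- purrr::imap(sents, function(s, i) {
      if (!length(s$entity_mentions)) return(NULL)
      tibble(
        document_id = d$document_id, sentence_index = i - 1L,
        entity_id = purrr::map_chr(s$entity_mentions,
                                   ~ as.character(.x[[1]])),
        start = purrr::map_int(s$entity_mentions, ~ as.integer(.x[[2]])),
        end = purrr::map_int(s$entity_mentions, ~ as.integer(.x[[3]]))
      )
    })
    list(tok = bind_rows(tok), dep = bind_rows(dep), men = bind_rows(men))
  })
  e <- empty_corpus()
  med_corpus(
    documents = documents,
    tokens = bind_rows(e$tokens, bind_rows(purrr::map(per_doc, "tok"))),
    dep_edges = bind_rows(e$dep_edges,
                          bind_rows(purrr::map(per_doc, "dep"))),
    entity_mentions = bind_rows(e$entity_mentions,
                                bind_rows(purrr::map(per_doc, "men")))
  )
}
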