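# builds a corpus of one-sentence documents, each "subj <cue words> obj"
# with a head-final chain parse and mentions on the first and last token.
support_corpus <- function(sentences) {
  rows <- purrr::imap(sentences, function(s, i) {
    doc <- sprintf("d%03d", i)
    toks <- c(s$subject, s$cues, s$object)
    n <- length(toks)
    list(
      documents = tibble::tibble(document_id = doc, n_sentences = 1L),
      tokens = tibble::tibble(document_id = doc, sentence_index = 0L,
                              token_index = seq_len(n) - 1L,
                              surface = toks, pos = "XX"),
      dep_edges = tibble::tibble(document_id = doc, sentence_index = 0L,
                                 head = 1:(n - 1L), dep = 0:(n - 2L),
                                 label = "dep"),
      mentions = tibble::tibble(
        document_id = doc, sentence_index = 0L,
        entity_id = c(s$subject, s$object),
        start = c(0L, n - 1L), end = c(1L, n))
    )
  })
  med_corpus(
    documents = dplyr::bind_rows(purrr::map(rows, "documents")),
    tokens = dplyr::bind_rows(purrr::map(rows, "tokens")),
    dep_edges = dplyr::bind_rows(purrr::map(rows, "dep_edges")),
    entity_mentions = dplyr::bind_rows(purrr::map(rows, "mentions")))
}

concepts_for <- function(symptoms = character(), parts = character(),
                         diseases = character(), treatments = character()) {
  tibble::tibble(
    entity_id = c(symptoms, parts, diseases, treatments),
    concept = rep(c("SYMPTOM", "BODILY_PART", "DISEASE", "TREATMENT"),
                  c(length(symptoms), length(parts), length(diseases),
                    length(treatments))))
}

sent <- function(subject, cues, object) {
  list(subject = subject, cues = cues, object = object)
}

test_that("the lifted signature replaces endpoints with placeholders", {
  corp <- support_corpus(list(sent("s1", c("located", "in"), "p1")))
  pat <- gather_patterns(corp, "LOCATED_IN", concepts_for("s1", "p1"))
  expect_identical(pat$signature, "<DOMAIN> located in <RANGE>")
  expect_identical(pat$support, 1L)
  expect_identical(pat$pair_count, 1L)
})

test_that("identical signatures aggregate into one pattern of support 2", {
  corp <- support_corpus(list(
    sent("s1", c("located", "in"), "p1"),
    sent("s2", c("located", "in"), "p2")))
  pat <- gather_patterns(corp, "LOCATED_IN",
                         concepts_for(c("s1", "s2"), c("p1", "p2")))
  expect_identical(nrow(pat), 1L)
  expect_identical(pat$support, 2L)
  expect_identical(pat$pair_count, 2L)
  expect_identical(nrow(pat$occurrences[[1]]), 2L)
})

test_that("support >= pair_count >= seed_hits always holds", {
  bundle <- generate_bundle(small_generator_config())
  for (sch in relation_schemas()$schema) {
    pat <- score_patterns(
      gather_patterns(bundle$corpus, sch, bundle$graph), bundle$seeds)
    expect_true(all(pat$support >= pat$pair_count))
    expect_true(all(pat$pair_count >= pat$seed_hits))
    expect_true(all(pat$confidence >= 0 & pat$confidence <= 1))
  }
})

test_that("the synthetic corpus yields one signature per template", {
  bundle <- generate_bundle(small_generator_config())
  for (sch in relation_schemas()$schema) {
    pat <- gather_patterns(bundle$corpus, sch, bundle$graph)
    expect_identical(nrow(pat),
                     bundle$config$templates_per_schema)
  }
})

test_that("pattern confidence is seed_hits / pair_count", {
  corp <- support_corpus(purrr::map(1:4, function(i) {
    sent(paste0("s", i), c("located", "in"), paste0("p", i))
  }))
  concepts <- concepts_for(paste0("s", 1:4), paste0("p", 1:4))
  pat <- gather_patterns(corp, "LOCATED_IN", concepts)
  all_seeds <- tibble::tibble(schema = "LOCATED_IN",
                              subject = paste0("s", 1:4),
                              object = paste0("p", 1:4))
  expect_identical(score_patterns(pat, all_seeds)$confidence, 1)
  expect_identical(
    score_patterns(pat, all_seeds[0, ])$confidence, 0)
  expect_identical(
    score_patterns(pat, all_seeds[1, ])$confidence, 0.25)
  expect_identical(score_patterns(pat, all_seeds[1, ])$seed_hits, 1L)
})

test_that("harvest at threshold 1 with full seed coverage recovers the truth", {
  bundle <- generate_bundle(small_generator_config())
  gt <- bundle$graph$relations %>% dplyr::filter(schema == "LOCATED_IN")
  seeds <- gt %>% dplyr::select(schema, subject, object)
  facts <- harvest(bundle$corpus, "LOCATED_IN", seeds, bundle$graph,
                   confidence_threshold = 1)
  expect_setequal(paste(facts$subject, facts$object),
                  paste(gt$subject, gt$object))
  expect_true(all(facts$confidence == 1))
  # and every harvested fact carries provenance
  expect_true(all(purrr::map_int(facts$provenance, nrow) >= 1L))
})

test_that("harvest without co-occurrences returns an empty candidate set", {
  corp <- support_corpus(list(sent("s1", c("located", "in"), "p1")))
  concepts <- concepts_for("s1", "p1", "d1")
  seeds <- tibble::tibble(schema = "CAUSE", subject = "s1", object = "d1")
  facts <- harvest(corp, "CAUSE", seeds, concepts)
  expect_identical(nrow(facts), 0L)
})

test_that("bootstrapping promotes harvested facts across iterations", {
  corp <- support_corpus(list(
    sent("s1", c("located", "in"), "p1"),
    sent("s2", c("located", "in"), "p2"),
    sent("s2", c("found", "in"), "p2"),
    sent("s3", c("found", "in"), "p3")))
  concepts <- concepts_for(paste0("s", 1:3), paste0("p", 1:3))
  seeds <- tibble::tibble(schema = "LOCATED_IN", subject = "s1",
                          object = "p1")
  one <- harvest(corp, "LOCATED_IN", seeds, concepts,
                 confidence_threshold = 0.5, max_iterations = 1L)
  three <- harvest(corp, "LOCATED_IN", seeds, concepts,
                   confidence_threshold = 0.5, max_iterations = 3L)
  expect_setequal(paste(one$subject, one$object), c("s1 p1", "s2 p2"))
  expect_setequal(paste(three$subject, three$object),
                  c("s1 p1", "s2 p2", "s3 p3"))
  expect_identical(three$iteration[three$subject == "s3"], 2L)
  # monotonicity: earlier iterations are a subset of later ones
  expect_true(all(paste(one$subject, one$object) %in%
                    paste(three$subject, three$object)))
})

test_that("harvest validates its configuration", {
  corp <- support_corpus(list(sent("s1", c("located", "in"), "p1")))
  concepts <- concepts_for("s1", "p1")
  seeds <- tibble::tibble(schema = "LOCATED_IN", subject = "s1",
                          object = "p1")
  expect_error(harvest(corp, "LOCATED_IN", seeds, concepts,
                       confidence_threshold = 0),
               class = "kgchains_config_error")
  expect_error(harvest(corp, "LOCATED_IN", seeds, concepts,
                       confidence_threshold = 1.2),
               class = "kgchains_config_error")
  expect_error(harvest(corp, "LOCATED_IN", seeds[0, ], concepts),
               class = "kgchains_config_error")
  expect_error(harvest(corp, "LOCATED_IN", seeds, concepts,
                       max_iterations = 0L),
               class = "kgchains_config_error")
})

test_that("consistency filter dedups and prefers higher confidence", {
  cand <- tibble::tibble(
    schema = "CAUSE",
    subject = c("s1", "s1", "s1"),
    object = c("d1", "d1", "d2"),
    confidence = c(0.4, 0.9, 0.5))
  out <- consistency_filter(
    cand, constraints = list(functional = c(CAUSE = "at_most_one_object")))
  expect_identical(nrow(out), 1L)
  expect_identical(out$object, "d1")
  expect_identical(out$confidence, 0.9)
  # dedup alone keeps one row per triple and both objects
  out2 <- consistency_filter(cand)
  expect_identical(nrow(out2), 2L)
  expect_setequal(out2$object, c("d1", "d2"))
  expect_identical(out2$confidence[out2$object == "d1"], 0.9)
})

test_that("greedy filtering matches the brute-force optimum (dedup only)", {
  withr::with_seed(19, {
    for (rep in seq_len(20L)) {
      n <- sample(4:10, 1L)
      cand <- tibble::tibble(
        schema = sample(relation_schemas()$schema, n, replace = TRUE),
        subject = sample(paste0("s", 1:3), n, replace = TRUE),
        object = sample(paste0("o", 1:3), n, replace = TRUE),
        confidence = round(stats::runif(n), 3))
      got <- sum(consistency_filter(cand)$confidence)
      opt <- brute_force_consistency_weight(cand)
      expect_equal(got, opt, tolerance = 1e-9)
    }
  })
})

test_that("greedy filtering is near-optimal under functional constraints", {
  constraints <- list(functional = c(CAUSE = "at_most_one_object",
                                     LOCATED_IN = "at_most_one_subject"))
  withr::with_seed(23, {
    for (rep in seq_len(15L)) {
      n <- sample(6:12, 1L)
      cand <- tibble::tibble(
        schema = sample(relation_schemas()$schema, n, replace = TRUE),
        subject = sample(paste0("s", 1:3), n, replace = TRUE),
        object = sample(paste0("o", 1:3), n, replace = TRUE),
        confidence = round(stats::runif(n, 0.05, 1), 3))
      got <- sum(consistency_filter(cand, constraints)$confidence)
      opt <- brute_force_consistency_weight(cand, constraints)
      expect_gte(got, 0.8 * opt)
    }
  })
})

test_that("verification sampling is reproducible and uniform", {
  cand <- tibble::tibble(schema = "CAUSE",
                         subject = paste0("s", 1:10),
                         object = paste0("d", 1:10),
                         confidence = 1)
  # k = n returns every candidate
  all_rows <- sample_for_verification(cand, 10L, seed = 3L)
  expect_setequal(all_rows$subject, cand$subject)
  # same seed, same sample
  expect_identical(sample_for_verification(cand, 4L, seed = 7L),
                   sample_for_verification(cand, 4L, seed = 7L))
  # k > n warns and returns all
  expect_warning(big <- sample_for_verification(cand, 20L, seed = 1L))
  expect_identical(nrow(big), 10L)
  # chi-square goodness of fit over 10,000 single draws
  draws <- vapply(seq_len(10000L), function(s) {
    sample_for_verification(cand, 1L, seed = s)$subject
  }, character(1))
  p <- stats::chisq.test(table(draws))$p.value
  expect_gt(p, 1e-3)
})

test_that("facts TSV round-trips including provenance", {
  bundle <- generate_bundle(small_generator_config())
  gt <- bundle$graph$relations %>% dplyr::filter(schema == "CAUSE")
  facts <- harvest(bundle$corpus, "CAUSE",
                   gt %>% dplyr::select(schema, subject, object),
                   bundle$graph, confidence_threshold = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_facts(facts, f)
  back <- read_facts(f)
  expect_identical(back$schema, facts$schema)
  expect_identical(back$subject, facts$subject)
  expect_identical(back$object, facts$object)
  expect_equal(back$confidence, facts$confidence)
  expect_identical(purrr::map(back$provenance, as.data.frame),
                   purrr::map(facts$provenance, as.data.frame))
})

test_that("manual overrides add and remove facts", {
  facts <- tibble::tibble(
    schema = c("CAUSE", "CAUSE"),
    subject = c("s1", "s2"), object = c("d1", "d2"),
    confidence = c(0.8, 0.9), iteration = 1L,
    provenance = list(provenance_of("d", 0L), provenance_of("d", 7L)))
  ov <- tibble::tibble(
    action = c("remove", "add"),
    schema = c("CAUSE", "LOCATED_IN"),
    subject = c("s2", "s1"), object = c("d2", "p1"),
    confidence = c(NA, 0.5))
  out <- apply_fact_overrides(facts, ov)
  expect_setequal(paste(out$schema, out$subject, out$object),
                  c("CAUSE s1 d1", "LOCATED_IN s1 p1"))
  expect_identical(out$confidence[out$schema == "LOCATED_IN"], 0.5)
  expect_identical(out$iteration[out$schema == "LOCATED_IN"], 0L)
  # adding an existing triple is a no-op
  again <- apply_fact_overrides(out, tibble::tibble(
    action = "add", schema = "CAUSE", subject = "s1", object = "d1"))
  expect_identical(nrow(again), nrow(out))
  # TSV form
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    action = "remove", relation = "CAUSE", subject_id = "s1",
    object_id = "d1"), f)
  out2 <- apply_fact_overrides(out, f)
  expect_false(any(out2$schema == "CAUSE"))
  # validation
  expect_error(apply_fact_overrides(facts, tibble::tibble(
    action = "frobnicate", schema = "CAUSE", subject = "s1",
    object = "d1")), class = "kgchains_format_error")
  expect_error(apply_fact_overrides(facts, file.path(tempdir(), "no.tsv")),
               class = "kgchains_io_error")
})
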