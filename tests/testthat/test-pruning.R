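# a single-step chains tibble over an ad-hoc corpus, for feature tests
one_step_chain <- function(chain_id, subject, object, doc, sent,
                           label = "unlabeled") {
  tibble::tibble(
    chain_id = chain_id,
    entity_path = list(c(subject, object)),
    steps = list(tibble::tibble(
      schema = "LOCATED_IN", traversal = "forward",
      subject = subject, object = object,
      provenance = list(provenance_of(doc, sent)))),
    label = label)
}

test_that("extract_ncs returns the clipped context window", {
  toks <- paste0("w", 1:10)
  corp <- med_corpus(
    tibble::tibble(document_id = "d1", n_sentences = 10L),
    tibble::tibble(document_id = "d1", sentence_index = 0:9,
                   token_index = 0L, surface = toks, pos = "XX"),
    tibble::tibble(document_id = character(), sentence_index = integer(),
                   head = integer(), dep = integer(), label = character()),
    tibble::tibble(document_id = character(), sentence_index = integer(),
                   entity_id = character(), start = integer(),
                   end = integer()))
  w <- extract_ncs(provenance_of("d1", 5L), corp, 3L)
  expect_identical(w$window[[1]], 2:8)
  w0 <- extract_ncs(provenance_of("d1", 0L), corp, 3L)
  expect_identical(w0$window[[1]], 0:3)
  wN0 <- extract_ncs(provenance_of("d1", 5L), corp, 0L)
  expect_identical(wN0$window[[1]], 5L)
  w9 <- extract_ncs(provenance_of("d1", 9L), corp, 3L)
  expect_identical(w9$window[[1]], 6:9)
  expect_error(extract_ncs(provenance_of("d1", 12L), corp, 3L),
               class = "kgchains_provenance_error")
  expect_error(extract_ncs(provenance_of("ghost", 0L), corp, 3L),
               class = "kgchains_provenance_error")
  expect_error(extract_ncs(provenance_of("d1", 0L)[0, ], corp, 3L),
               class = "kgchains_provenance_error")
  expect_error(extract_ncs(provenance_of("d1", 5L), corp, -1L),
               class = "kgchains_config_error")
})

test_that("the vocabulary is invariant to chain order", {
  bundle <- generate_bundle(small_generator_config())
  v1 <- fit_vocabulary(bundle$chains, bundle$corpus, 3L)
  v2 <- fit_vocabulary(bundle$chains[rev(seq_len(nrow(bundle$chains))), ],
                       bundle$corpus, 3L)
  expect_identical(v1, v2)
  expect_identical(unclass(v1), sort(unique(unclass(v1))))
})

test_that("featurize counts window terms into the step's block", {
  corp <- one_sentence_corpus(c("lung", "lung", "cough"))
  vocab <- structure(c("cough", "lung"), class = "kgc_vocabulary")
  ch <- one_step_chain(1L, "s1", "p1", "d1", 0L)
  X <- featurize_chains(ch, corp, vocab, 0L)
  expect_identical(dim(X), c(1L, 4L))
  expect_identical(as.numeric(X[1, 1:2]), c(1, 2))   # cough 1, lung 2
  expect_identical(as.numeric(X[1, 3:4]), c(0, 0))   # entity terms not in V
  # entity-name blocks count endpoint terms present in the vocabulary
  ch2 <- one_step_chain(1L, "cough", "lung", "d1", 0L)
  X2 <- featurize_chains(ch2, corp, vocab, 0L)
  expect_identical(as.numeric(X2[1, 3:4]), c(1, 1))
})

test_that("chains with identical windows get identical feature rows", {
  bundle <- generate_bundle(small_generator_config())
  ch <- bundle$chains[1, ]
  two <- dplyr::bind_rows(ch, ch) %>% dplyr::mutate(chain_id = 1:2)
  vocab <- fit_vocabulary(bundle$chains, bundle$corpus, 3L)
  X <- featurize_chains(two, bundle$corpus, vocab, 3L)
  expect_identical(as.numeric(X[1, ]), as.numeric(X[2, ]))
  # featurization is a pure function: same inputs, same matrix
  X2 <- featurize_chains(two, bundle$corpus, vocab, 3L)
  expect_identical(as.matrix(X), as.matrix(X2))
})

test_that("a relation without provenance is a feature error naming the chain", {
  corp <- one_sentence_corpus(c("a", "b"))
  ch <- one_step_chain(7L, "s1", "p1", "d1", 0L)
  ch$steps[[1]]$provenance <- list(provenance_of("d1", 0L)[0, ])
  err <- expect_error(
    featurize_chains(ch, corp,
                     structure("a", class = "kgc_vocabulary"), 0L),
    class = "kgchains_feature_error")
  expect_match(conditionMessage(err), "chain 7")
  # out-of-range provenance is a provenance error
  ch2 <- one_step_chain(1L, "s1", "p1", "d1", 5L)
  expect_error(
    featurize_chains(ch2, corp,
                     structure("a", class = "kgc_vocabulary"), 0L),
    class = "kgchains_provenance_error")
})

test_that("noise-free signal lands in the step context blocks", {
  bundle <- generate_bundle(small_generator_config(p_signal = 1,
                                                   p_noise = 0))
  vocab <- fit_vocabulary(bundle$chains, bundle$corpus, 3L)
  X <- featurize_chains(bundle$chains, bundle$corpus, vocab, 3L)
  V <- length(vocab)
  # the CAUSE step (block 2) context co-mentions the chain's bodily part
  # for meaningful chains and never for meaningless ones
  part_surface <- purrr::map_chr(bundle$chains$entity_path, 1L)
  col <- V + match(part_surface, vocab)
  hit <- vapply(seq_len(nrow(bundle$chains)),
                function(i) X[i, col[i]] > 0, logical(1))
  expect_identical(hit, bundle$chains$label == "meaningful")
})

test_that("all four classifiers reach accuracy 1 on a separable fixture", {
  bundle <- generate_bundle(medium_generator_config())
  for (cls in c("logistic_regression", "naive_bayes", "linear_svm",
                "decision_tree")) {
    model <- train_pruner(bundle$chains, bundle$corpus,
                          pruning_config(classifier = cls, seed = 1L))
    pred <- suppressWarnings(predict(model, bundle$chains,
                                     bundle$corpus))
    expect_identical(pred$.pred_label, bundle$chains$label,
                     info = cls)
  }
})

test_that("flipping the training labels flips the predictions", {
  bundle <- generate_bundle(small_generator_config(p_signal = 1,
                                                   p_noise = 0))
  cfg <- pruning_config(seed = 4L)
  flip <- function(l) ifelse(l == "meaningful", "meaningless",
                             "meaningful")
  m1 <- train_pruner(bundle$chains, bundle$corpus, cfg)
  chains_flipped <- bundle$chains %>% dplyr::mutate(label = flip(label))
  m2 <- train_pruner(chains_flipped, bundle$corpus, cfg)
  p1 <- predict(m1, bundle$chains, bundle$corpus)$.pred_label
  p2 <- predict(m2, bundle$chains, bundle$corpus)$.pred_label
  expect_identical(p2, flip(p1))
})

test_that("training is deterministic under the configuration seed", {
  bundle <- generate_bundle(small_generator_config())
  cfg <- pruning_config(seed = 9L)
  e1 <- evaluate_pruning(bundle$chains, bundle$corpus, cfg)
  e2 <- evaluate_pruning(bundle$chains, bundle$corpus, cfg)
  expect_identical(e1$folds, e2$folds)
  expect_identical(e1$precision, e2$precision)
  expect_identical(e1$recall, e2$recall)
})

test_that("the no-pruning baseline precision is the positive prevalence", {
  bundle <- generate_bundle(small_generator_config())
  ev <- evaluate_pruning(bundle$chains, bundle$corpus,
                         pruning_config(seed = 1L))
  expect_identical(ev$baseline_precision, 0.5)
  expect_identical(ev$baseline_recall, NA_real_)
  # every chain is scored exactly once across the folds
  expect_identical(sum(ev$folds$tp + ev$folds$fp + ev$folds$tn +
                         ev$folds$fn),
                   as.integer(nrow(bundle$chains)))
  expect_identical(nrow(ev$folds), 5L)
})

test_that("evaluation metrics are invariant to chain order (noise-free)", {
  bundle <- generate_bundle(medium_generator_config())
  cfg <- pruning_config(seed = 2L)
  e1 <- evaluate_pruning(bundle$chains, bundle$corpus, cfg)
  shuffled <- bundle$chains[rev(seq_len(nrow(bundle$chains))), ]
  e2 <- evaluate_pruning(shuffled, bundle$corpus, cfg)
  expect_identical(e1$precision, 1)
  expect_identical(e1$recall, 1)
  expect_identical(e2$precision, e1$precision)
  expect_identical(e2$recall, e1$recall)
})

test_that("prune_chains partitions its input", {
  bundle <- generate_bundle(small_generator_config())
  model <- train_pruner(bundle$chains, bundle$corpus,
                        pruning_config(seed = 1L))
  parts <- prune_chains(bundle$chains, model, bundle$corpus)
  expect_identical(nrow(parts$retained) + nrow(parts$discarded),
                   nrow(bundle$chains))
  expect_length(intersect(parts$retained$chain_id,
                          parts$discarded$chain_id), 0L)
  expect_setequal(c(parts$retained$chain_id, parts$discarded$chain_id),
                  bundle$chains$chain_id)
  expect_false(".pred_label" %in% names(parts$retained))
  # empty input gives two empty parts
  empty <- prune_chains(bundle$chains[0, ], model, bundle$corpus)
  expect_identical(nrow(empty$retained), 0L)
  expect_identical(nrow(empty$discarded), 0L)
})

test_that("the worked-example chains split as the motif predicts", {
  bundle <- generate_bundle(medium_generator_config())
  model <- train_pruner(bundle$chains, bundle$corpus,
                        pruning_config(seed = 1L))
  demo <- bundle$chains[1:2, ]
  expect_identical(demo$entity_path[[1]][1], "lung")
  expect_identical(demo$entity_path[[2]][1], "skin")
  parts <- prune_chains(demo, model, bundle$corpus)
  expect_identical(parts$retained$entity_path[[1]][1], "lung")
  expect_identical(parts$discarded$entity_path[[1]][1], "skin")
})

test_that("configuration and label validation", {
  expect_error(pruning_config(context_range = -1L),
               class = "kgchains_config_error")
  expect_error(pruning_config(cv_folds = 1L),
               class = "kgchains_config_error")
  expect_error(pruning_config(classifier = "perceptron"))
  bundle <- generate_bundle(small_generator_config())
  bad <- bundle$chains %>% dplyr::mutate(label = "unlabeled")
  expect_error(train_pruner(bad, bundle$corpus),
               class = "kgchains_config_error")
  one_class <- bundle$chains %>% dplyr::mutate(label = "meaningful")
  expect_error(train_pruner(one_class, bundle$corpus),
               class = "kgchains_config_error")
  # too few chains per class for the fold count
  tiny <- bundle$chains[1:4, ]
  expect_error(evaluate_pruning(tiny, bundle$corpus,
                                pruning_config(cv_folds = 5L)),
               class = "kgchains_config_error")
  # predicting with mismatched chain length
  model <- train_pruner(bundle$chains, bundle$corpus,
                        pruning_config(seed = 1L))
  short <- one_step_chain(1L, "s1", "p1", "dX", 0L)
  expect_error(predict(model, short, bundle$corpus),
               class = "kgchains_model_error")
})
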