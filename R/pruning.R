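#' Configuration of the contextual pruning classifier
#'
#' Defaults reproduce the evaluation setting: context range 3 sentences on
#' each side of a supporting sentence, logistic regression, stratified
#' 5-fold cross-validation.
#'
#' @param context_range Non-negative integer N; each supporting sentence
#'   contributes the window of the N preceding and N following sentences
#'   (its "N-contextual sentences").
#' @param classifier One of `"logistic_regression"`, `"naive_bayes"`,
#'   `"linear_svm"`, `"decision_tree"`.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling fold assignment.
#' @return A list of class `kgc_pruning_config`.
#' @export
pruning_config <- function(context_range = 3L,
                           classifier = c("logistic_regression",
                                          "naive_bayes", "linear_svm",
                                          "decision_tree"),
                           cv_folds = 5L, seed = 1L) {
  classifier <- match.arg(classifier)
  if (context_range < 0L) {
    kgc_abort("context_range must be >= 0", "kgchains_config_error")
  }
  if (cv_folds < 2L) {
    kgc_abort("cv_folds must be >= 2", "kgchains_config_error")
  }
  structure(list(context_range = as.integer(context_range),
                 classifier = classifier, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "kgc_pruning_config")
}

#' Context windows of a relation's supporting sentences
#'
#' For each provenance sentence s the window `{s-N, ..., s, ..., s+N}` is
#' returned, clipped to the document bounds, so a window never exceeds
#' 2N + 1 sentences.
#'
#' @param provenance Tibble with `document_id`, `sentence_index` rows.
#' @param corpus A `med_corpus`.
#' @param N Context range (non-negative integer).
#' @return A tibble with one row per provenance sentence: `document_id`,
#'   `support_sentence`, `window` (list of sorted sentence indices).
#' @export
extract_ncs <- function(provenance, corpus, N) {
  stopifnot(inherits(corpus, "med_corpus"))
  if (N < 0L) kgc_abort("N must be >= 0", "kgchains_config_error")
  prov <- normalize_provenance(provenance)
  if (nrow(prov) == 0L) {
    kgc_abort("relation has no provenance", "kgchains_provenance_error")
  }
  len <- setNames(corpus$documents$n_sentences,
                  corpus$documents$document_id)
  doc_len <- len[prov$document_id]
  if (anyNA(doc_len) || any(prov$sentence_index < 0L) ||
      any(prov$sentence_index >= doc_len)) {
    bad <- which(is.na(doc_len) | prov$sentence_index < 0L |
                   prov$sentence_index >= doc_len)[1L]
    kgc_abort(paste0("provenance sentence out of document range: ",
                     prov$document_id[bad], ":", prov$sentence_index[bad]),
              "kgchains_provenance_error")
  }
  prov %>%
    mutate(window = purrr::map2(
      .data$sentence_index, doc_len,
      function(s, L) seq.int(max(0L, s - N), min(L - 1L, s + N)))) %>%
    select("document_id", support_sentence = "sentence_index", "window")
}

chain_n_steps <- function(chains) {
  ns <- unique(purrr::map_int(chains$steps, nrow))
  if (length(ns) != 1L) {
    kgc_abort("all chains must have the same number of relations",
              "kgchains_model_error")
  }
  ns
}

entity_name_terms <- function(entity_id) {
  strsplit(gsub("_", " ", entity_id), " ", fixed = TRUE)[[1]]
}

# One row per (chain, step, document, window sentence), windows unioned
# over the step's provenance sentences.
chain_window_sentences <- function(chains, corpus, N) {
  steps <- chains %>%
    select("chain_id", "steps") %>%
    tidyr::unnest("steps") %>%
    group_by(.data$chain_id) %>%
    mutate(step_idx = row_number()) %>%
    ungroup()
  prov_n <- purrr::map_int(steps$provenance,
                           ~ if (is.null(.x)) 0L else nrow(.x))
  if (any(prov_n == 0L)) {
    i <- which(prov_n == 0L)[1L]
    kgc_abort(paste0("relation without provenance in chain ",
                     steps$chain_id[i], ": ", steps$schema[i], "(",
                     steps$subject[i], ", ", steps$object[i], ")"),
              "kgchains_feature_error")
  }
  pv <- bind_rows(steps$provenance)
  prov <- tibble(
    chain_id = rep(steps$chain_id, prov_n),
    step_idx = rep(steps$step_idx, prov_n),
    document_id = as.character(pv$document_id),
    sentence_index = as.integer(pv$sentence_index)
  )
  len <- setNames(corpus$documents$n_sentences,
                  corpus$documents$document_id)
  L <- unname(len[prov$document_id])
  oob <- is.na(L) | prov$sentence_index < 0L | prov$sentence_index >= L
  if (any(oob)) {
    i <- which(oob)[1L]
    kgc_abort(paste0("provenance sentence out of document range: ",
                     prov$document_id[i], ":", prov$sentence_index[i]),
              "kgchains_provenance_error")
  }
  off <- seq.int(-N, N)
  k <- length(off)
  win <- tibble(
    chain_id = rep(prov$chain_id, each = k),
    step_idx = rep(prov$step_idx, each = k),
    document_id = rep(prov$document_id, each = k),
    sentence_index = rep(prov$sentence_index, each = k) +
      rep(off, nrow(prov)),
    .max_sent = rep(L, each = k)
  ) %>%
    filter(.data$sentence_index >= 0L,
           .data$sentence_index < .data$.max_sent) %>%
    distinct(.data$chain_id, .data$step_idx, .data$document_id,
             .data$sentence_index)
  list(steps = steps, windows = win)
}

#' Fit the document-term vocabulary of a training chain set
#'
#' The vocabulary is the sorted set of all token surfaces occurring in any
#' training chain's N-contextual sentences, together with the entity-name
#' terms of the chain relations' endpoints.  It is fixed after fitting;
#' unseen terms are ignored at transform time.
#'
#' @param chains A chains tibble whose relations carry provenance.
#' @param corpus A `med_corpus`.
#' @param N Context range.
#' @return Sorted character vector of terms (class `kgc_vocabulary`).
#' @export
fit_vocabulary <- function(chains, corpus, N) {
  if (nrow(chains) == 0L) {
    kgc_abort("empty training chain set", "kgchains_config_error")
  }
  cw <- chain_window_sentences(chains, corpus, N)
  toks <- cw$windows %>%
    distinct(.data$document_id, .data$sentence_index) %>%
    inner_join(corpus$tokens, by = c("document_id", "sentence_index"))
  ent_terms <- unlist(lapply(unique(c(cw$steps$subject, cw$steps$object)),
                             entity_name_terms))
  terms <- sort(unique(c(toks$surface, ent_terms)), method = "radix")
  structure(terms, class = "kgc_vocabulary")
}

#' Turn chains into blocked document-term feature vectors
#'
#' For each relation of a chain, term counts are summed over the union of
#' its context windows; the per-relation blocks are concatenated in chain
#' order, followed by per-relation entity-name term-count blocks in the
#' same order.  The result has `2 * n_relations * |vocabulary|` columns and
#' is a pure function of (chains, corpus, vocabulary, N).
#'
#' @param chains A chains tibble.
#' @param corpus A `med_corpus`.
#' @param vocab A `kgc_vocabulary`.
#' @param N Context range.
#' @return A sparse `dgCMatrix` with one row per chain.
#' @export
featurize_chains <- function(chains, corpus, vocab, N) {
  n_steps <- chain_n_steps(chains)
  V <- length(vocab)
  n <- nrow(chains)
  cw <- chain_window_sentences(chains, corpus, N)
  row_of <- match(cw$steps$chain_id, chains$chain_id)
  ncs_counts <- cw$windows %>%
    inner_join(corpus$tokens, by = c("document_id", "sentence_index"),
               relationship = "many-to-many") %>%
    mutate(term_idx = match(.data$surface, vocab)) %>%
    filter(!is.na(.data$term_idx)) %>%
    dplyr::count(.data$chain_id, .data$step_idx, .data$term_idx,
                 name = "count")
  ncs_i <- match(ncs_counts$chain_id, chains$chain_id)
  ncs_j <- (ncs_counts$step_idx - 1L) * V + ncs_counts$term_idx
  ent <- cw$steps %>%
    mutate(row = row_of) %>%
    select("row", "step_idx", "subject", "object") %>%
    tidyr::pivot_longer(c("subject", "object"), values_to = "entity_id") %>%
    mutate(terms = purrr::map(.data$entity_id, entity_name_terms)) %>%
    tidyr::unnest("terms") %>%
    mutate(term_idx = match(.data$terms, vocab)) %>%
    filter(!is.na(.data$term_idx)) %>%
    dplyr::count(.data$row, .data$step_idx, .data$term_idx, name = "count")
  ent_j <- n_steps * V + (ent$step_idx - 1L) * V + ent$term_idx
  Matrix::sparseMatrix(
    i = c(ncs_i, ent$row),
    j = c(ncs_j, ent_j),
    x = c(ncs_counts$count, ent$count),
    dims = c(n, 2L * n_steps * V)
  )
}

fit_classifier <- function(X, y, classifier) {
  # y: factor with levels c("meaningless", "meaningful")
  switch(
    classifier,
    logistic_regression = {
      # elastic-net penalized logistic regression with per-feature
      # standardization; the penalty strength is chosen by internal
      # cross-validation, which is deterministic here because
      # fit_classifier runs under the configuration seed
      nfolds <- max(3L, min(10L, floor(min(table(y)) / 2)))
      fit <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0.5,
                               nfolds = nfolds, standardize = TRUE)
      list(kind = "glmnet", fit = fit)
    },
    linear_svm = {
      # standardize nonconstant columns (training statistics are stored
      # and re-applied at prediction time)
      Xd <- as.matrix(X)
      ctr <- colMeans(Xd)
      sdv <- apply(Xd, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      Xs <- sweep(sweep(Xd, 2L, ctr), 2L, sdv, "/")
      fit <- e1071::svm(x = Xs, y = y, kernel = "linear",
                        scale = FALSE, cost = 1)
      list(kind = "svm", fit = fit, center = ctr, scale = sdv)
    },
    decision_tree = {
      df <- as.data.frame(as.matrix(X))
      names(df) <- paste0("x", seq_len(ncol(df)))
      df$.y <- y
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(cp = 0,
                                                         minsplit = 2L))
      list(kind = "rpart", fit = fit)
    },
    naive_bayes = {
      # multinomial event model with Laplace smoothing
      Xl <- as.matrix(X)
      classes <- levels(y)
      log_prior <- log(table(y)[classes] / length(y))
      log_theta <- sapply(classes, function(cl) {
        cnt <- colSums(Xl[y == cl, , drop = FALSE]) + 1
        log(cnt / sum(cnt))
      })
      list(kind = "multinomial_nb", log_prior = as.numeric(log_prior),
           log_theta = log_theta, classes = classes)
    },
    kgc_abort(paste0("unknown classifier: ", classifier),
              "kgchains_config_error")
  )
}

predict_classifier <- function(model, X) {
  switch(
    model$kind,
    glmnet = as.character(predict(model$fit, newx = X, type = "class",
                                  s = "lambda.min")),
    svm = {
      Xs <- sweep(sweep(as.matrix(X), 2L, model$center), 2L,
                  model$scale, "/")
      as.character(predict(model$fit, newdata = Xs))
    },
    rpart = {
      df <- as.data.frame(as.matrix(X))
      names(df) <- paste0("x", seq_len(ncol(df)))
      as.character(predict(model$fit, newdata = df, type = "class"))
    },
    multinomial_nb = {
      scores <- as.matrix(X) %*% model$log_theta
      scores <- sweep(scores, 2L, model$log_prior, "+")
      model$classes[max.col(scores, ties.method = "first")]
    }
  )
}

check_labels <- function(labels) {
  ok <- labels %in% c("meaningful", "meaningless")
  if (!all(ok)) {
    kgc_abort("chains must be labeled meaningful or meaningless",
              "kgchains_config_error")
  }
  if (length(unique(labels)) < 2L) {
    kgc_abort("training data must contain both labels",
              "kgchains_config_error")
  }
  factor(labels, levels = c("meaningless", "meaningful"))
}

#' Train a contextual chain-pruning classifier
#'
#' Fits the configured binary classifier on the blocked document-term
#' features of the labeled chains; the positive class is `meaningful`.
#' Deterministic for a fixed configuration seed.
#'
#' @param chains Labeled chains tibble (labels `meaningful` /
#'   `meaningless`, both present).
#' @param corpus A `med_corpus`.
#' @param config A [pruning_config()].
#' @return A fitted model of class `chain_pruner` carrying its vocabulary
#'   and configuration.
#' @export
train_pruner <- function(chains, corpus, config = pruning_config()) {
  stopifnot(inherits(config, "kgc_pruning_config"))
  y <- check_labels(chains$label)
  vocab <- fit_vocabulary(chains, corpus, config$context_range)
  X <- featurize_chains(chains, corpus, vocab, config$context_range)
  fit <- withr::with_seed(config$seed,
                          fit_classifier(X, y, config$classifier))
  structure(
    list(config = config, vocab = vocab,
         n_steps = chain_n_steps(chains), fit = fit,
         n_train = nrow(chains)),
    class = "chain_pruner"
  )
}

#' @exportS3Method base::print
print.chain_pruner <- function(x, ...) {
  cat("<chain_pruner> ", x$config$classifier, ", ", x$n_steps,
      "-relation chains, |V| = ", length(x$vocab),
      ", trained on ", x$n_train, " chains\n", sep = "")
  invisible(x)
}

#' Predict chain labels with a fitted pruner
#'
#' @param object A `chain_pruner`.
#' @param chains A chains tibble with the same number of relations per
#'   chain as the training data.
#' @param corpus The corpus the chains' provenance points into.
#' @param ... Unused.
#' @return `chains` with a `.pred_label` column.
#' @export
predict.chain_pruner <- function(object, chains, corpus, ...) {
  if (nrow(chains) == 0L) {
    chains$.pred_label <- character()
    return(chains)
  }
  if (chain_n_steps(chains) != object$n_steps) {
    kgc_abort("chain length differs from the model's training chains",
              "kgchains_model_error")
  }
  X <- featurize_chains(chains, corpus, object$vocab,
                        object$config$context_range)
  chains$.pred_label <- predict_classifier(object$fit, X)
  chains
}

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        kgc_abort(paste0("need at least ", k, " chains of class ", cl,
                         " for ", k, "-fold cross-validation"),
                  "kgchains_config_error")
      }
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated evaluation of contextual pruning
#'
#' Stratified k-fold cross-validation of the configured classifier; within
#' each fold the vocabulary and model are fitted on the training chains
#' only.  Reports the pooled precision and recall of the positive
#' (meaningful) class over all folds, the per-fold confusion matrices, and
#' the no-pruning baseline that accepts every chain (precision = positive
#' prevalence; recall trivially 1, reported as `NA`).
#'
#' @inheritParams train_pruner
#' @return An object of class `pruning_eval`.
#' @export
evaluate_pruning <- function(chains, corpus, config = pruning_config()) {
  stopifnot(inherits(config, "kgc_pruning_config"))
  y <- check_labels(chains$label)
  fold <- stratified_folds(as.character(y), config$cv_folds, config$seed)
  folds <- purrr::map(seq_len(config$cv_folds), function(f) {
    train_idx <- which(fold != f)
    test_idx <- which(fold == f)
    model <- train_pruner(chains[train_idx, ], corpus, config)
    pred <- predict(model, chains[test_idx, ], corpus)$.pred_label
    truth <- as.character(y)[test_idx]
    tibble(
      fold = f,
      tp = sum(pred == "meaningful" & truth == "meaningful"),
      fp = sum(pred == "meaningful" & truth == "meaningless"),
      tn = sum(pred == "meaningless" & truth == "meaningless"),
      fn = sum(pred == "meaningless" & truth == "meaningful")
    )
  }) %>% bind_rows()
  tp <- sum(folds$tp); fp <- sum(folds$fp); fn <- sum(folds$fn)
  structure(
    list(
      classifier = config$classifier,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      baseline_precision = mean(y == "meaningful"),
      baseline_recall = NA_real_,
      folds = folds,
      n = nrow(chains),
      config = config
    ),
    class = "pruning_eval"
  )
}

#' @exportS3Method base::print
print.pruning_eval <- function(x, ...) {
  cat("<pruning_eval> ", x$classifier, " over ",
      nrow(x$folds), " folds, n = ", x$n, "\n", sep = "")
  cat(sprintf("  precision %.3f  recall %.3f  (no-pruning baseline precision %.3f)\n",
              x$precision, x$recall, x$baseline_precision))
  invisible(x)
}

#' Partition chains into retained and discarded sets
#'
#' Applies a fitted pruner to candidate chains: chains predicted meaningful
#' are retained, chains predicted meaningless are discarded.  The two parts
#' are disjoint and their union is the input.
#'
#' @param chains A chains tibble.
#' @param model A `chain_pruner`.
#' @param corpus A `med_corpus`.
#' @return A list with elements `retained` and `discarded`.
#' @export
prune_chains <- function(chains, model, corpus) {
  stopifnot(inherits(model, "chain_pruner"))
  if (nrow(chains) == 0L) {
    return(list(retained = chains, discarded = chains))
  }
  pred <- predict(model, chains, corpus)
  list(
    retained = pred %>% filter(.data$.pred_label == "meaningful") %>%
      select(-".pred_label"),
    discarded = pred %>% filter(.data$.pred_label == "meaningless") %>%
      select(-".pred_label")
  )
}

#' Write an evaluation report as JSON
#'
#' @param report A `pruning_eval`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "pruning_eval"))
  jsonlite::write_json(
    list(classifier = report$classifier,
         precision = report$precision, recall = report$recall,
         baseline_precision = report$baseline_precision,
         n = report$n,
         folds = report$folds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
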