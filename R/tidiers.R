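#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validated pruning evaluation
#'
#' @param x A `pruning_eval`.
#' @param ... Unused.
#' @return One row per fold with the confusion-matrix counts and the
#'   fold-level precision/recall of the meaningful class.
#' @export
tidy.pruning_eval <- function(x, ...) {
  x$folds %>%
    mutate(
      precision = if_else(.data$tp + .data$fp > 0,
                          .data$tp / (.data$tp + .data$fp), NA_real_),
      recall = if_else(.data$tp + .data$fn > 0,
                       .data$tp / (.data$tp + .data$fn), NA_real_)
    )
}

#' @rdname tidy.pruning_eval
#' @export
glance.pruning_eval <- function(x, ...) {
  tibble(
    classifier = x$classifier,
    precision = x$precision,
    recall = x$recall,
    baseline_precision = x$baseline_precision,
    cv_folds = nrow(x$folds),
    n = x$n
  )
}

decode_feature <- function(j, vocab, n_steps) {
  V <- length(vocab)
  block <- ifelse(j <= n_steps * V, "context", "entity")
  step <- ifelse(j <= n_steps * V, (j - 1L) %/% V + 1L,
                 (j - n_steps * V - 1L) %/% V + 1L)
  term <- vocab[(j - 1L) %% V + 1L]
  tibble(feature = j, block = block, step = step, term = term)
}

#' Tidy a fitted chain pruner
#'
#' @param x A `chain_pruner`.
#' @param ... Unused.
#' @return A tibble of per-feature weights (nonzero logistic-regression
#'   coefficients, naive-Bayes log-likelihood-ratio scores, or
#'   decision-tree variable importances), decoded into block / step / term.
#' @export
tidy.chain_pruner <- function(x, ...) {
  w <- switch(
    x$fit$kind,
    glmnet = {
      b <- as.matrix(stats::coef(x$fit$fit, s = "lambda.min"))[-1L, 1L]
      tibble(feature = which(b != 0), weight = b[b != 0])
    },
    multinomial_nb = {
      d <- x$fit$log_theta[, "meaningful"] - x$fit$log_theta[, "meaningless"]
      tibble(feature = seq_along(d), weight = unname(d))
    },
    rpart = {
      imp <- x$fit$fit$variable.importance
      if (is.null(imp)) return(tibble(feature = integer(),
                                      block = character(),
                                      step = integer(), term = character(),
                                      weight = double()))
      tibble(feature = as.integer(sub("^x", "", names(imp))),
             weight = unname(imp))
    },
    svm = {
      w <- drop(crossprod(x$fit$fit$coefs, x$fit$fit$SV))
      tibble(feature = which(w != 0), weight = w[w != 0])
    }
  )
  left_join(w, decode_feature(w$feature, x$vocab, x$n_steps),
            by = "feature") %>%
    select("feature", "block", "step", "term", "weight") %>%
    arrange(dplyr::desc(abs(.data$weight)))
}

#' @rdname tidy.chain_pruner
#' @export
glance.chain_pruner <- function(x, ...) {
  tibble(
    classifier = x$config$classifier,
    context_range = x$config$context_range,
    vocabulary_size = length(x$vocab),
    n_relations = x$n_steps,
    n_features = 2L * x$n_steps * length(x$vocab),
    n_train = x$n_train
  )
}

#' Plot a pruning evaluation
#'
#' Bar chart of the pooled precision and recall of the meaningful class,
#' with the accept-everything baseline precision as a dashed reference.
#'
#' @param object A `pruning_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pruning_eval <- function(object, ...) {
  df <- tibble(metric = c("precision", "recall"),
               value = c(object$precision, object$recall))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(width = 0.6, fill = "#33658A") +
    ggplot2::geom_hline(yintercept = object$baseline_precision,
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      title = paste0("Contextual pruning (", object$classifier, ", ",
                     nrow(object$folds), "-fold CV, n = ", object$n, ")"),
      y = "pooled score (meaningful class)", x = NULL,
      caption = "dashed line: no-pruning baseline precision") +
    ggplot2::theme_minimal()
}

#' Plot the strongest features of a fitted pruner
#'
#' @param object A `chain_pruner`.
#' @param n Number of features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chain_pruner <- function(object, n = 20L, ...) {
  df <- tidy(object) %>%
    head(n) %>%
    mutate(label = paste0(.data$term, " [", .data$block, " ", .data$step,
                          "]"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, abs(.data$weight)),
    y = .data$weight)) +
    ggplot2::geom_col(fill = "#758E4F") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "feature weight",
                  title = paste0("Top features (",
                                 object$config$classifier, ")")) +
    ggplot2::theme_minimal()
}

#' Plot the composition of a knowledge graph
#'
#' @param object A `med_kg`.
#' @param ... Unused.
#' @return A ggplot object with entity counts per concept class and
#'   relation counts per schema.
#' @export
autoplot.med_kg <- function(object, ...) {
  df <- bind_rows(
    object$entities %>% dplyr::count(name = "n", .data$concept) %>%
      rename(level = "concept") %>% mutate(kind = "entities"),
    object$relations %>% dplyr::count(name = "n", .data$schema) %>%
      rename(level = "schema") %>% mutate(kind = "relations")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$n)) +
    ggplot2::geom_col(fill = "#86BBD8") +
    ggplot2::facet_wrap(~kind, scales = "free") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}
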