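Package: kgchains
Title: Medical Knowledge Graph Construction, Chain Inference and
    Contextual Pruning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds typed medical knowledge graphs from text by
    bootstrapped, seed-fact-driven mining of shortest-dependency-path
    patterns, performs forward and backward chain inference over the
    resulting binary relations, and prunes meaningless inference chains
    with a contextual classifier trained on document-term features of
    each relation's surrounding sentences.  Includes a synthetic corpus
    and graph generator with controllable contextual co-mention signal,
    RDF N-Triples export, broom-style tidiers, ggplot2 autoplot methods
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
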