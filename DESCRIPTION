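Package: radvizr
Title: RadViz Projection Search and Sparse Classification for Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Visualization-aided feature selection and classification for
    high-dimensional expression profiles. Maps samples into the unit disk with
    the RadViz spring-equilibrium projection, scores projections by
    leave-one-out k-nearest-neighbour class separation (VizRank), searches the
    projection space with signal-to-noise biased subset sampling, exhaustive
    anchor permutations and local optimization, and derives gene signatures
    from projection frequency tables. Includes threshold gradient descent
    regularized (TGDR) multinomial logistic models, Gaussian naive Bayes and
    support vector machine classifiers, multiclass probabilistic evaluation
    metrics (error rate, generalized Brier score, belief confusion metric,
    macro-averaged area under the precision-recall curve), and a multinomial
    logit simulator with known relevant features for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    stats,
    utils,
    tools,
    generics,
    e1071
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr,
    pROC,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
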