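#' Softmax class probabilities with a reference class
#'
#' Converts a matrix of logits for classes `2..K` (class 1 is the reference,
#' with implicit logit 0) into multinomial class probabilities. Computed with
#' a log-sum-exp guard so large logits do not overflow.
#'
#' @param logits Numeric matrix, samples by `K - 1` logits (or a vector for a
#'   single sample).
#' @return Numeric matrix, samples by `K` probabilities; rows sum to 1.
#' @examples
#' class_probabilities(matrix(c(0, 0), 1))        # (1/3, 1/3, 1/3)
#' class_probabilities(matrix(c(log(2), 0), 1))   # (0.25, 0.5, 0.25)
#' @export
class_probabilities <- function(logits) {
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1)
  if (!all(is.finite(logits))) abort("logits must be finite")
  # log denominator = log(1 + sum exp(f_k)), stabilised by the row max of (0, f)
  m <- pmax(0, apply(logits, 1, max))
  log_denom <- m + log(exp(-m) + rowSums(exp(logits - m)))
  p <- cbind(exp(-log_denom), exp(logits - log_denom))
  colnames(p) <- paste0("class", seq_len(ncol(p)))
  p
}

design_relevant_sets <- function(design) {
  switch(as.character(design),
    "1" = list("2" = 1:5, "3" = 1:5),
    "2" = list("2" = 1:6, "3" = 7:12),
    "3" = list("2" = 1:2, "3" = 1:2),
    abort("`design` must be 1, 2 or 3")
  )
}

#' Simulate a multinomial-logit expression benchmark with known relevant genes
#'
#' Generates the three benchmark designs used to test whether the projection
#' search recovers truly informative features. Samples have i.i.d. standard
#' normal expression values for `n_features` genes; class membership for
#' `K = 3` classes is drawn from a multinomial logit in which the logits of
#' classes 2 and 3 (class 1 as reference) are linear in a small set of
#' relevant features with coefficients drawn once from
#' `Unif(coef_range[1], coef_range[2])`:
#' * design 1 — both logits share relevant features `X1..X5` (with different
#'   coefficients); by default 20 irrelevant features are additionally made
#'   highly correlated (`rho = 0.9`) with randomly chosen relevant ones;
#' * design 2 — the class-2 logit depends on `X1..X6`, the class-3 logit on
#'   `X7..X12`;
#' * design 3 — both logits share `X1..X2`.
#'
#' Class membership is assigned by the logit functions: each sample gets the
#' class whose logit is largest (the reference class has logit 0), so labels
#' are a deterministic function of the relevant features and the drawn
#' coefficients, and perfect class separation exists in the relevant-feature
#' subspace. Set `assignment = "multinomial"` to instead draw labels from
#' the multinomial probabilities, which adds irreducible label noise on top
#' of the same logits.
#'
#' A single master `seed` is fanned out to independent sub-streams for the
#' coefficient draw, the feature draw, the correlated block and the label
#' draw, so changing `n_samples` does not perturb the coefficients.
#'
#' @param design Design id: 1, 2 or 3.
#' @param n_samples,n_features,n_classes Dataset dimensions (defaults 71,
#'   384, 3).
#' @param relevant_sets Optional override: named list (names = non-reference
#'   class labels) of feature index vectors driving each logit.
#' @param coef_range Length-2 numeric, the Unif() support for coefficients.
#' @param corr_block `NULL`, or `list(n_features =, rho =)` to regenerate that
#'   many irrelevant features as `rho`-correlated copies of randomly chosen
#'   relevant features plus independent noise. Default: 20 features at
#'   `rho = 0.9` for design 1, none otherwise.
#' @param assignment `"logit_argmax"` (default): class = argmax of the
#'   logits, reference logit 0; `"multinomial"`: labels drawn from the
#'   multinomial class probabilities.
#' @param seed Master seed (integer) for reproducibility.
#' @return An object of class `radviz_sim`: a list with `data` (tibble with
#'   `sample_id`, `class` and feature columns `X1..Xp`), `truth` (indices of
#'   truly relevant features), `truth_features` (their names), `coefficients`
#'   (tibble: class, feature, beta), `probabilities` (the generating
#'   multinomial probabilities, samples x K), and the design settings.
#' @examples
#' sim <- simulate_design(3, seed = 1)
#' sim$truth_features  # "X1" "X2"
#' @export
simulate_design <- function(design = 1, n_samples = 71, n_features = 384,
                            n_classes = 3, relevant_sets = NULL,
                            coef_range = c(0, 2),
                            corr_block = if (design == 1) list(n_features = 20, rho = 0.9) else NULL,
                            assignment = c("logit_argmax", "multinomial"),
                            seed = NULL) {
  assignment <- match.arg(assignment)
  n_samples <- check_count(n_samples, "n_samples", 2L)
  n_features <- check_count(n_features, "n_features", 3L)
  n_classes <- check_count(n_classes, "n_classes", 2L)
  if (is.null(relevant_sets)) relevant_sets <- design_relevant_sets(design)
  if (length(relevant_sets) != n_classes - 1L) {
    abort("`relevant_sets` must have one entry per non-reference class")
  }
  all_rel <- sort(unique(unlist(relevant_sets)))
  if (any(all_rel < 1 | all_rel > n_features)) {
    abort("relevant feature indices out of range")
  }
  if (!is.null(corr_block)) {
    if (corr_block$rho >= 1 || corr_block$rho < 0) abort("`rho` must be in [0, 1)")
  }
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)

  # coefficient sub-stream: one draw per (non-reference class, relevant feature)
  set.seed(sub_seed(seed, 1L))
  coefs <- purrr::imap(relevant_sets, function(idx, cls) {
    tibble::tibble(class = cls, feature_index = idx,
                   feature = paste0("X", idx),
                   beta = runif(length(idx), coef_range[1], coef_range[2]))
  })
  coefs <- dplyr::bind_rows(coefs)

  # feature sub-stream
  set.seed(sub_seed(seed, 2L))
  x <- matrix(rnorm(n_samples * n_features), n_samples, n_features)
  colnames(x) <- paste0("X", seq_len(n_features))

  # correlated irrelevant block sub-stream
  corr_map <- NULL
  if (!is.null(corr_block) && corr_block$n_features > 0) {
    set.seed(sub_seed(seed, 3L))
    irrelevant <- setdiff(seq_len(n_features), all_rel)
    nc <- min(corr_block$n_features, length(irrelevant))
    targets <- sample(irrelevant, nc)
    sources <- sample(all_rel, nc, replace = TRUE)
    rho <- corr_block$rho
    x[, targets] <- rho * x[, sources, drop = FALSE] +
      sqrt(1 - rho^2) * matrix(rnorm(n_samples * nc), n_samples, nc)
    corr_map <- tibble::tibble(feature = paste0("X", targets),
                               source = paste0("X", sources), rho = rho)
  }

  # logits are linear with no intercept; class labels from the multinomial
  logits <- vapply(seq_along(relevant_sets), function(j) {
    b <- coefs[coefs$class == names(relevant_sets)[j], ]
    as.vector(x[, b$feature_index, drop = FALSE] %*% b$beta)
  }, numeric(n_samples))
  probs <- class_probabilities(logits)

  if (assignment == "logit_argmax") {
    y <- apply(cbind(0, logits), 1, which.max)
  } else {
    set.seed(sub_seed(seed, 4L))
    y <- apply(probs, 1, function(p) sample.int(n_classes, 1, prob = p))
  }

  data <- tibble::tibble(sample_id = sprintf("S%02d", seq_len(n_samples)),
                         class = factor(y, levels = seq_len(n_classes)))
  data <- dplyr::bind_cols(data, tibble::as_tibble(x))

  structure(list(
    data = data,
    truth = all_rel,
    truth_features = paste0("X", all_rel),
    coefficients = coefs,
    probabilities = probs,
    logits = logits,
    assignment = assignment,
    design = design,
    n_samples = n_samples, n_features = n_features, n_classes = n_classes,
    corr_map = corr_map,
    seed = seed
  ), class = "radviz_sim")
}

#' @export
print.radviz_sim <- function(x, ...) {
  cat(sprintf("Simulated benchmark (design %s): %d samples x %d features, %d classes\n",
              x$design, x$n_samples, x$n_features, x$n_classes))
  cat("Relevant features:", paste(x$truth_features, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname simulate_design
#' @param x A `radviz_sim` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.radviz_sim <- function(x, ...) x$coefficients
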