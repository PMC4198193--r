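# Independent oracle implementations used to verify the package's fast paths.
# These deliberately take different algorithmic routes than the implementation.

# Brute-force leave-one-out k-NN score: full distance sort per sample,
# distance ties broken by ascending sample index.
oracle_loo_knn <- function(px, py, y, k) {
  n <- length(px)
  y <- as.integer(factor(y))
  contrib <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    d <- sqrt((px[others] - px[i])^2 + (py[others] - py[i])^2)
    nb <- others[order(d, others)][seq_len(k)]
    mean(y[nb] == y[i])
  }, numeric(1))
  100 * mean(contrib)
}

# Average precision by exhaustive threshold enumeration on the PR curve.
oracle_ap <- function(score, positive) {
  th <- sort(unique(score), decreasing = TRUE)
  n_pos <- sum(positive)
  ap <- 0
  rec_prev <- 0
  for (t in th) {
    sel <- score >= t
    prec <- sum(positive & sel) / sum(sel)
    rec <- sum(positive & sel) / n_pos
    ap <- ap + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  ap
}

# ROC AUC by exhaustive enumeration of positive/negative pairs.
oracle_auc <- function(score, positive) {
  ps <- score[positive]
  ns <- score[!positive]
  mean(outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Build a dataset tibble from a plain matrix + labels.
make_dataset <- function(x, y = NULL, prefix = "F") {
  if (is.null(colnames(x))) colnames(x) <- paste0(prefix, seq_len(ncol(x)))
  out <- tibble::tibble(sample_id = sprintf("S%03d", seq_len(nrow(x))))
  if (!is.null(y)) out$class <- factor(y)
  dplyr::bind_cols(out, tibble::as_tibble(x))
}

# Two well-separated Gaussian blobs in feature space.
make_blobs <- function(n_per = 10, p = 3, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  make_dataset(x, rep(c("a", "b"), each = n_per))
}
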