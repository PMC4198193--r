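# Evaluation metrics for multiclass probabilistic classifiers. Ideal values:
# error 0, GBS 0, BCM 1, AUPR 1.

check_posterior <- function(p, y, tol = 1e-6) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (nrow(p) != length(y)) abort("posterior rows and labels differ in length")
  if (any(p < -tol | p > 1 + tol)) abort("posterior entries must lie in [0, 1]")
  if (any(abs(rowSums(p) - 1) > tol)) abort("posterior rows must sum to 1")
  y <- factor(y)
  lev <- colnames(p)
  if (is.null(lev)) {
    if (ncol(p) != nlevels(y)) abort("posterior columns do not match classes")
    colnames(p) <- levels(y)
  } else {
    if (!all(levels(y) %in% lev)) abort("posterior columns do not match classes")
    p <- p[, levels(y), drop = FALSE]
  }
  list(p = p, y = y)
}

#' Misclassification rate in percent
#'
#' @param predicted Predicted class labels, or a posterior matrix (argmax is
#'   taken, probability ties to the smallest class index).
#' @param truth True class labels.
#' @return Percentage of mismatches, `100 * errors / n`.
#' @examples
#' error_rate(c(1, 2, 2), c(1, 2, 1))  # 33.33
#' @export
error_rate <- function(predicted, truth) {
  if (is.matrix(predicted) || is.data.frame(predicted)) {
    predicted <- posterior_classes(as.matrix(predicted))
  }
  if (length(predicted) != length(truth)) abort("length mismatch")
  100 * mean(as.character(predicted) != as.character(truth))
}

#' Generalized Brier score
#'
#' Mean squared distance between the one-hot truth and the posterior vector:
#' `(1/N) sum_i sum_k (delta_ik - p_ik)^2`, ranging from 0 (perfect,
#' confident) to 2 (confidently wrong). In the binary case it equals twice
#' the Brier score of the true-class probability. `halved = TRUE` divides by
#' two for comparability with conventions that include a 1/2 factor.
#'
#' @param posterior Samples x classes probability matrix.
#' @param truth True class labels.
#' @param halved Divide by 2 (default `FALSE`).
#' @return Nonnegative scalar.
#' @export
gbs <- function(posterior, truth, halved = FALSE) {
  ck <- check_posterior(posterior, truth)
  d <- matrix(0, nrow(ck$p), ncol(ck$p))
  d[cbind(seq_len(nrow(ck$p)), as.integer(ck$y))] <- 1
  out <- mean(rowSums((d - ck$p)^2))
  if (halved) out / 2 else out
}

#' Belief confusion metric
#'
#' Macro-averaged posterior belief in the correct class: for each class, the
#' mean posterior probability its members received for it, averaged over
#' classes. 1 is perfect; uniform predictions give `1/K`.
#'
#' @inheritParams gbs
#' @return Scalar in `[0, 1]`.
#' @export
bcm <- function(posterior, truth) {
  ck <- check_posterior(posterior, truth)
  if (any(table(ck$y) == 0)) abort("every class must be present in `truth`")
  mean(vapply(levels(ck$y), function(l) mean(ck$p[ck$y == l, l]), numeric(1)))
}

# Average precision with distance ties handled as blocks: within a tie block
# precision is the block-level precision and recall accrues for the whole
# block, so constant scores yield the prevalence.
average_precision <- function(score, positive) {
  n_pos <- sum(positive)
  if (n_pos == 0) abort("no positives for this class")
  ord <- order(-score)
  score <- score[ord]; positive <- positive[ord]
  blocks <- cumsum(!duplicated(score))
  ap <- 0
  tp <- 0; seen <- 0
  for (b in unique(blocks)) {
    in_b <- blocks == b
    tp_b <- sum(positive[in_b])
    tp <- tp + tp_b
    seen <- seen + sum(in_b)
    if (tp_b > 0) ap <- ap + (tp / seen) * (tp_b / n_pos)
  }
  ap
}

#' Macro-averaged area under the precision-recall curve
#'
#' One-vs-rest per class, using the posterior probability of the class as
#' the ranking score; the per-class area is the average precision (step-wise
#' summation, score ties treated as a single block), and the result is the
#' unweighted mean over classes.
#'
#' @inheritParams gbs
#' @return Scalar in `[0, 1]`.
#' @export
aupr <- function(posterior, truth) {
  ck <- check_posterior(posterior, truth)
  if (any(table(ck$y) == 0)) abort("every class needs at least one positive")
  mean(vapply(levels(ck$y), function(l) {
    average_precision(ck$p[, l], ck$y == l)
  }, numeric(1)))
}

#' Area under the ROC curve (binary)
#'
#' Trapezoidal AUC, computed as the Mann-Whitney U statistic with 0.5 credit
#' for score ties.
#'
#' @param score Real-valued score per sample (higher means more positive).
#' @param truth Binary labels; the second factor level (or `1`) is positive.
#' @return Scalar in `[0, 1]`.
#' @export
roc_auc <- function(score, truth) {
  y <- factor(truth)
  if (nlevels(y) != 2) abort("roc_auc() needs exactly two classes")
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(score)  # mean ranks give the 0.5 tie credit
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pearson correlation between two features
#'
#' @param data Dataset tibble.
#' @param i,j Feature ids (or column indices among the feature columns).
#' @param class_col,id_col Column names.
#' @return Pearson r.
#' @export
feature_correlation <- function(data, i, j, class_col = "class",
                                id_col = "sample_id") {
  parts <- split_dataset(data, class_col, id_col, require_class = FALSE)
  if (is.numeric(i)) i <- parts$feature_ids[i]
  if (is.numeric(j)) j <- parts$feature_ids[j]
  a <- parts$x[, i]; b <- parts$x[, j]
  if (sd(a) == 0 || sd(b) == 0) abort("feature correlation undefined for a constant feature")
  cor(a, b)
}

#' All four evaluation metrics at once
#'
#' @inheritParams gbs
#' @param gbs_halved Use the halved Brier convention.
#' @return One-row tibble: `error_pct`, `gbs`, `bcm`, `aupr`.
#' @export
evaluate_classifier <- function(posterior, truth, gbs_halved = FALSE) {
  tibble::tibble(
    error_pct = error_rate(posterior, truth),
    gbs = gbs(posterior, truth, halved = gbs_halved),
    bcm = bcm(posterior, truth),
    aupr = aupr(posterior, truth)
  )
}
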