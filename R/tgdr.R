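# Threshold gradient descent regularization for (multinomial) logistic
# regression. Coefficients start at zero and follow the gradient of the mean
# log-likelihood; at each step only coefficients whose gradient magnitude is
# within a factor tau of the largest are moved, which produces sparse models.
# The intercepts are always updated and never thresholded.

mean_loglik <- function(eta, yind) {
  p <- class_probabilities(eta)
  ycol <- cbind(1 - rowSums(yind), yind)  # reference class indicator first
  mean(log(pmax(rowSums(p * ycol), .Machine$double.xmin)))
}

tgdr_engine <- function(x, yind, tau, delta_nu, k_iters, variant,
                        snapshot_at = NULL) {
  n <- nrow(x); p <- ncol(x); km1 <- ncol(yind)
  beta <- matrix(0, p, km1)
  intercept <- rep(0, km1)
  snaps <- list()
  ll <- numeric(k_iters)
  ycol <- cbind(1 - rowSums(yind), yind)  # reference indicator first
  for (step in seq_len(k_iters)) {
    eta <- sweep(x %*% beta, 2, intercept, "+")
    prob <- class_probabilities(eta)
    # eta belongs to the parameters left by the previous step
    if (step > 1L) {
      ll[step - 1L] <- mean(log(pmax(rowSums(prob * ycol), .Machine$double.xmin)))
    }
    resid <- yind - prob[, -1, drop = FALSE]
    g_int <- colMeans(resid)
    g <- crossprod(x, resid) / n
    if (tau > 0) {
      ag <- abs(g)
      if (variant == "multi_global") {
        srow <- apply(ag, 1, max)
        f <- matrix(srow >= tau * max(srow), p, km1)
      } else {
        cmax <- apply(ag, 2, max)
        f <- sweep(ag, 2, tau * cmax, ">=")
      }
      g <- g * f
    }
    beta <- beta + delta_nu * g
    intercept <- intercept + delta_nu * g_int
    if (!is.null(snapshot_at) && step %in% snapshot_at) {
      snaps[[as.character(step)]] <- list(beta = beta, intercept = intercept)
    }
  }
  if (k_iters > 0L) {
    ll[k_iters] <- mean_loglik(sweep(x %*% beta, 2, intercept, "+"), yind)
  }
  list(beta = beta, intercept = intercept, ll_trace = ll, snapshots = snaps)
}

tgdr_prepare <- function(data, class_col, id_col, standardize) {
  parts <- split_dataset(data, class_col, id_col)
  stats <- NULL
  x <- parts$x
  if (standardize) {
    std <- standardize(data, class_col = class_col, id_col = id_col)
    stats <- attr(std, "stats")
    x <- split_dataset(std, class_col, id_col)$x
  }
  yind <- vapply(levels(parts$y)[-1], function(l) as.numeric(parts$y == l),
                 numeric(nrow(x)))
  yind <- matrix(yind, nrow = nrow(x),
                 dimnames = list(NULL, levels(parts$y)[-1]))
  list(x = x, y = parts$y, yind = yind, stats = stats,
       feature_ids = parts$feature_ids)
}

new_tgdr <- function(fit, prep, tau, delta_nu, k_iters, variant) {
  beta <- fit$beta
  dimnames(beta) <- list(prep$feature_ids, levels(prep$y)[-1])
  structure(list(
    coefficients = beta,
    intercepts = setNames(fit$intercept, levels(prep$y)[-1]),
    classes = levels(prep$y),
    tau = tau, delta_nu = delta_nu, k_iters = k_iters, variant = variant,
    standardize_stats = prep$stats,
    feature_ids = prep$feature_ids,
    ll_trace = fit$ll_trace
  ), class = "radviz_tgdr")
}

check_tgdr_params <- function(tau, delta_nu, k_iters) {
  if (tau < 0 || tau > 1) abort("`tau` must be in [0, 1]")
  if (delta_nu <= 0) abort("`delta_nu` must be positive")
  check_count(k_iters, "k_iters", 0L)
}

#' Fit a binary TGDR logistic model
#'
#' Threshold gradient descent regularization: gradient ascent on the mean
#' logistic log-likelihood starting from zero coefficients, where at each of
#' `k_iters` steps only coefficients with gradient magnitude at least
#' `tau * max_j |g_j|` move by `delta_nu * g_j`. The intercept is always
#' updated and never thresholded. `tau = 0` is plain gradient ascent (all
#' coefficients move); `tau = 1` moves only the steepest coefficient(s) per
#' step. Features with nonzero coefficients after `k_iters` steps are the
#' selected set.
#'
#' @param data Dataset tibble with a two-level class column.
#' @param class_col,id_col Column names.
#' @param tau Threshold in `[0, 1]`.
#' @param delta_nu Step size (default 0.01).
#' @param k_iters Number of gradient steps (choose by [cv_select_k()]).
#' @param standardize Z-score features on the training data (default `TRUE`;
#'   statistics are stored and reused at prediction time).
#' @return A `radviz_tgdr` model.
#' @export
fit_tgdr <- function(data, class_col = "class", id_col = "sample_id",
                     tau = 0, delta_nu = 0.01, k_iters = 100,
                     standardize = TRUE) {
  k_iters <- check_tgdr_params(tau, delta_nu, k_iters)
  prep <- tgdr_prepare(data, class_col, id_col, standardize)
  if (nlevels(prep$y) != 2) abort("fit_tgdr() needs a binary class; use fit_multi_tgdr()")
  fit <- tgdr_engine(prep$x, prep$yind, tau, delta_nu, k_iters, "binary")
  new_tgdr(fit, prep, tau, delta_nu, k_iters, "binary")
}

#' Fit a multiclass (multi-)TGDR model
#'
#' Multinomial logit with the first class level as reference, fitted by
#' thresholded gradient ascent. The gradient is a features-by-classes
#' matrix `G`; the `multi_local` variant thresholds each entry against
#' `tau` times the largest magnitude in the same class (column), while
#' `multi_global` summarises each feature by its largest magnitude across
#' classes and thresholds whole feature rows. With two classes either
#' variant reduces exactly to [fit_tgdr()]; with `tau = 0` the two variants
#' coincide.
#'
#' @inheritParams fit_tgdr
#' @param variant `"multi_global"` or `"multi_local"`.
#' @return A `radviz_tgdr` model.
#' @export
fit_multi_tgdr <- function(data, class_col = "class", id_col = "sample_id",
                           tau = 0, delta_nu = 0.01, k_iters = 100,
                           variant = c("multi_global", "multi_local"),
                           standardize = TRUE) {
  variant <- match.arg(variant)
  k_iters <- check_tgdr_params(tau, delta_nu, k_iters)
  prep <- tgdr_prepare(data, class_col, id_col, standardize)
  fit <- tgdr_engine(prep$x, prep$yind, tau, delta_nu, k_iters, variant)
  new_tgdr(fit, prep, tau, delta_nu, k_iters, variant)
}

#' Features with nonzero TGDR coefficients
#' @param model A `radviz_tgdr` model.
#' @return Character vector of selected feature ids.
#' @export
selected_features <- function(model) {
  model$feature_ids[rowSums(abs(model$coefficients)) > 0]
}

#' Choose the TGDR iteration count by cross-validation
#'
#' Stratified `folds`-fold cross-validation: each candidate `k` in `k_grid`
#' is scored by the mean held-out log-likelihood of the model stopped at `k`
#' steps (one fit per fold up to `max(k_grid)`, snapshotting along the
#' trajectory). Returns the `k` with the best mean held-out log-likelihood;
#' ties go to the smaller `k`.
#'
#' @inheritParams fit_multi_tgdr
#' @param folds Number of CV folds (default 5).
#' @param k_grid Candidate iteration counts.
#' @param seed Seed for the fold assignment.
#' @return List: `k` (the selection), `cv` (tibble of mean held-out
#'   log-likelihood per candidate).
#' @export
cv_select_k <- function(data, class_col = "class", id_col = "sample_id",
                        tau = 0, delta_nu = 0.01, folds = 5,
                        k_grid = c(25, 50, 100, 200, 400),
                        variant = c("multi_global", "multi_local"),
                        standardize = TRUE, seed = NULL) {
  variant <- match.arg(variant)
  folds <- check_count(folds, "folds", 2L)
  k_grid <- sort(unique(as.integer(k_grid)))
  parts <- split_dataset(data, class_col, id_col)
  if (any(table(parts$y) < folds)) {
    abort("every class needs at least `folds` samples for stratified CV")
  }
  if (!is.null(seed)) set.seed(seed)
  fold_id <- integer(nrow(data))
  for (lev in levels(parts$y)) {
    idx <- which(parts$y == lev)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  ll <- matrix(NA_real_, folds, length(k_grid))
  for (f in seq_len(folds)) {
    train <- data[fold_id != f, , drop = FALSE]
    test <- data[fold_id == f, , drop = FALSE]
    prep <- tgdr_prepare(train, class_col, id_col, standardize)
    fit <- tgdr_engine(prep$x, prep$yind, tau, delta_nu, max(k_grid), variant,
                       snapshot_at = k_grid)
    test_parts <- split_dataset(test, class_col, id_col)
    xt <- test_parts$x[, prep$feature_ids, drop = FALSE]
    if (standardize) {
      st <- prep$stats
      xt <- sweep(sweep(xt, 2, st$mean, "-"), 2, ifelse(st$sd > 0, st$sd, 1), "/")
    }
    yt <- factor(test_parts$y, levels = levels(prep$y))
    ytind <- vapply(levels(prep$y)[-1], function(l) as.numeric(yt == l),
                    numeric(nrow(xt)))
    ytind <- matrix(ytind, nrow = nrow(xt))
    for (j in seq_along(k_grid)) {
      s <- fit$snapshots[[as.character(k_grid[j])]]
      eta <- sweep(xt %*% s$beta, 2, s$intercept, "+")
      ll[f, j] <- mean_loglik(eta, ytind)
    }
  }
  cv <- tibble::tibble(k = k_grid, mean_loglik = colMeans(ll))
  best <- cv$k[which.max(cv$mean_loglik)]
  list(k = best, cv = cv)
}

#' @export
print.radviz_tgdr <- function(x, ...) {
  cat(sprintf("TGDR model (%s): %d classes, %d/%d features selected (tau = %g, k = %d)\n",
              x$variant, length(x$classes), length(selected_features(x)),
              length(x$feature_ids), x$tau, x$k_iters))
  invisible(x)
}

#' @rdname fit_multi_tgdr
#' @param x A `radviz_tgdr` model.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.radviz_tgdr <- function(x, ...) {
  out <- tibble::as_tibble(x$coefficients)
  out <- dplyr::mutate(out, term = x$feature_ids, .before = 1)
  tidyr::pivot_longer(out, -"term", names_to = "class",
                      values_to = "estimate")
}

#' @rdname fit_multi_tgdr
#' @exportS3Method generics::glance
glance.radviz_tgdr <- function(x, ...) {
  tibble::tibble(n_selected = length(selected_features(x)),
                 n_features = length(x$feature_ids),
                 tau = x$tau, delta_nu = x$delta_nu, k_iters = x$k_iters,
                 variant = x$variant,
                 train_loglik = x$ll_trace[length(x$ll_trace)])
}
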