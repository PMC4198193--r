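#' Posterior class probabilities
#'
#' Unified prediction surface for the classifiers in this package. Every
#' method returns a samples-by-classes matrix of posterior probabilities
#' whose rows sum to 1, the input every evaluation metric consumes.
#'
#' @param model A fitted `radviz_tgdr`, `radviz_nb` or `radviz_svm` model.
#' @param data Dataset tibble with the training feature columns (a class
#'   column, if present, is ignored).
#' @param ... Passed to methods.
#' @return Numeric matrix, samples x classes, columns named by class level.
#' @export
predict_proba <- function(model, data, ...) UseMethod("predict_proba")

model_matrix <- function(model, data, class_col = "class", id_col = "sample_id") {
  parts <- split_dataset(data, class_col, id_col, require_class = FALSE)
  missing <- setdiff(model$feature_ids, parts$feature_ids)
  if (length(missing)) {
    abort(paste0("feature missing from prediction data: ", missing[1]))
  }
  parts$x[, model$feature_ids, drop = FALSE]
}

#' @rdname predict_proba
#' @export
predict_proba.radviz_tgdr <- function(model, data, ...) {
  x <- model_matrix(model, data)
  if (!is.null(model$standardize_stats)) {
    st <- model$standardize_stats
    x <- sweep(sweep(x, 2, st$mean, "-"), 2, ifelse(st$sd > 0, st$sd, 1), "/")
  }
  eta <- sweep(x %*% model$coefficients, 2, model$intercepts, "+")
  p <- class_probabilities(eta)
  colnames(p) <- model$classes
  rownames(p) <- rownames(x)
  p
}

#' @export
predict.radviz_tgdr <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else posterior_classes(p)
}

#' Gaussian naive Bayes classifier
#'
#' Class-conditional densities are products of univariate Gaussians (the
#' independence assumption), with per-class feature means and variances
#' estimated on the training data (variances floored at 1e-9) and class
#' priors from the training frequencies. Posteriors follow from Bayes' rule,
#' computed in log space.
#'
#' @param data Training dataset tibble with a class column.
#' @param class_col,id_col Column names.
#' @param var_floor Lower bound on the per-class variances.
#' @return A `radviz_nb` model.
#' @export
fit_nb <- function(data, class_col = "class", id_col = "sample_id",
                   var_floor = 1e-9) {
  parts <- split_dataset(data, class_col, id_col)
  y <- parts$y
  mu <- lapply(levels(y), function(l) colMeans(parts$x[y == l, , drop = FALSE]))
  v <- lapply(levels(y), function(l) {
    vv <- apply(parts$x[y == l, , drop = FALSE], 2, function(col) {
      if (length(col) < 2) 0 else stats::var(col)
    })
    pmax(vv, var_floor)
  })
  structure(list(
    classes = levels(y),
    prior = as.vector(table(y) / length(y)),
    mean = do.call(rbind, mu),
    var = do.call(rbind, v),
    feature_ids = parts$feature_ids
  ), class = "radviz_nb")
}

#' @rdname predict_proba
#' @export
predict_proba.radviz_nb <- function(model, data, ...) {
  x <- model_matrix(model, data)
  k <- length(model$classes)
  loglik <- vapply(seq_len(k), function(c) {
    mu <- model$mean[c, ]; v <- model$var[c, ]
    rowSums(-0.5 * log(2 * pi * matrix(v, nrow(x), ncol(x), byrow = TRUE)) -
              0.5 * sweep(x, 2, mu, "-")^2 %*% diag(1 / v, ncol(x)))
  }, numeric(nrow(x)))
  loglik <- matrix(loglik, nrow = nrow(x))
  logpost <- sweep(loglik, 2, log(model$prior), "+")
  logpost <- logpost - apply(logpost, 1, max)
  p <- exp(logpost) / rowSums(exp(logpost))
  colnames(p) <- model$classes
  rownames(p) <- rownames(x)
  p
}

#' @export
predict.radviz_nb <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else posterior_classes(p)
}

#' Support vector machine with calibrated probabilities
#'
#' Thin wrapper around [e1071::svm()] (linear kernel by default,
#' `probability = TRUE` so decision values are calibrated to posterior
#' probabilities) presenting the same `predict_proba()` surface as the other
#' classifiers.
#'
#' @param data Training dataset tibble with a class column.
#' @param class_col,id_col Column names.
#' @param kernel Kernel name passed to [e1071::svm()] (default `"linear"`).
#' @param cost Soft-margin cost.
#' @param ... Further arguments to [e1071::svm()].
#' @return A `radviz_svm` model.
#' @export
fit_svm <- function(data, class_col = "class", id_col = "sample_id",
                    kernel = "linear", cost = 1, ...) {
  parts <- split_dataset(data, class_col, id_col)
  fit <- e1071::svm(parts$x, parts$y, kernel = kernel, cost = cost,
                    probability = TRUE, ...)
  structure(list(fit = fit, classes = levels(parts$y),
                 feature_ids = parts$feature_ids),
            class = "radviz_svm")
}

#' @rdname predict_proba
#' @export
predict_proba.radviz_svm <- function(model, data, ...) {
  x <- model_matrix(model, data)
  pred <- predict(model$fit, x, probability = TRUE)
  p <- attr(pred, "probabilities")
  p <- p[, model$classes, drop = FALSE]  # e1071 orders columns arbitrarily
  rownames(p) <- rownames(x)
  p
}

#' @export
predict.radviz_svm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else posterior_classes(p)
}

#' Hard class labels from a posterior matrix
#'
#' Argmax per row; probability ties go to the smallest class index.
#'
#' @param posterior Samples x classes probability matrix (named columns).
#' @return Factor of predicted class labels.
#' @export
posterior_classes <- function(posterior) {
  idx <- apply(posterior, 1, which.max)  # which.max takes the first maximum
  lev <- colnames(posterior)
  if (is.null(lev)) lev <- as.character(seq_len(ncol(posterior)))
  factor(lev[idx], levels = lev)
}
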