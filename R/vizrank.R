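#' Score a 2-D layout by leave-one-out k-NN class separation
#'
#' The VizRank score of a projection: for each sample, the predicted
#' probability of its true class is the fraction of its `k` nearest other
#' samples (Euclidean distance in the layout; distance ties broken by
#' ascending sample index) sharing that class. The score is 100 times the
#' mean over samples, so it lies in `[0, 100]`.
#'
#' @param layout A `radviz_layout` tibble (or any data frame with `x`, `y`
#'   columns).
#' @param y Class labels; taken from `layout$class` when omitted.
#' @param k Number of neighbours; default `round(sqrt(n_samples))`.
#' @return A single score in `[0, 100]`.
#' @export
score_projection <- function(layout, y = NULL, k = NULL) {
  if (is.null(y)) {
    if (!"class" %in% names(layout)) abort("supply `y` or a layout with a class column")
    y <- layout$class
  }
  y <- factor(y)
  n <- nrow(layout)
  if (length(y) != n) abort("`layout` and `y` lengths differ")
  if (is.null(k)) k <- max(1L, as.integer(round(sqrt(n))))
  k <- check_count(k, "k")
  if (k >= n) abort("k must be smaller than the number of samples")
  score_layout_cpp(layout$x, layout$y, class_codes(y), k)
}

#' Rank features by signal-to-noise ratio
#'
#' Binary SNR of feature j: `|mean_1 - mean_2| / (sd_1 + sd_2)` (sample
#' standard deviations). For more than two classes the SNR is the maximum of
#' the binary formula over one-vs-rest splits. A zero numerator gives SNR 0;
#' a perfect separator (positive numerator, zero denominator) gets `Inf` and
#' ranks first. Ties are broken by ascending feature index.
#'
#' @param data Dataset tibble with a class column and numeric features.
#' @param class_col,id_col Column names.
#' @return Tibble `feature`, `index` (column position), `snr`, `rank`,
#'   sorted by rank.
#' @export
snr_rank <- function(data, class_col = "class", id_col = "sample_id") {
  parts <- split_dataset(data, class_col, id_col)
  x <- parts$x
  y <- parts$y
  if (any(table(y) < 2)) abort("every class needs >= 2 samples for SNR")
  snr <- rep(0, ncol(x))
  for (lev in levels(y)) {
    inl <- y == lev
    mu_d <- abs(colMeans(x[inl, , drop = FALSE]) - colMeans(x[!inl, , drop = FALSE]))
    s_sum <- apply(x[inl, , drop = FALSE], 2, sd) + apply(x[!inl, , drop = FALSE], 2, sd)
    s <- ifelse(mu_d == 0, 0, ifelse(s_sum == 0, Inf, mu_d / s_sum))
    snr <- pmax(snr, s)
  }
  ord <- order(-snr, seq_along(snr))
  tibble::tibble(feature = parts$feature_ids[ord], index = ord,
                 snr = snr[ord], rank = seq_along(ord))
}

# exp(-rank/sigma) sampling weights in feature-column order
snr_sampling_weights <- function(snr_tbl, n_features, sigma = NULL) {
  if (is.null(sigma)) sigma <- max(10, n_features / 20)
  w <- numeric(n_features)
  w[snr_tbl$index] <- exp(-snr_tbl$rank / sigma)
  w
}

# All circular anchor orders of m features distinct up to rotation and
# reflection: anchor 1 fixed at position 1; reflections removed by requiring
# the second entry to precede the last. (m-1)!/2 orders; 0-based for C++.
circular_orders <- function(m) {
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perms(v[-i]))
    }))
  }
  p <- perms(seq_len(m - 1L))
  if (m > 3) p <- p[p[, 1] < p[, m - 1L], , drop = FALSE]
  if (m == 3) p <- p[p[, 1] < p[, 2], , drop = FALSE]
  cbind(0L, p)
}

random_orders <- function(m, n_orders) {
  t(vapply(seq_len(n_orders), function(i) c(0L, sample.int(m - 1L)),
           integer(m)))
}

# ordered top-list insert; keeps parallel score vector and index list sorted
# by descending score
top_insert <- function(top, scores, idx_list) {
  for (i in seq_along(scores)) {
    pos <- sum(top$scores > scores[i])
    top$scores <- append(top$scores, scores[i], after = pos)
    top$idx <- append(top$idx, idx_list[i], after = pos)
  }
  if (length(top$scores) > top$capacity) {
    keep <- seq_len(top$capacity)
    top$scores <- top$scores[keep]
    top$idx <- top$idx[keep]
  }
  top
}

#' Heuristic search over RadViz projections
#'
#' Searches the space of (feature subset, anchor order) projections for the
#' arrangement with the best class separation. Each round draws a subset
#' size uniformly from `3..max_features`, draws that many distinct features
#' with probability decaying exponentially in SNR rank (weight
#' `exp(-rank / sigma)`, `sigma = max(10, n_features / 20)`), and scores
#' anchor arrangements of the subset: all `(m-1)!/2` circular orders distinct
#' up to rotation/reflection when `m <= 6`, else `perm_cap` randomly sampled
#' orders. Every scored (subset, order) pair counts as one evaluated
#' projection; the search stops once `budget` projections have been
#' evaluated. Features are min-max normalized internally.
#'
#' @param data Dataset tibble with a class column and numeric features.
#' @param class_col,id_col Column names.
#' @param max_features Largest subset size (>= 3).
#' @param budget Minimum number of projections to evaluate (default 50000).
#' @param k Neighbours for the score; default `round(sqrt(n_samples))`.
#' @param seed Integer seed; the same seed reproduces the search exactly.
#' @param top_capacity How many best projections to retain (default 1000).
#' @param perm_cap Sampled anchor orders per subset when `m >= 7`.
#' @param sigma Decay scale of the SNR rank bias (default
#'   `max(10, n_features / 20)`).
#' @return A `vizrank_result`: list with `top` (tibble of retained
#'   projections: `score`, `m`, `features` list-column in anchor order),
#'   `frequency` (per-feature appearance counts over all evaluated
#'   projections), `evaluated_count`, and the search settings.
#' @export
vizrank_search <- function(data, class_col = "class", id_col = "sample_id",
                           max_features = 8, budget = 50000, k = NULL,
                           seed = NULL, top_capacity = 1000, perm_cap = 60,
                           sigma = NULL) {
  budget <- check_count(budget, "budget")
  max_features <- check_count(max_features, "max_features", 3L)
  parts <- split_dataset(data, class_col, id_col)
  p <- ncol(parts$x)
  if (max_features > p) abort("max_features exceeds the number of features")
  norm <- normalize_features(data, class_col = class_col, id_col = id_col)
  xn <- split_dataset(norm, class_col, id_col)$x
  y0 <- class_codes(parts$y)
  n <- nrow(xn)
  if (is.null(k)) k <- max(1L, as.integer(round(sqrt(n))))
  k <- check_count(k, "k")

  snr <- snr_rank(data, class_col, id_col)
  wts <- snr_sampling_weights(snr, p, sigma)

  order_cache <- lapply(3:min(max_features, 6), circular_orders)

  if (!is.null(seed)) set.seed(seed)
  freq <- integer(p)
  evaluated <- 0L
  top <- list(scores = numeric(0), idx = list(), capacity = top_capacity)
  sizes <- 3:max_features
  while (evaluated < budget) {
    m <- if (length(sizes) == 1) sizes else sample(sizes, 1)
    subset <- sample.int(p, m, prob = wts)
    orders <- if (m <= 6) order_cache[[m - 2L]] else random_orders(m, perm_cap)
    scores <- eval_orders_cpp(xn[, subset, drop = FALSE], orders, y0, k)
    q <- length(scores)
    evaluated <- evaluated + q
    freq[subset] <- freq[subset] + q
    # only candidates that can enter the retained list are inserted
    floor_score <- if (length(top$scores) >= top$capacity) top$scores[top$capacity] else -Inf
    cand <- which(scores > floor_score)
    if (length(cand)) {
      idx_list <- lapply(cand, function(r) subset[orders[r, ] + 1L])
      top <- top_insert(top, scores[cand], idx_list)
    }
  }

  new_vizrank_result(top, freq, evaluated, parts, k, max_features, budget,
                     seed, snr, wts, attr(norm, "scaling"), perm_cap)
}

new_vizrank_result <- function(top, freq, evaluated, parts, k, max_features,
                               budget, seed, snr, wts, scaling, perm_cap) {
  feature_ids <- parts$feature_ids
  top_tbl <- tibble::tibble(
    score = top$scores,
    m = vapply(top$idx, length, integer(1)),
    features = lapply(top$idx, function(i) feature_ids[i])
  )
  frequency <- tibble::tibble(feature = feature_ids,
                              index = seq_along(feature_ids),
                              count = freq)
  frequency <- frequency[order(-frequency$count, frequency$index), ]
  frequency$rank <- seq_len(nrow(frequency))
  structure(list(
    top = top_tbl, frequency = frequency, evaluated_count = evaluated,
    k = k, max_features = max_features, budget = budget, seed = seed,
    snr = snr, feature_ids = feature_ids, scaling = scaling,
    perm_cap = perm_cap, top_idx = top$idx, sampling_weights = wts
  ), class = "vizrank_result")
}

#' @export
print.vizrank_result <- function(x, ...) {
  cat(sprintf("VizRank search: %d projections evaluated (k = %d, max features %d)\n",
              x$evaluated_count, x$k, x$max_features))
  if (nrow(x$top)) {
    cat(sprintf("Best projection (score %.2f): %s\n", x$top$score[1],
                paste(x$top$features[[1]], collapse = ", ")))
  }
  invisible(x)
}

#' @rdname vizrank_search
#' @param x A `vizrank_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.vizrank_result <- function(x, ...) {
  dplyr::mutate(x$top, rank = dplyr::row_number(), .before = 1)
}

#' @rdname vizrank_search
#' @exportS3Method generics::glance
glance.vizrank_result <- function(x, ...) {
  tibble::tibble(best_score = if (nrow(x$top)) x$top$score[1] else NA_real_,
                 best_m = if (nrow(x$top)) x$top$m[1] else NA_integer_,
                 evaluated_count = x$evaluated_count,
                 k = x$k, max_features = x$max_features)
}

#' Hill-climbing refinement of the best projections
#'
#' Runs `iterations` local moves. Each iteration picks a parent uniformly
#' from the current top `top_pool` projections and applies one random move:
#' (a) swap two anchor positions, (b) replace one feature by an SNR-rank
#' biased draw, or (c) add or remove one feature (respecting
#' `3 <= m <= max_features`). The mutant is scored and retained in the top
#' list only if it strictly improves on its parent. All evaluations update
#' the evaluated-projection count and the feature frequency table.
#'
#' @param result A `vizrank_result` from [vizrank_search()].
#' @param data The same dataset the search ran on.
#' @param iterations Number of local moves (default 10000).
#' @param seed Integer seed.
#' @param top_pool Size of the parent pool (default 20).
#' @param class_col,id_col Column names.
#' @return An updated `vizrank_result`.
#' @export
local_optimize <- function(result, data, iterations = 10000, seed = NULL,
                           top_pool = 20, class_col = "class",
                           id_col = "sample_id") {
  if (!inherits(result, "vizrank_result")) abort("`result` must be a vizrank_result")
  if (!length(result$top_idx)) abort("`result` holds no projections to optimize")
  iterations <- check_count(iterations, "iterations", 0L)
  parts <- split_dataset(data, class_col, id_col)
  norm <- normalize_features(data, scaling = result$scaling,
                             class_col = class_col, id_col = id_col)
  xn <- split_dataset(norm, class_col, id_col)$x[, result$feature_ids, drop = FALSE]
  y0 <- class_codes(parts$y)
  p <- length(result$feature_ids)
  wts <- result$sampling_weights
  k <- result$k
  max_features <- result$max_features

  if (!is.null(seed)) set.seed(seed)
  top <- list(scores = result$top$score, idx = result$top_idx,
              capacity = max(length(result$top_idx), 1000L))
  freq <- integer(p)
  freq[result$frequency$index] <- result$frequency$count
  evaluated <- result$evaluated_count

  draw_feature <- function(exclude) {
    w <- wts
    w[exclude] <- 0
    sample.int(p, 1, prob = w)
  }

  for (it in seq_len(iterations)) {
    pool <- min(top_pool, length(top$scores))
    pi_ <- if (pool == 1) 1L else sample.int(pool, 1)
    parent <- top$idx[[pi_]]
    parent_score <- top$scores[pi_]
    m <- length(parent)
    mutant <- parent
    move <- sample.int(3L, 1)
    if (move == 1L) {                      # swap two anchors
      sw <- sample.int(m, 2)
      mutant[sw] <- mutant[rev(sw)]
    } else if (move == 2L) {               # replace one feature
      pos <- sample.int(m, 1)
      mutant[pos] <- draw_feature(parent)
    } else {                               # add or remove one feature
      can_add <- m < max_features
      can_remove <- m > 3L
      add <- if (can_add && can_remove) runif(1) < 0.5 else can_add
      if (add) {
        newf <- draw_feature(parent)
        at <- sample.int(m + 1L, 1)
        mutant <- append(parent, newf, after = at - 1L)
      } else {
        mutant <- parent[-sample.int(m, 1)]
      }
    }
    sc <- eval_orders_cpp(xn[, mutant, drop = FALSE],
                          matrix(seq_along(mutant) - 1L, nrow = 1), y0, k)
    evaluated <- evaluated + 1L
    freq[mutant] <- freq[mutant] + 1L
    if (sc > parent_score) top <- top_insert(top, sc, list(mutant))
  }

  out <- new_vizrank_result(top, freq, evaluated, parts, k, max_features,
                            result$budget, result$seed, result$snr, wts,
                            result$scaling, result$perm_cap)
  out$optimize_iterations <- iterations
  out
}
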