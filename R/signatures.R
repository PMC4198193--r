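#' Best projection across several search runs
#'
#' Typically the search is repeated with the maximum subset size varied (e.g.
#' 3 to 8) and the single highest-scoring projection across all runs is the
#' reported gene signature. Score ties are broken in favour of the smaller
#' projection, then by lexicographic feature ids.
#'
#' @param results A list of `vizrank_result` objects (or a single one).
#' @return One-row tibble: `score`, `m`, `features` (list-column, anchor
#'   order), `max_features` (which run won).
#' @export
best_projection <- function(results) {
  if (inherits(results, "vizrank_result")) results <- list(results)
  rows <- purrr::map_dfr(results, function(r) {
    if (!nrow(r$top)) return(tibble::tibble())
    dplyr::mutate(r$top[1, ], max_features = r$max_features)
  })
  if (!nrow(rows)) abort("all search results are empty")
  key <- vapply(rows$features, function(f) paste(sort(f), collapse = "|"), character(1))
  rows[order(-rows$score, rows$m, key), ][1, ]
}

#' Frequency ranking truncated at the last true relevant feature
#'
#' Features are ranked by how often they appeared in evaluated projections
#' (descending count, ties by ascending feature index) and the ranking is cut
#' at the last member of `truth` to appear — the prefix a practitioner would
#' read off as the recovered signature. If some member of `truth` never
#' appears in the table the full ranking is returned and flagged incomplete.
#'
#' @param x A `vizrank_result` or its `frequency` tibble (columns `feature`,
#'   `index`, `count`).
#' @param truth Character vector of truly relevant feature ids (or integer
#'   indices).
#' @return List of class `signature_prefix`: `features` (the prefix, in rank
#'   order), `length`, `complete` (all of `truth` appeared with positive
#'   count), `ranking` (the full ranked table).
#' @export
frequency_truncate <- function(x, truth) {
  tbl <- if (inherits(x, "vizrank_result")) x$frequency else tibble::as_tibble(x)
  if (!length(truth)) abort("`truth` must be non-empty")
  tbl <- tbl[order(-tbl$count, tbl$index), ]
  tbl$rank <- seq_len(nrow(tbl))
  truth_f <- if (is.numeric(truth)) tbl$feature[match(truth, tbl$index)] else as.character(truth)
  pos <- match(truth_f, tbl$feature)
  appeared <- !is.na(pos) & tbl$count[pos] > 0
  complete <- all(appeared)
  feats <- if (complete) tbl$feature[seq_len(max(pos))] else tbl$feature
  structure(list(features = feats, length = length(feats),
                 complete = complete, ranking = tbl),
            class = "signature_prefix")
}

#' @export
print.signature_prefix <- function(x, ...) {
  cat(sprintf("Frequency-ranked signature prefix (%d features%s):\n%s\n",
              x$length, if (x$complete) "" else "; some true features never appeared",
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Directional signature from the frequency ranking
#'
#' Walks the frequency ranking and classifies each feature as over-expressed
#' in one of two groups by the sign of the mean difference on the training
#' data, collecting the first `n_up` features higher in the first group and
#' the first `n_down` higher in the second.
#'
#' @param x A `vizrank_result` or frequency tibble.
#' @param data Training dataset tibble.
#' @param groups A two-level factor/vector over the samples (e.g. the class
#'   labels of a binary problem), or the name of a two-level column of
#'   `data`.
#' @param n_up,n_down How many features over-expressed in the first / second
#'   level to collect.
#' @param id_col Sample-id column name.
#' @return Tibble: `feature`, `rank`, `direction` (first or second level),
#'   `mean_diff`.
#' @export
directional_signature <- function(x, data, groups, n_up, n_down,
                                  id_col = "sample_id") {
  n_up <- check_count(n_up, "n_up", 0L)
  n_down <- check_count(n_down, "n_down", 0L)
  tbl <- if (inherits(x, "vizrank_result")) x$frequency else tibble::as_tibble(x)
  tbl <- tbl[order(-tbl$count, tbl$index), ]
  if (is.character(groups) && length(groups) == 1) groups <- data[[groups]]
  g <- factor(groups)
  if (nlevels(g) != 2) abort("`groups` must have exactly two levels")
  parts <- split_dataset(data, class_col = "class", id_col = id_col,
                         require_class = FALSE)
  out <- tibble::tibble(feature = character(), rank = integer(),
                        direction = character(), mean_diff = numeric())
  got_up <- 0L; got_down <- 0L
  for (r in seq_len(nrow(tbl))) {
    if (got_up >= n_up && got_down >= n_down) break
    f <- tbl$feature[r]
    if (!f %in% parts$feature_ids) next
    d <- mean(parts$x[g == levels(g)[1], f]) - mean(parts$x[g == levels(g)[2], f])
    if (d > 0 && got_up < n_up) {
      got_up <- got_up + 1L
      out <- dplyr::add_row(out, feature = f, rank = r,
                            direction = levels(g)[1], mean_diff = d)
    } else if (d < 0 && got_down < n_down) {
      got_down <- got_down + 1L
      out <- dplyr::add_row(out, feature = f, rank = r,
                            direction = levels(g)[2], mean_diff = d)
    }
  }
  if (got_up < n_up || got_down < n_down) {
    abort("frequency ranking exhausted before the directional quota was filled")
  }
  out
}
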