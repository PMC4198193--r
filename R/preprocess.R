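#' Z-score features on the training scale
#'
#' Per-feature standardization to mean 0, variance 1 (sample standard
#' deviation). Constant features cannot be scaled: they are centred at 0 and
#' flagged in the stored statistics. When a `stats` table from a previous
#' (training) call is supplied, its means and standard deviations are used,
#' so test samples are transformed on the training scale.
#'
#' @param data Dataset tibble with numeric feature columns.
#' @param stats Optional statistics table from a previous call (the
#'   `"stats"` attribute of its result).
#' @param class_col,id_col Column names passed through untouched.
#' @return The tibble with standardized features; attribute `"stats"` holds
#'   a tibble `feature`, `mean`, `sd`, `constant`.
#' @export
standardize <- function(data, stats = NULL, class_col = "class",
                        id_col = "sample_id") {
  parts <- split_dataset(data, class_col, id_col, require_class = FALSE)
  x <- parts$x
  if (is.null(stats)) {
    mu <- colMeans(x)
    s <- apply(x, 2, sd)
    stats <- tibble::tibble(feature = parts$feature_ids, mean = mu, sd = s,
                            constant = s == 0)
    if (any(stats$constant)) {
      warn(paste0("constant feature(s) centred but not scaled: ",
                  paste(head(stats$feature[stats$constant], 5), collapse = ", ")))
    }
  } else {
    missing <- setdiff(parts$feature_ids, stats$feature)
    if (length(missing)) abort(paste0("no statistics for feature ", missing[1]))
    stats <- stats[match(parts$feature_ids, stats$feature), ]
  }
  xs <- sweep(x, 2, stats$mean, "-")
  xs <- sweep(xs, 2, ifelse(stats$sd > 0, stats$sd, 1), "/")
  out <- tibble::as_tibble(data)
  out[parts$feature_ids] <- tibble::as_tibble(xs)
  attr(out, "stats") <- stats
  out
}

#' Collapse probes to genes by largest fold change
#'
#' When several array probes map to one gene, the probe whose mean difference
#' between two sample groups (on the log scale the matrix is assumed to be
#' in) is largest in absolute value represents the gene; ties go to the
#' lexicographically smaller probe id.
#'
#' @param data Dataset tibble whose feature columns are probes.
#' @param probe_map Data frame with columns `probe` and `gene` (each probe
#'   maps to exactly one gene).
#' @param groups Two-level factor/vector over the samples defining the fold
#'   change, or the name of such a column of `data`.
#' @param class_col,id_col Column names.
#' @return Tibble with one feature column per gene (named by gene), other
#'   columns passed through; attribute `"chosen"` records the probe kept for
#'   each gene and its fold change.
#' @export
collapse_probes <- function(data, probe_map, groups, class_col = "class",
                            id_col = "sample_id") {
  parts <- split_dataset(data, class_col, id_col, require_class = FALSE)
  probe_map <- tibble::as_tibble(probe_map)
  if (anyDuplicated(probe_map$probe)) abort("each probe must map to one gene")
  missing <- setdiff(parts$feature_ids, probe_map$probe)
  if (length(missing)) abort(paste0("probe not in map: ", missing[1]))
  if (is.character(groups) && length(groups) == 1) groups <- data[[groups]]
  g <- factor(groups)
  if (nlevels(g) != 2) abort("`groups` must have exactly two levels")
  if (any(table(g) == 0)) abort("empty fold-change group")

  fc <- colMeans(parts$x[g == levels(g)[1], , drop = FALSE]) -
    colMeans(parts$x[g == levels(g)[2], , drop = FALSE])
  tbl <- tibble::tibble(probe = parts$feature_ids,
                        gene = probe_map$gene[match(parts$feature_ids, probe_map$probe)],
                        abs_fc = abs(fc), log_fc = fc)
  chosen <- tbl |>
    dplyr::arrange(.data$gene, dplyr::desc(.data$abs_fc), .data$probe) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)

  keep_cols <- setdiff(names(data), parts$feature_ids)
  out <- tibble::as_tibble(data[keep_cols])
  xg <- parts$x[, chosen$probe, drop = FALSE]
  colnames(xg) <- chosen$gene
  out <- dplyr::bind_cols(out, tibble::as_tibble(xg))
  attr(out, "chosen") <- chosen
  out
}
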