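delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a class-label table
#'
#' Two-column delimited file (TSV, or CSV by extension) with a header:
#' sample id and class label.
#'
#' @param path File path.
#' @return Tibble `sample_id`, `class` (factor).
#' @export
read_labels <- function(path) {
  tbl <- readr::read_delim(path, delim = delim_for(path), col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(tbl) == 0) abort(paste0("label file has no rows: ", path))
  if (ncol(tbl) < 2) abort("label file needs sample-id and class columns")
  out <- tibble::tibble(sample_id = as.character(tbl[[1]]),
                        class = factor(tbl[[2]]))
  dup <- out$sample_id[duplicated(out$sample_id)]
  if (length(dup)) abort(paste0("duplicate sample id in labels: ", dup[1]))
  out
}

#' Read an expression matrix
#'
#' Delimited file with a header row and ids in the first column. The matrix
#' is returned in samples-by-features orientation; when `labels` are given
#' the orientation is auto-detected by matching their sample ids against the
#' first column versus the header, and the matrix is transposed if the ids
#' live in the header. Joined with the labels when provided.
#'
#' @param path File path (TSV, or CSV by extension).
#' @param labels Optional label tibble from [read_labels()] (or a path).
#' @return Dataset tibble: `sample_id`, `class` (if labels given), feature
#'   columns.
#' @export
read_expression <- function(path, labels = NULL) {
  if (is.character(labels)) labels <- read_labels(labels)
  tbl <- readr::read_delim(path, delim = delim_for(path), col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(tbl) == 0) abort(paste0("expression file has no rows: ", path))
  row_ids <- as.character(tbl[[1]])
  col_ids <- names(tbl)[-1]
  x <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(x)) abort("non-numeric cells in the expression matrix")
  if (!is.null(labels)) {
    in_rows <- mean(labels$sample_id %in% row_ids)
    in_cols <- mean(labels$sample_id %in% col_ids)
    if (in_rows < 1 && in_cols < 1) {
      abort("sample ids in labels match neither rows nor columns of the matrix")
    }
    if (in_rows == 1 && in_cols == 1) {
      abort("orientation ambiguous: label ids match both rows and columns")
    }
    if (in_cols == 1) {  # features in rows; transpose
      feat <- row_ids
      x <- t(x)
      row_ids <- col_ids
      col_ids <- feat
    }
  }
  if (anyDuplicated(row_ids)) {
    abort(paste0("duplicate sample id: ", row_ids[duplicated(row_ids)][1]))
  }
  if (anyDuplicated(col_ids)) {
    abort(paste0("duplicate feature id: ", col_ids[duplicated(col_ids)][1]))
  }
  out <- tibble::tibble(sample_id = row_ids)
  colnames(x) <- col_ids
  out <- dplyr::bind_cols(out, tibble::as_tibble(x))
  if (!is.null(labels)) {
    out <- dplyr::inner_join(labels, out, by = "sample_id")
  }
  out
}

#' Write a dataset tibble as expression + label files
#'
#' @param data Dataset tibble (`sample_id`, optional `class`, features).
#' @param prefix Output path prefix; writes `<prefix>.expr.tsv` and, when a
#'   class column is present, `<prefix>.labels.tsv`.
#' @return The paths written, invisibly.
#' @export
write_dataset <- function(data, prefix) {
  expr_path <- paste0(prefix, ".expr.tsv")
  keep <- setdiff(names(data), "class")
  readr::write_tsv(data[keep], expr_path, progress = FALSE)
  paths <- expr_path
  if ("class" %in% names(data)) {
    lab_path <- paste0(prefix, ".labels.tsv")
    readr::write_tsv(data[c("sample_id", "class")], lab_path, progress = FALSE)
    paths <- c(paths, lab_path)
  }
  invisible(paths)
}

#' Pipeline configuration
#'
#' Collects every setting of the end-to-end run: input paths (or in-memory
#' tibbles), the range of maximum projection sizes to search, the search
#' budget and local-optimization iterations, the classifier and its tuning,
#' and one master seed that is fanned out to the per-stage random streams.
#'
#' @param expression,labels Paths to the training expression matrix and
#'   labels (alternatively supply `data`).
#' @param data In-memory training dataset tibble.
#' @param test_expression,test_labels,test_data Held-out test set; when
#'   absent, `test_fraction` of the training samples (stratified) is held
#'   out.
#' @param max_features Vector of maximum projection sizes to search
#'   (default `3:8`).
#' @param budget Projections to evaluate per search run.
#' @param optimize Local-optimization iterations per run (0 disables).
#' @param k Neighbours for the projection score (default
#'   `round(sqrt(n_train))`).
#' @param classifier `"nb"`, `"svm"`, `"tgdr"` or `"multi_tgdr"`.
#' @param tau,delta_nu,k_iters,variant TGDR settings.
#' @param test_fraction Held-out fraction when no test set is supplied.
#' @param gbs_halved Use the halved Brier convention in the report.
#' @param out_dir Directory for report, manifest and artifact files
#'   (`NULL` = return only).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression = NULL, labels = NULL, data = NULL,
                            test_expression = NULL, test_labels = NULL,
                            test_data = NULL, max_features = 3:8,
                            budget = 50000, optimize = 10000, k = NULL,
                            classifier = c("nb", "svm", "tgdr", "multi_tgdr"),
                            tau = 0, delta_nu = 0.01, k_iters = 200,
                            variant = "multi_global", test_fraction = 0.3,
                            gbs_halved = FALSE, out_dir = NULL, seed = 1L) {
  structure(list(expression = expression, labels = labels, data = data,
                 test_expression = test_expression, test_labels = test_labels,
                 test_data = test_data, max_features = max_features,
                 budget = budget, optimize = optimize, k = k,
                 classifier = match.arg(classifier), tau = tau,
                 delta_nu = delta_nu, k_iters = k_iters, variant = variant,
                 test_fraction = test_fraction, gbs_halved = gbs_halved,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full projection-search classification pipeline
#'
#' Normalize, search the projection space for each maximum size, locally
#' optimize, take the best projection as the gene signature, fit the chosen
#' classifier on those features, predict posteriors on the held-out samples
#' and compute all four evaluation metrics. All artifacts (and a manifest
#' with the configuration, seeds and input checksums) are written under
#' `config$out_dir` when set.
#'
#' @param config A [pipeline_config()].
#' @return List of class `radviz_pipeline`: `searches`, `best` (best
#'   projection row), `model`, `posterior`, `metrics` (one-row tibble),
#'   `frequency`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  train <- config$data
  if (is.null(train)) {
    if (is.null(config$expression) || is.null(config$labels)) {
      abort("pipeline [input]: supply `data` or `expression` + `labels` paths")
    }
    train <- read_expression(config$expression, config$labels)
  }
  test <- config$test_data
  if (is.null(test) && !is.null(config$test_expression)) {
    test <- read_expression(config$test_expression, config$test_labels)
  }
  seed <- config$seed
  if (is.null(test)) {
    set.seed(sub_seed(seed, 10L))
    y <- factor(train$class)
    hold <- unlist(lapply(levels(y), function(l) {
      idx <- which(y == l)
      sample(idx, max(1, round(config$test_fraction * length(idx))))
    }))
    test <- train[hold, , drop = FALSE]
    train <- train[-hold, , drop = FALSE]
  }

  searches <- lapply(seq_along(config$max_features), function(i) {
    m <- config$max_features[i]
    res <- vizrank_search(train, max_features = m, budget = config$budget,
                          k = config$k, seed = sub_seed(seed, 20L + i))
    if (config$optimize > 0) {
      res <- local_optimize(res, train, iterations = config$optimize,
                            seed = sub_seed(seed, 40L + i))
    }
    res
  })
  names(searches) <- paste0("max", config$max_features)

  best <- best_projection(searches)
  sig <- best$features[[1]]
  cols <- c("sample_id", "class", sig)
  model <- switch(config$classifier,
    nb = fit_nb(train[cols]),
    svm = fit_svm(train[cols]),
    tgdr = fit_tgdr(train[cols], tau = config$tau, delta_nu = config$delta_nu,
                    k_iters = config$k_iters),
    multi_tgdr = fit_multi_tgdr(train[cols], tau = config$tau,
                                delta_nu = config$delta_nu,
                                k_iters = config$k_iters,
                                variant = config$variant)
  )
  posterior <- predict_proba(model, test[cols])
  metrics <- evaluate_classifier(posterior, test$class,
                                 gbs_halved = config$gbs_halved)

  # pooled frequency table across the per-size runs
  freq <- dplyr::bind_rows(lapply(searches, function(s) s$frequency)) |>
    dplyr::group_by(.data$feature, .data$index) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$index) |>
    dplyr::mutate(rank = dplyr::row_number())

  checksum <- function(p) if (is.null(p)) NULL else unname(tools::md5sum(p))
  manifest <- list(
    package = "radvizr",
    version = as.character(utils::packageVersion("radvizr")),
    seed = seed,
    config = config[c("max_features", "budget", "optimize", "classifier",
                      "tau", "delta_nu", "k_iters", "variant",
                      "test_fraction", "gbs_halved")],
    inputs = list(expression = config$expression, labels = config$labels,
                  expression_md5 = checksum(config$expression),
                  labels_md5 = checksum(config$labels)),
    n_train = nrow(train), n_test = nrow(test)
  )

  out <- structure(list(searches = searches, best = best, model = model,
                        posterior = posterior, metrics = metrics,
                        frequency = freq, manifest = manifest,
                        train = train, test = test),
                   class = "radviz_pipeline")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- list(best_projection = list(features = sig,
                                          score = best$score,
                                          max_features = best$max_features),
                   metrics = as.list(metrics),
                   manifest = manifest)
    write_report(report, file.path(config$out_dir, "report.json"))
    readr::write_tsv(freq, file.path(config$out_dir, "frequency.tsv"),
                     progress = FALSE)
    post_tbl <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(posterior)),
                                 tibble::as_tibble(posterior))
    readr::write_tsv(post_tbl, file.path(config$out_dir, "posterior.tsv"),
                     progress = FALSE)
  }
  out
}

#' Write a report list as pretty JSON
#' @param report A list.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.radviz_pipeline <- function(x, ...) {
  cat("RadViz classification pipeline\n")
  cat(sprintf("Best projection (score %.2f, max %d features): %s\n",
              x$best$score, x$best$max_features,
              paste(x$best$features[[1]], collapse = ", ")))
  print(x$metrics)
  invisible(x)
}
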