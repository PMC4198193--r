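# Internal helpers shared across modules.

# Derive an independent sub-stream seed from a master seed. Keeps the result
# a positive 32-bit integer so set.seed() accepts it.
sub_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) * 48271 + stream * 104729
  as.integer(s %% 2147483646) + 1L
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(seed)
  code
}

# Split a dataset tibble (sample id column + class column + numeric feature
# columns) into the pieces the numeric code works with.
split_dataset <- function(data, class_col = "class", id_col = "sample_id",
                          require_class = TRUE) {
  data <- tibble::as_tibble(data)
  nms <- names(data)
  has_id <- !is.null(id_col) && id_col %in% nms
  has_class <- !is.null(class_col) && class_col %in% nms
  if (require_class && !has_class) {
    abort(paste0("column '", class_col, "' not found in `data`"))
  }
  drop <- c(if (has_id) id_col, if (has_class) class_col)
  feat_cols <- setdiff(nms, drop)
  numeric_ok <- vapply(data[feat_cols], is.numeric, logical(1))
  if (!all(numeric_ok)) {
    abort(paste0("non-numeric feature columns: ",
                 paste(feat_cols[!numeric_ok], collapse = ", ")))
  }
  x <- as.matrix(data[feat_cols])
  if (!all(is.finite(x))) abort("expression values must be finite")
  ids <- if (has_id) as.character(data[[id_col]]) else sprintf("S%d", seq_len(nrow(x)))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sample id: ", ids[duplicated(ids)][1]))
  }
  if (anyDuplicated(feat_cols)) abort("duplicate feature ids")
  rownames(x) <- ids
  y <- NULL
  if (has_class) {
    y <- factor(data[[class_col]])
    if (any(table(y) < 1) || nlevels(y) < 2) {
      abort("every class must have at least one sample and K >= 2")
    }
  }
  list(x = x, y = y, feature_ids = feat_cols, sample_ids = ids)
}

# Map a class factor to 0-based integer codes for the C++ kernels.
class_codes <- function(y) as.integer(y) - 1L

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  as.integer(x)
}
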