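#' Min-max normalize features to [0, 1]
#'
#' RadViz spring weights must be nonnegative, so feature values are rescaled
#' per feature to `[0, 1]` by the training minimum and range. A constant
#' feature maps to 0.5 everywhere. When a `scaling` table from a previous
#' (training) call is supplied it is reused and the transformed values are
#' clipped to `[0, 1]`, so test samples are mapped with training statistics.
#'
#' @param data Dataset tibble: optional `sample_id` and `class` columns plus
#'   numeric feature columns.
#' @param scaling Optional scaling table from a previous call (the
#'   `"scaling"` attribute of its result).
#' @param class_col,id_col Names of the class / sample-id columns (passed
#'   through untouched if present).
#' @return The tibble with feature columns rescaled to `[0, 1]`, carrying the
#'   scaling table in attribute `"scaling"`.
#' @export
normalize_features <- function(data, scaling = NULL, class_col = "class",
                               id_col = "sample_id") {
  parts <- split_dataset(data, class_col, id_col, require_class = FALSE)
  x <- parts$x
  if (is.null(scaling)) {
    mins <- apply(x, 2, min)
    maxs <- apply(x, 2, max)
    scaling <- tibble::tibble(feature = parts$feature_ids, min = mins,
                              max = maxs, constant = maxs == mins)
  } else {
    missing <- setdiff(parts$feature_ids, scaling$feature)
    if (length(missing)) abort(paste0("no scaling for feature ", missing[1]))
    scaling <- scaling[match(parts$feature_ids, scaling$feature), ]
  }
  rng <- scaling$max - scaling$min
  xn <- sweep(x, 2, scaling$min, "-")
  xn <- sweep(xn, 2, ifelse(scaling$constant, 1, rng), "/")
  xn[, scaling$constant] <- 0.5
  xn[xn < 0] <- 0
  xn[xn > 1] <- 1
  out <- tibble::as_tibble(data)
  out[parts$feature_ids] <- tibble::as_tibble(xn)
  attr(out, "scaling") <- scaling
  out
}

#' Anchor positions for a RadViz projection
#'
#' Features are anchored at equally spaced points on the unit circle, anchor
#' 1 at (1, 0), proceeding counterclockwise.
#'
#' @param features Character vector of feature ids (or a count).
#' @return Tibble: `feature`, `angle`, `x`, `y`.
#' @export
radviz_anchors <- function(features) {
  if (is.numeric(features) && length(features) == 1) {
    features <- paste0("F", seq_len(features))
  }
  m <- length(features)
  if (m < 3) abort("a RadViz projection needs at least 3 features")
  ang <- 2 * pi * (seq_len(m) - 1) / m
  tibble::tibble(feature = features, angle = ang, x = cos(ang), y = sin(ang))
}

#' Project one sample onto the RadViz plane
#'
#' The spring-equilibrium rule: each anchor pulls the sample point with
#' stiffness equal to the sample's normalized value for that feature, so the
#' point comes to rest at the stiffness-weighted mean of the anchors,
#' `p = sum(w_i a_i) / sum(w_i)`. A sample with all-zero weights rests at the
#' origin.
#'
#' @param w Nonnegative weights (the sample's normalized values, in anchor
#'   order); at least 3.
#' @return Length-2 numeric, the (x, y) equilibrium point.
#' @examples
#' radviz_project(c(1, 0, 0))  # anchor 1: (1, 0)
#' radviz_project(c(1, 1, 1))  # centre: (0, 0)
#' @export
radviz_project <- function(w) {
  if (any(w < 0)) abort("RadViz weights must be nonnegative (normalize first)")
  a <- radviz_anchors(length(w))
  s <- sum(w)
  if (s == 0) return(c(x = 0, y = 0))
  c(x = sum(w * a$x) / s, y = sum(w * a$y) / s)
}

#' Lay out all samples of a normalized matrix in a RadViz projection
#'
#' @param data Normalized dataset tibble (values in `[0, 1]`, e.g. from
#'   [normalize_features()]).
#' @param features Ordered character vector of feature ids defining the
#'   projection (anchor order).
#' @param class_col,id_col Column names carried into the layout.
#' @return A `radviz_layout` tibble: `sample_id`, `class` (if present), `x`,
#'   `y`; every point lies in the convex hull of the anchors.
#' @export
radviz_layout <- function(data, features, class_col = "class",
                          id_col = "sample_id") {
  parts <- split_dataset(data, class_col, id_col, require_class = FALSE)
  missing <- setdiff(features, parts$feature_ids)
  if (length(missing)) abort(paste0("feature not in data: ", missing[1]))
  w <- parts$x[, features, drop = FALSE]
  if (any(w < 0)) abort("RadViz weights must be nonnegative (normalize first)")
  a <- radviz_anchors(features)
  s <- rowSums(w)
  px <- ifelse(s == 0, 0, (w %*% a$x) / pmax(s, .Machine$double.xmin))
  py <- ifelse(s == 0, 0, (w %*% a$y) / pmax(s, .Machine$double.xmin))
  out <- tibble::tibble(sample_id = parts$sample_ids, x = as.vector(px),
                        y = as.vector(py))
  if (!is.null(parts$y)) out$class <- parts$y
  attr(out, "features") <- features
  class(out) <- c("radviz_layout", class(out))
  out
}

#' Plot a RadViz projection
#'
#' Draws the unit circle, labelled feature anchors, and the samples coloured
#' by class.
#'
#' @param data Dataset tibble (raw scale; normalized internally with
#'   [normalize_features()] unless `normalize = FALSE`).
#' @param features Ordered feature ids for the projection.
#' @param class_col,id_col Column names.
#' @param normalize Min-max normalize before projecting (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_radviz <- function(data, features, class_col = "class",
                        id_col = "sample_id", normalize = TRUE) {
  if (normalize) data <- normalize_features(data, class_col = class_col, id_col = id_col)
  layout <- radviz_layout(data, features, class_col, id_col)
  autoplot(layout)
}

#' @rdname plot_radviz
#' @param object A `radviz_layout`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.radviz_layout <- function(object, ...) {
  anchors <- radviz_anchors(attr(object, "features"))
  circ <- tibble::tibble(t = seq(0, 2 * pi, length.out = 361),
                         x = cos(.data$t), y = sin(.data$t))
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circ, colour = "grey60") +
    ggplot2::geom_point(data = anchors, shape = 15, size = 2, colour = "grey30") +
    ggplot2::geom_text(data = anchors, ggplot2::aes(label = .data$feature),
                       vjust = -1, size = 3) +
    ggplot2::coord_fixed(xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
  if ("class" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p
}
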