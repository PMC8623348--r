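#' Uniformity measure of a segmentation
#'
#' Unsupervised quality score penalizing within-class intensity variance:
#' \deqn{U = 1 - \frac{2 K \sum_j \sum_{i \in S_j} (I_i - \overline{S_j})^2}
#'   {M N (I_{max} - I_{min})^2}.}
#' U = 1 exactly when every class is internally constant. The squared
#' dynamic range keeps U dimensionless and inside \[0, 1\];
#' `squared_range = FALSE` switches to a first-power normalization for
#' compatibility with sources that print it that way. A constant image
#' (zero dynamic range) has U defined as 1.
#'
#' @param image Gray-level matrix.
#' @param labels Label map partitioning `image` into K + 1 classes.
#' @param K Number of thresholds (classes minus one).
#' @param squared_range Use the squared dynamic range (default TRUE).
#' @return Scalar U <= 1.
#' @export
uniformity <- function(image, labels, K, squared_range = TRUE) {
  image <- as_gray_image(image)
  if (!identical(dim(labels), dim(image))) {
    stop("label map and image shapes differ", call. = FALSE)
  }
  rng <- diff(range(image))
  if (rng == 0) return(1)
  dev2 <- stats::ave(as.numeric(image), as.vector(labels))
  ss <- sum((as.numeric(image) - dev2)^2)
  norm <- length(image) * (if (squared_range) rng^2 else rng)
  1 - 2 * K * ss / norm
}

binarize <- function(labels, foreground_class) labels == foreground_class

#' Misclassification error against a reference map
#'
#' Binary form: with foreground = `foreground_class` and background = the
#' rest, \deqn{ME = 1 - \frac{|R_1^f \cap R_2^f| + |R_1^b \cap R_2^b|}
#'   {|R_2^f| + |R_2^b|}} where R1 is the segmentation under test and R2 the
#' reference. With `foreground_class = NULL` the multilevel aggregate is
#' returned: the unweighted mean of one-vs-rest ME over classes 0..K
#' (optionally dropping class 0 via `exclude_background`).
#'
#' @param seg,truth Label maps of identical shape.
#' @param foreground_class Class treated as foreground, or NULL for the
#'   multilevel aggregate.
#' @param K Number of thresholds; defaults to the largest label present in
#'   either map.
#' @param exclude_background Drop class 0 from the aggregate.
#' @return Value in \[0, 1\]; 0 iff the (binarized) maps agree everywhere.
#' @export
misclassification_error <- function(seg, truth, foreground_class = NULL,
                                    K = max(seg, truth),
                                    exclude_background = FALSE) {
  if (!identical(dim(seg), dim(truth))) {
    stop("shape mismatch between segmentation and reference", call. = FALSE)
  }
  one <- function(cls) {
    f1 <- binarize(seg, cls)
    f2 <- binarize(truth, cls)
    1 - (sum(f1 & f2) + sum(!f1 & !f2)) / length(truth)
  }
  if (!is.null(foreground_class)) return(one(foreground_class))
  classes <- seq.int(if (exclude_background) 1L else 0L, K)
  mean(vapply(classes, one, numeric(1)))
}

#' Hausdorff distance between two pixel sets
#'
#' \deqn{H(A, B) = \max\{h(A, B), h(B, A)\}, \quad
#'   h(A, B) = \max_{a \in A} \min_{b \in B} \lVert a - b \rVert}
#' with Euclidean distances in pixel units. Operates on region pixel sets as
#' given (no boundary extraction); pass boundary sets for a boundary
#' Hausdorff.
#'
#' @param a,b Two-column matrices of (row, col) coordinates; both non-empty.
#' @return Non-negative scalar; 0 iff the sets are equal.
#' @export
hausdorff_distance <- function(a, b) {
  a <- coord_matrix(a)
  b <- coord_matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("undefined distance: empty pixel set", call. = FALSE)
  }
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("coordinates must have two columns", call. = FALSE)
  x
}

# max over a of the distance to the nearest point of b, via an exact
# Euclidean distance transform on the joint bounding grid.
directed_hausdorff <- function(a, b) {
  lo <- pmin(apply(a, 2L, min), apply(b, 2L, min)) - 1L
  hi <- pmax(apply(a, 2L, max), apply(b, 2L, max))
  m <- hi[1L] - lo[1L]
  n <- hi[2L] - lo[2L]
  mask <- matrix(1, m, n)
  mask[cbind(b[, 1L] - lo[1L], b[, 2L] - lo[2L])] <- 0
  dm <- EBImage::distmap(mask, metric = "euclidean")
  max(dm[cbind(a[, 1L] - lo[1L], a[, 2L] - lo[2L])])
}

#' Jaccard index between two pixel sets
#'
#' \deqn{J(A, B) = |A \cap B| / |A \cup B|.} Two empty sets are defined as
#' identical (J = 1).
#'
#' @param a,b Two-column coordinate matrices or logical masks of identical
#'   shape.
#' @return Value in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    uni <- sum(a | b)
    if (uni == 0L) return(1)
    return(sum(a & b) / uni)
  }
  a <- coord_matrix(a)
  b <- coord_matrix(b)
  if (nrow(a) == 0L && nrow(b) == 0L) return(1)
  ka <- paste(a[, 1L], a[, 2L])
  kb <- paste(b[, 1L], b[, 2L])
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Full metrics report for a segmentation
#'
#' Computes the uniformity of `labels` on `image` and, when a ground-truth
#' map is supplied, the multilevel aggregates (unweighted one-vs-rest class
#' means) of misclassification error, Hausdorff distance and Jaccard index,
#' with per-class breakdowns. Classes empty in both maps score J = 1 and are
#' skipped (with a warning) for H.
#'
#' @param image Gray-level matrix.
#' @param labels Label map under evaluation.
#' @param K Number of thresholds.
#' @param truth Optional reference label map.
#' @param exclude_background Drop class 0 from ME/H/J aggregates.
#' @return An object of class `metrics_report`: list with `U` and, given
#'   truth, `ME`, `H`, `J` and a `per_class` data frame.
#' @export
segmentation_metrics <- function(image, labels, K, truth = NULL,
                                 exclude_background = FALSE) {
  out <- list(U = uniformity(image, labels, K))
  if (!is.null(truth)) {
    classes <- seq.int(if (exclude_background) 1L else 0L, K)
    per <- data.frame(class = classes, ME = NA_real_, H = NA_real_,
                      J = NA_real_)
    for (i in seq_along(classes)) {
      cls <- classes[i]
      a <- which(labels == cls, arr.ind = TRUE)
      b <- which(truth == cls, arr.ind = TRUE)
      per$ME[i] <- misclassification_error(labels, truth, cls)
      per$J[i] <- if (nrow(a) == 0L && nrow(b) == 0L) 1 else
        jaccard_index(labels == cls, truth == cls)
      if (nrow(a) > 0L && nrow(b) > 0L) {
        per$H[i] <- hausdorff_distance(a, b)
      } else if (nrow(a) > 0L || nrow(b) > 0L) {
        warning("class ", cls, " empty in one map; skipped in Hausdorff ",
                "aggregate", call. = FALSE)
      } else {
        per$H[i] <- 0
      }
    }
    out$ME <- mean(per$ME)
    out$H <- mean(per$H, na.rm = TRUE)
    out$J <- mean(per$J)
    out$per_class <- per
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("U  = %.4f\n", x$U))
  if (!is.null(x$ME)) {
    cat(sprintf("ME = %.4f   H = %.4f   J = %.4f\n", x$ME, x$H, x$J))
  }
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report A `metrics_report`.
#' @param path Output file path.
#' @param config Optional configuration list echoed into the report.
#' @return The path, invisibly.
#' @export
write_metrics_json <- function(report, path, config = NULL) {
  payload <- unclass(report)
  if (!is.null(config)) payload$config <- config
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
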