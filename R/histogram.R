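#' Validate an 8-bit grayscale image matrix
#'
#' Checks that `image` is a numeric matrix whose entries are integers in
#' \[0, 255\]. Images throughout the package are plain base matrices with
#' rows indexing image height and columns indexing width.
#'
#' @param image A numeric matrix.
#' @return The validated matrix, invisibly coerced to storage mode integer.
#' @keywords internal
as_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(image) < 1L || ncol(image) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(image)) stop("image contains missing values", call. = FALSE)
  if (any(image != round(image))) {
    stop("image pixel values must be integers", call. = FALSE)
  }
  if (any(image < 0) || any(image > 255)) {
    stop("image pixel values must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(image) <- "integer"
  image
}

#' Gray-level histogram of an 8-bit image
#'
#' Builds the 256-bin histogram of a grayscale image: per-level pixel counts
#' \eqn{n_j} and probabilities \eqn{P_j = n_j / (M N)} for gray levels
#' \eqn{j = 0, \dots, 255}.
#'
#' @param image A matrix of integer gray levels in \[0, 255\].
#' @return An object of class `gray_histogram`: a list with `counts`
#'   (integer vector of length 256), `probabilities` (numeric, sums to 1)
#'   and `total_pixels`.
#' @examples
#' h <- gray_histogram(matrix(c(0L, 0L, 128L, 255L), 2, 2))
#' h$probabilities[c(1, 129, 256)]
#' @export
gray_histogram <- function(image) {
  image <- as_gray_image(image)
  counts <- tabulate(as.vector(image) + 1L, nbins = 256L)
  total <- length(image)
  structure(
    list(
      counts = counts,
      probabilities = counts / total,
      total_pixels = total
    ),
    class = "gray_histogram"
  )
}

#' Build a gray_histogram directly from counts
#'
#' Used for histogram-level experiments where no raster exists.
#'
#' @param counts Non-negative integer vector of length 256 (or shorter;
#'   padded with zeros).
#' @return A `gray_histogram`.
#' @export
histogram_from_counts <- function(counts) {
  if (length(counts) > 256L) stop("at most 256 bins", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts <- c(as.integer(counts), integer(256L - length(counts)))
  total <- sum(counts)
  if (total == 0L) stop("histogram has no mass", call. = FALSE)
  structure(
    list(counts = counts, probabilities = counts / total, total_pixels = total),
    class = "gray_histogram"
  )
}

#' @export
print.gray_histogram <- function(x, ...) {
  occ <- which(x$counts > 0L) - 1L
  cat("gray_histogram:", x$total_pixels, "pixels,",
      length(occ), "occupied bins in [", min(occ), ",", max(occ), "]\n")
  invisible(x)
}
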