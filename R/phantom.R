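#' Specification of a synthetic brain-like phantom
#'
#' Describes a piecewise-constant grayscale raster built from nested
#' regions (concentric ellipses or rectangles) standing in for the
#' background / skull / CSF / GM / WM-style tissue bands of an axial brain
#' slice. Class 0 is the outermost (darkest) region; class k the k-th
#' nested band. Band boundaries are spaced so the nested regions have
#' roughly equal areas, and every class is guaranteed at least 1% of the
#' pixels.
#'
#' @param height,width Raster size in pixels.
#' @param class_means Strictly increasing integer gray means in \[0, 255\],
#'   one per class (length K + 1).
#' @param geometry `"concentric-ellipses"` or `"nested-rectangles"`.
#' @param jitter Half-width of the uniform within-class intensity jitter in
#'   gray levels (default 0: exactly piecewise constant). Must stay below
#'   half the smallest gap between consecutive class means so the class
#'   intensity ranges remain disjoint.
#' @param seed Mandatory RNG seed; generation is fully deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height, width, class_means,
                         geometry = c("concentric-ellipses",
                                      "nested-rectangles"),
                         jitter = 0, seed) {
  geometry <- match.arg(geometry)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (height < 8L || width < 8L) stop("raster too small", call. = FALSE)
  class_means <- as.integer(class_means)
  if (length(class_means) < 2L) stop("need at least two classes", call. = FALSE)
  if (any(diff(class_means) <= 0)) {
    stop("class_means must be strictly increasing", call. = FALSE)
  }
  if (any(class_means < 0) || any(class_means > 255)) {
    stop("class_means must lie in [0, 255]", call. = FALSE)
  }
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  if (jitter > 0 && jitter >= min(diff(class_means)) / 2) {
    stop("jitter must be below half the smallest class-mean gap",
         call. = FALSE)
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         class_means = class_means, geometry = geometry,
         jitter = jitter, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a phantom image with ground-truth labels
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (integer gray matrix) and `labels` (the
#'   ground-truth label map, values 0..K).
#' @examples
#' ph <- generate_phantom(phantom_spec(64, 64, c(20, 90, 160, 230), seed = 1))
#' table(ph$labels)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  m <- spec$height
  n <- spec$width
  k1 <- length(spec$class_means)
  cy <- (m + 1) / 2
  cx <- (n + 1) / 2
  ry <- 0.92 * (m - 1) / 2
  rx <- 0.92 * (n - 1) / 2
  yy <- matrix(seq_len(m), m, n)
  xx <- matrix(seq_len(n), m, n, byrow = TRUE)
  e <- if (spec$geometry == "concentric-ellipses") {
    sqrt(((yy - cy) / ry)^2 + ((xx - cx) / rx)^2)
  } else {
    pmax(abs(yy - cy) / ry, abs(xx - cx) / rx)
  }
  # equal-area band boundaries inside the outer contour (e = 1)
  bnd <- sqrt(seq(k1 - 1L, 1L) / (k1 - 1L))
  labels <- matrix(0L, m, n)
  for (j in seq_along(bnd)) labels <- labels + (e <= bnd[j])
  sizes <- tabulate(labels + 1L, nbins = k1)
  if (any(sizes < 0.01 * m * n)) {
    stop("infeasible geometry: a class occupies less than 1% of pixels",
         call. = FALSE)
  }
  img <- matrix(spec$class_means[labels + 1L], m, n)
  if (spec$jitter > 0) {
    old <- local_seed(spec$seed)
    on.exit(restore_seed(old))
    img <- img + stats::runif(m * n, -spec$jitter, spec$jitter)
  }
  img <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), m, n)
  list(image = img, labels = labels)
}

#' Add Gaussian read-out noise to an 8-bit image
#'
#' Noise is drawn i.i.d. per pixel as N(0, `variance`) on the \[0, 1\]
#' intensity scale (so the conventional "N(0, 0.001)" corresponds to a
#' standard deviation of about 8 gray levels), rescaled to \[0, 255\],
#' clipped and rounded.
#'
#' @param image Gray-level matrix.
#' @param variance Noise variance on the \[0, 1\] scale (>= 0).
#' @param seed Mandatory RNG seed.
#' @return Noisy integer gray matrix, same shape.
#' @export
add_gaussian_noise <- function(image, variance, seed) {
  image <- as_gray_image(image)
  if (variance < 0) stop("variance must be >= 0", call. = FALSE)
  if (variance == 0) return(image)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  noisy <- (image / 255 + stats::rnorm(length(image), 0, sqrt(variance))) * 255
  matrix(as.integer(round(pmin(pmax(noisy, 0), 255))), nrow(image),
         ncol(image))
}

# Seed scoping: set the RNG deterministically without clobbering the
# caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
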