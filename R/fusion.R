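#' Fusion configuration
#'
#' @param radius Neighborhood radius in pixels (Euclidean disc, default 12).
#' @param alpha Spatial bandwidth of the similarity kernel (default 1).
#' @param beta Intensity bandwidth of the similarity kernel, in gray levels
#'   (default 1).
#' @param shape Neighborhood shape: `"disc"` (Dis <= radius) or `"square"`
#'   (Chebyshev window).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(radius = 12, alpha = 1, beta = 1,
                          shape = c("disc", "square")) {
  if (radius <= 0 || alpha <= 0 || beta <= 0) {
    stop("radius, alpha and beta must be > 0", call. = FALSE)
  }
  structure(list(radius = radius, alpha = alpha, beta = beta,
                 shape = match.arg(shape)),
            class = "fusion_config")
}

#' Similarity between two pixels
#'
#' \deqn{SIM(p, q) = \exp\!\left(-\frac{Dis(p,q)^2}{2\alpha^2}
#'   - \frac{|I(p) - I(q)|^2}{2\beta^2}\right)}
#' with Euclidean pixel distance and intensities on the 0-255 scale.
#' Symmetric, in (0, 1], and 1 exactly when p = q.
#'
#' @param p,q Length-2 integer vectors `(row, col)`.
#' @param image Gray-level matrix.
#' @param alpha,beta Kernel bandwidths.
#' @return Scalar similarity.
#' @export
pixel_similarity <- function(p, q, image, alpha = 1, beta = 1) {
  d2 <- sum((p - q)^2)
  di <- as.numeric(image[p[1L], p[2L]]) - as.numeric(image[q[1L], q[2L]])
  exp(-(d2 / (2 * alpha^2) + di^2 / (2 * beta^2)))
}

#' Partition pixels into uncontested and controversial sets
#'
#' @param m1,m2 Two label maps of identical shape.
#' @return List of two logical matrices, `uncontested` (labels agree) and
#'   `controversial` (labels differ); they partition the image.
#' @export
split_pixels <- function(m1, m2) {
  if (!identical(dim(m1), dim(m2))) {
    stop("incompatible maps: shapes differ", call. = FALSE)
  }
  agree <- m1 == m2
  list(uncontested = agree, controversial = !agree)
}

# Disc (or square) offsets within `radius`, excluding the center.
neighborhood_offsets <- function(radius, shape = "disc") {
  r <- ceiling(radius)
  dx <- rep(-r:r, times = 2L * r + 1L)
  dy <- rep(-r:r, each = 2L * r + 1L)
  keep <- if (shape == "disc") dx^2 + dy^2 <= radius^2 else rep(TRUE, length(dx))
  keep <- keep & !(dx == 0L & dy == 0L)
  cbind(drow = dy[keep], dcol = dx[keep],
        dist2 = (dx^2 + dy^2)[keep])
}

#' Re-vote the label of one controversial pixel
#'
#' Implements the similarity-weighted vote between the pixel's two candidate
#' labels l_a = m1(p) and l_b = m2(p): uncontested neighbors within the
#' radius whose agreed label equals l_a or l_b contribute their similarity
#' to the respective sum, and l_a wins only if its sum is strictly greater
#' (ties and an empty neighborhood fall to l_b). Controversial neighbors do
#' not vote: their label is undefined at voting time.
#'
#' @param p Length-2 integer vector `(row, col)` of a controversial pixel.
#' @param image Gray-level matrix.
#' @param m1,m2 The two label maps.
#' @param uncontested Logical matrix from [split_pixels()].
#' @param config A [fusion_config()].
#' @return The winning label (scalar integer).
#' @export
relabel_pixel <- function(p, image, m1, m2, uncontested,
                          config = fusion_config()) {
  offs <- neighborhood_offsets(config$radius, config$shape)
  relabel_pixel_impl(p[1L], p[2L], image, m1, m2, uncontested, offs, config)
}

relabel_pixel_impl <- function(row, col, image, m1, m2, uncontested, offs,
                               config) {
  la <- m1[row, col]
  lb <- m2[row, col]
  rows <- row + offs[, 1L]
  cols <- col + offs[, 2L]
  inb <- rows >= 1L & rows <= nrow(image) & cols >= 1L & cols <= ncol(image)
  if (!any(inb)) return(lb)
  rows <- rows[inb]
  cols <- cols[inb]
  d2 <- offs[inb, 3L]
  idx <- cbind(rows, cols)
  unc <- uncontested[idx]
  lab <- m1[idx]
  va <- unc & lab == la
  vb <- unc & lab == lb
  if (!any(va)) return(lb)
  di <- as.numeric(image[row, col]) - as.numeric(image[idx])
  sim <- exp(-(d2 / (2 * config$alpha^2) + di^2 / (2 * config$beta^2)))
  if (sum(sim[va]) > sum(sim[vb])) la else lb
}

#' Fuse two candidate segmentations of the same image
#'
#' Keeps the label wherever the two maps agree and re-votes every
#' controversial pixel with [relabel_pixel()].
#'
#' @param m1,m2 Label maps of identical shape with the same class count and
#'   the same label ordering (label k = k-th darkest class in both).
#' @param image The underlying gray-level matrix.
#' @param config A [fusion_config()].
#' @return The fused label map.
#' @export
fuse_labels <- function(m1, m2, image, config = fusion_config()) {
  image <- as_gray_image(image)
  if (!identical(dim(m1), dim(image))) {
    stop("label map and image shapes differ", call. = FALSE)
  }
  parts <- split_pixels(m1, m2)
  out <- m1
  contested <- which(parts$controversial, arr.ind = TRUE)
  if (nrow(contested) == 0L) return(out)
  offs <- neighborhood_offsets(config$radius, config$shape)
  for (i in seq_len(nrow(contested))) {
    out[contested[i, 1L], contested[i, 2L]] <- relabel_pixel_impl(
      contested[i, 1L], contested[i, 2L], image, m1, m2,
      parts$uncontested, offs, config
    )
  }
  out
}
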