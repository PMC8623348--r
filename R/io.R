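#' Read an 8-bit grayscale image
#'
#' Reads PNG/TIFF (and other formats EBImage supports) into the package's
#' integer gray-matrix representation. Color inputs are converted to
#' luminance first.
#'
#' @param path Image file path.
#' @return Integer matrix of gray levels in \[0, 255\], rows = image height.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) != EBImage::Grayscale) {
    img <- EBImage::channel(img, "gray")
  }
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) > 2L) dat <- dat[, , 1L]
  matrix(as.integer(round(pmin(pmax(t(dat), 0), 1) * 255)),
         ncol(dat), nrow(dat))
}

#' Write an 8-bit grayscale image
#'
#' @param image Integer gray matrix.
#' @param path Output path; the extension selects the format (png/tiff).
#' @return The path, invisibly.
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  EBImage::writeImage(EBImage::Image(t(image) / 255), path)
  invisible(path)
}

#' Write a label map with a JSON sidecar
#'
#' The label map is stored as an 8-bit grayscale image holding the raw
#' label values (0..K), with a `<path>.json` sidecar recording K, the
#' threshold set and the gray interval of every class, so the file is
#' lossless and self-describing.
#'
#' @param labels Integer label matrix.
#' @param path Output image path.
#' @param thresholds Optional threshold set that produced the labels.
#' @return The path, invisibly.
#' @export
write_label_map <- function(labels, path, thresholds = NULL) {
  if (any(labels < 0) || any(labels > 255)) {
    stop("labels must fit 8 bits", call. = FALSE)
  }
  EBImage::writeImage(EBImage::Image(t(labels) / 255), path)
  sidecar <- list(K = max(labels), labels = sort(unique(as.vector(labels))))
  if (!is.null(thresholds)) {
    bounds <- c(-1L, as.integer(thresholds), 255L)
    sidecar$thresholds <- as.integer(thresholds)
    sidecar$gray_intervals <- lapply(seq_len(length(bounds) - 1L), function(i) {
      list(lo = bounds[i] + 1L, hi = bounds[i + 1L])
    })
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path Image path.
#' @return Integer label matrix.
#' @export
read_label_map <- function(path) {
  read_gray_image(path)
}
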