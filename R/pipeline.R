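#' Pipeline configuration
#'
#' Bundles the per-stage configurations with the defaults of the published
#' parameter table: delta = 0.01, lambda1 = 1, lambda2 = 0.1 * lambda1,
#' fusion radius 12, K in 1..5.
#'
#' @param K Number of thresholds.
#' @param delta IIMT convergence constant.
#' @param max_iterations IIMT iteration cap.
#' @param decomposition A [decomposition_config()].
#' @param fusion A [fusion_config()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(K, delta = 0.01, max_iterations = 100L,
                            decomposition = decomposition_config(),
                            fusion = fusion_config()) {
  structure(
    list(iimt = iimt_config(K, delta, max_iterations),
         decomposition = decomposition, fusion = fusion),
    class = "pipeline_config"
  )
}

#' Segment a grayscale image (decompose, threshold both, fuse)
#'
#' The full pipeline: (1) hybrid L1-L0 decomposition extracts the base
#' layer; (2) interval-iteration thresholding segments the original image
#' (map A) and the base layer (map B); (3) the two maps are fused by
#' similarity-weighted voting at the controversial pixels. Both stages can
#' be switched off: `decompose = FALSE, fuse = FALSE` is plain IIMT on the
#' original image; `decompose = TRUE, fuse = FALSE` returns the base-layer
#' segmentation; additionally capping `max_iterations` at 1 reduces IIMT to
#' global multilevel Otsu. These reductions expose the four-way comparison
#' (Otsu / IIMT / HL-IIMT / full pipeline).
#'
#' @param image A matrix of integer gray levels in \[0, 255\].
#' @param config A [pipeline_config()].
#' @param truth Optional ground-truth label map; attaches a
#'   [segmentation_metrics()] report.
#' @param decompose Run the layer-decomposition branch.
#' @param fuse Fuse the two candidate maps.
#' @return An object of class `iimt_segmentation`: list with `labels`,
#'   optional `metrics`, and a `provenance` record (threshold sets,
#'   iteration counts, configuration).
#' @export
segment_image <- function(image, config, truth = NULL, decompose = TRUE,
                          fuse = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  image <- as_gray_image(image)
  k <- config$iimt$K

  t_orig <- with_stage("iimt-original",
                       iimt_thresholds(gray_histogram(image), config$iimt))
  a <- apply_thresholds(image, t_orig)

  t_base <- NULL
  b_map <- NULL
  if (decompose) {
    layers <- with_stage("decompose",
                         hybrid_l1_l0_decompose(image, config$decomposition))
    t_base <- with_stage("iimt-base",
                         iimt_thresholds(gray_histogram(layers$base),
                                         config$iimt))
    b_map <- apply_thresholds(layers$base, t_base)
  }

  labels <- if (decompose && fuse) {
    with_stage("fuse", fuse_labels(a, b_map, image, config$fusion))
  } else if (decompose) {
    b_map
  } else {
    a
  }

  out <- list(
    labels = labels,
    provenance = list(
      K = k,
      thresholds_original = as.integer(t_orig),
      iterations_original = attr(t_orig, "iterations"),
      trace_original = attr(t_orig, "trace"),
      thresholds_base = if (!is.null(t_base)) as.integer(t_base),
      iterations_base = if (!is.null(t_base)) attr(t_base, "iterations"),
      decompose = decompose, fuse = fuse,
      config = list(
        delta = config$iimt$delta,
        max_iterations = config$iimt$max_iterations,
        lambda1 = config$decomposition$lambda1,
        lambda2 = config$decomposition$lambda2,
        rho = config$decomposition$rho,
        outer_iterations = config$decomposition$outer_iterations,
        radius = config$fusion$radius,
        alpha = config$fusion$alpha,
        beta = config$fusion$beta
      )
    )
  )
  if (!is.null(truth)) {
    out$metrics <- segmentation_metrics(image, labels, k, truth)
  }
  structure(out, class = "iimt_segmentation")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.iimt_segmentation <- function(x, ...) {
  p <- x$provenance
  cat("iimt_segmentation:", nrow(x$labels), "x", ncol(x$labels),
      "pixels, K =", p$K, "\n")
  cat("  thresholds (original):", paste(p$thresholds_original, collapse = ", "),
      sprintf("(%d iterations)\n", p$iterations_original))
  if (!is.null(p$thresholds_base)) {
    cat("  thresholds (base)    :", paste(p$thresholds_base, collapse = ", "),
        sprintf("(%d iterations)\n", p$iterations_base))
  }
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
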