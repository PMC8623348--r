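#' Interval-iteration configuration
#'
#' @param K Number of thresholds (>= 1). The original formulation targets
#'   K >= 2 but K = 1 is supported: the first iteration then yields a single
#'   class-mean interval and refinement proceeds identically.
#' @param delta Convergence constant: the search for threshold i stops when
#'   two consecutive values differ by less than `delta`. With integer
#'   thresholds the default 0.01 means "unchanged between iterations".
#' @param max_iterations Safety cap on the total number of iterations,
#'   counting the global-Otsu initialization as iteration 1. Setting 1
#'   reduces the algorithm to plain multilevel Otsu.
#' @return An object of class `iimt_config`.
#' @export
iimt_config <- function(K, delta = 0.01, max_iterations = 100L) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  structure(list(K = K, delta = delta, max_iterations = max_iterations),
            class = "iimt_config")
}

#' First iteration of interval-iteration thresholding
#'
#' Runs exact multilevel Otsu on the full histogram, computes the K + 1
#' class means, and sets up one refinement interval
#' \[mu_i, mu_{i+1}\] per threshold i, each carrying the corresponding
#' global threshold as its current value.
#'
#' Should a class come out empty (its mean is then reported as 0 by
#' [class_stats()]), the interval endpoint falls back to the midpoint of the
#' class's gray range so that the interval sequence stays ordered; at a
#' global Otsu optimum with a feasible K this is not reachable in practice.
#'
#' @param hist A `gray_histogram`.
#' @param K Number of thresholds.
#' @return An `iimt_state`: data frame with one row per threshold
#'   (`lower`, `upper`, `threshold`, `previous`, `converged`) plus an
#'   `iteration` attribute.
#' @export
iimt_first_iteration <- function(hist, K) {
  t <- otsu_multilevel(hist, K)
  st <- class_stats(hist, t)
  means <- st$means
  bounds <- c(-1L, t, 255L)
  for (i in seq_along(means)) {
    if (st$weights[i] == 0) {
      means[i] <- (bounds[i] + 1L + bounds[i + 1L]) / 2
    }
  }
  state <- data.frame(
    lower = means[seq_len(K)],
    upper = means[seq_len(K) + 1L],
    threshold = as.integer(t),
    previous = NA_integer_,
    converged = FALSE,
    # interval from which the current threshold was computed (the global
    # search for iteration 1)
    src_lower = 0,
    src_upper = 255
  )
  attr(state, "iteration") <- 1L
  class(state) <- c("iimt_state", class(state))
  state
}

#' One refinement sweep of interval-iteration thresholding
#'
#' For every non-converged threshold, runs single-threshold Otsu restricted
#' to its current interval, replaces the interval by the two within-interval
#' class means (which always lie inside the old interval, so intervals are
#' nested), and marks the threshold converged once it moves by less than
#' `delta` or the interval degenerates to fewer than two occupied bins.
#' Converged thresholds are frozen.
#'
#' @param hist A `gray_histogram`.
#' @param state An `iimt_state` from [iimt_first_iteration()] or a previous
#'   refinement.
#' @param delta Convergence constant.
#' @return The updated `iimt_state`.
#' @export
iimt_refine <- function(hist, state, delta = 0.01) {
  for (i in seq_len(nrow(state))) {
    if (state$converged[i]) next
    res <- otsu_single_in_interval(hist, state$lower[i], state$upper[i])
    state$previous[i] <- state$threshold[i]
    state$threshold[i] <- res$threshold
    state$src_lower[i] <- state$lower[i]
    state$src_upper[i] <- state$upper[i]
    state$lower[i] <- res$mean_low
    state$upper[i] <- res$mean_high
    state$converged[i] <- res$degenerate ||
      abs(res$threshold - state$previous[i]) < delta
  }
  attr(state, "iteration") <- attr(state, "iteration") + 1L
  state
}

#' Interval-iteration multilevel thresholds
#'
#' The full algorithm: global multilevel Otsu initialization, then
#' independent per-threshold refinement inside nested class-mean intervals
#' until every threshold is stable (moves by less than `delta` between
#' consecutive iterations) or the iteration cap is hit.
#'
#' @param hist A `gray_histogram`.
#' @param config An [iimt_config()].
#' @return Integer vector of K strictly increasing thresholds, with
#'   attributes `iterations` (total sweeps used, including the
#'   initialization), `trace` (list of per-iteration threshold vectors) and
#'   `state` (the final `iimt_state`, exposing each track's last interval).
#' @export
iimt_thresholds <- function(hist, config) {
  stopifnot(inherits(config, "iimt_config"))
  state <- iimt_first_iteration(hist, config$K)
  trace <- list(state$threshold)
  while (any(!state$converged) &&
         attr(state, "iteration") < config$max_iterations) {
    state <- iimt_refine(hist, state, config$delta)
    trace[[length(trace) + 1L]] <- state$threshold
  }
  t <- state$threshold
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("internal consistency error: refined thresholds are not strictly ",
         "increasing (", paste(t, collapse = ", "), ")", call. = FALSE)
  }
  structure(as.integer(t), iterations = attr(state, "iteration"),
            trace = trace, state = state)
}

#' Rasterize a threshold set into a label map
#'
#' Pixel p gets the 0-based label i - 1 of the class t_{i-1} < g(p) <= t_i
#' (t_0 = -1, t_{K+1} = 255): label 0 is the darkest class.
#'
#' @param image A matrix of integer gray levels in \[0, 255\].
#' @param thresholds Strictly increasing integer thresholds.
#' @return Integer matrix of labels in \[0, K\], same shape as `image`.
#' @export
apply_thresholds <- function(image, thresholds) {
  image <- as_gray_image(image)
  thresholds <- check_thresholds(thresholds)
  labels <- findInterval(as.vector(image), thresholds + 0.5)
  matrix(as.integer(labels), nrow(image), ncol(image))
}
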