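#' Class statistics for a threshold set
#'
#' Given K strictly increasing thresholds, gray levels are partitioned into
#' K + 1 classes: class i holds levels t_{i-1} + 1, ..., t_i (with t_0 = -1
#' and t_{K+1} = 255), so a pixel with gray g belongs to class i iff
#' t_{i-1} < g <= t_i. Returns the class probabilities (weights), class mean
#' gray levels and the total mean. A class with zero weight has its mean
#' defined as 0; it contributes nothing to the between-class variance.
#'
#' @param hist A `gray_histogram`.
#' @param thresholds Integer vector, strictly increasing, in \[0, 254\].
#' @return List with `weights` (length K + 1), `means` (length K + 1) and
#'   `total_mean`.
#' @export
class_stats <- function(hist, thresholds) {
  check_thresholds(thresholds)
  p <- hist$probabilities
  levels <- 0:255
  bounds <- c(-1L, as.integer(thresholds), 255L)
  k1 <- length(thresholds) + 1L
  weights <- numeric(k1)
  means <- numeric(k1)
  for (i in seq_len(k1)) {
    sel <- (bounds[i] + 1L):bounds[i + 1L]
    # degenerate: when t_i == t_{i-1} cannot happen (strictly increasing)
    w <- sum(p[sel + 1L])
    weights[i] <- w
    means[i] <- if (w > 0) sum(levels[sel + 1L] * p[sel + 1L]) / w else 0
  }
  list(weights = weights, means = means, total_mean = sum(levels * p))
}

#' Between-class variance of a threshold set (Otsu criterion)
#'
#' \deqn{\sigma_B^2 = \sum_{i=1}^{K+1} \omega_i (\mu_i - \mu_T)^2}
#'
#' @inheritParams class_stats
#' @return Non-negative scalar.
#' @export
between_class_variance <- function(hist, thresholds) {
  st <- class_stats(hist, thresholds)
  # empty classes have weight 0 and drop out regardless of their mean
  sum(st$weights * (st$means - st$total_mean)^2)
}

check_thresholds <- function(thresholds) {
  if (length(thresholds) < 1L) stop("need at least one threshold", call. = FALSE)
  if (any(thresholds != round(thresholds))) {
    stop("thresholds must be integers", call. = FALSE)
  }
  if (any(thresholds < 0) || any(thresholds > 254)) {
    stop("thresholds must lie in [0, 254]", call. = FALSE)
  }
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  invisible(as.integer(thresholds))
}

# Prefix-sum closure for class "scores": S(a, b) = (sum_{j=a}^{b} j P_j)^2 /
# sum_{j=a}^{b} P_j, the contribution of class [a, b] to
# sum_i omega_i mu_i^2 (= sigma_B^2 + mu_T^2, a constant shift). Empty
# classes score 0. Vectorized over `b`.
class_score_fun <- function(p) {
  cp <- c(0, cumsum(p))
  cm <- c(0, cumsum((0:255) * p))
  function(a, b) {
    w <- cp[b + 2L] - cp[a + 1L]
    m <- cm[b + 2L] - cm[a + 1L]
    ifelse(w > 0, m * m / w, 0)
  }
}

#' Exact multilevel Otsu thresholds
#'
#' Finds the K strictly increasing integer thresholds maximizing the
#' between-class variance, by dynamic programming over prefix sums of the
#' histogram. The search is exact (global optimum) for any K; ties are broken
#' by the lexicographically smallest tuple. Candidate thresholds are capped at
#' the largest occupied bin plus K, which provably contains the
#' lexicographically smallest maximizer of the full \[0, 254\] search
#' (thresholds beyond the top occupied bin only delimit empty classes).
#'
#' @param hist A `gray_histogram`.
#' @param K Number of thresholds (K >= 1). The histogram must have at least
#'   K + 1 occupied bins.
#' @return Integer vector of K thresholds, strictly increasing, in \[0, 254\].
#' @examples
#' h <- histogram_from_counts(c(10, rep(0, 254), 10))
#' otsu_multilevel(h, 1)  # 0: smallest of the tied maximizers
#' @export
otsu_multilevel <- function(hist, K) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  p <- hist$probabilities
  occ <- which(p > 0) - 1L
  if (length(occ) < K + 1L) {
    stop("infeasible K: histogram has ", length(occ),
         " occupied bins, need at least ", K + 1L, call. = FALSE)
  }
  tmax <- min(max(occ) + K, 254L)
  cand <- 0:tmax
  sc <- class_score_fun(p)

  # R[[k]][t + 1]: best achievable score of classes k+1, ..., K+1 given
  # threshold k sits at t (includes the top class up to level 255).
  R <- vector("list", K)
  R[[K]] <- sc(cand + 1L, 255L)
  if (K > 1L) {
    for (k in (K - 1L):1L) {
      nxt <- R[[k + 1L]]
      rk <- rep(-Inf, length(cand))
      for (ti in seq_len(length(cand) - 1L)) {
        t <- cand[ti]
        ts <- (t + 1L):tmax
        rk[ti] <- max(sc(t + 1L, ts) + nxt[ts + 1L])
      }
      R[[k]] <- rk
    }
  }

  # Greedy left-to-right reconstruction; which.max takes the first (smallest)
  # maximizer at every stage, yielding the lexicographically smallest tuple.
  out <- integer(K)
  prev <- -1L
  for (k in seq_len(K)) {
    ts <- (prev + 1L):tmax
    val <- sc(prev + 1L, ts) + R[[k]][ts + 1L]
    prev <- ts[which.max(val)]
    out[k] <- prev
  }
  out
}

#' Single-threshold Otsu restricted to a gray-level interval
#'
#' Restricts the histogram to integer gray levels g with `lo <= g <= hi`
#' (inclusive real bounds), renormalizes, and runs the exact single-threshold
#' Otsu search on the restricted histogram. Also reports the two class means
#' within the interval. If the restricted support holds fewer than two
#' occupied bins the problem is degenerate: the midpoint
#' `floor((lo + hi) / 2)` is returned with means (lo, hi).
#'
#' @param hist A `gray_histogram`.
#' @param lo,hi Real interval bounds, `0 <= lo <= hi <= 255`.
#' @return List with `threshold` (integer), `mean_low`, `mean_high` and
#'   logical `degenerate`.
#' @export
otsu_single_in_interval <- function(hist, lo, hi) {
  if (lo > hi) stop("invalid interval: lo > hi", call. = FALSE)
  if (lo < 0 || hi > 255) stop("interval must lie within [0, 255]", call. = FALSE)
  a <- max(0L, as.integer(ceiling(lo)))
  b <- min(255L, as.integer(floor(hi)))
  p <- hist$probabilities
  occ <- if (a <= b) which(p[(a + 1L):(b + 1L)] > 0) else integer(0)
  if (length(occ) < 2L) {
    return(list(
      threshold = as.integer(floor((lo + hi) / 2)),
      mean_low = lo, mean_high = hi, degenerate = TRUE
    ))
  }
  pr <- numeric(256L)
  cr <- integer(256L)
  sel <- (a:b) + 1L
  pr[sel] <- p[sel]
  cr[sel] <- hist$counts[sel]
  hr <- structure(
    list(counts = cr, probabilities = pr / sum(pr), total_pixels = sum(cr)),
    class = "gray_histogram"
  )
  t <- otsu_multilevel(hr, 1L)
  st <- class_stats(hr, t)
  list(threshold = t, mean_low = st$means[1L], mean_high = st$means[2L],
       degenerate = FALSE)
}
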