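# Independent oracles, deliberately written against the defining formulas
# rather than the package's search machinery.

# Between-class variance straight from the class definitions: weights and
# means accumulated per class, then sum w_i (mu_i - mu_T)^2.
oracle_between_var <- function(p, thresholds) {
  bounds <- c(-1L, thresholds, 255L)
  mu_t <- sum((0:255) * p)
  acc <- 0
  for (i in seq_len(length(thresholds) + 1L)) {
    sel <- (bounds[i] + 1L):bounds[i + 1L] + 1L
    w <- sum(p[sel])
    if (w > 0) {
      mu <- sum((sel - 1L) * p[sel]) / w
      acc <- acc + w * (mu - mu_t)^2
    }
  }
  acc
}

# Exhaustive enumeration of all strictly increasing K-tuples of thresholds.
# Candidates are capped at the top occupied bin + K: thresholds beyond that
# only delimit empty classes, and any tuple using them can be remapped to
# consecutive integers just above the top bin with the same partition and a
# lexicographically smaller-or-equal tuple, so the cap preserves both the
# maximum and the lexicographically smallest argmax of the full [0, 254]
# search.
oracle_otsu <- function(p, K) {
  tmax <- min(max(which(p > 0)) - 1L + K, 254L)
  tuples <- utils::combn(0:tmax, K)
  vals <- apply(tuples, 2L, function(t) oracle_between_var(p, t))
  tuples[, which.max(vals)]  # first max = lexicographically smallest
}

# Random histogram with n_occ occupied bins at random positions.
random_histogram <- function(n_occ, max_level = 255L) {
  pos <- sort(sample.int(max_level + 1L, n_occ) - 1L)
  counts <- integer(256L)
  counts[pos + 1L] <- sample.int(50L, n_occ, replace = TRUE)
  histogram_from_counts(counts)
}

# Directed Hausdorff by the raw double loop.
oracle_hausdorff <- function(a, b) {
  h <- function(x, y) {
    max(apply(x, 1L, function(pt) {
      min(sqrt((y[, 1L] - pt[1L])^2 + (y[, 2L] - pt[2L])^2))
    }))
  }
  max(h(a, b), h(b, a))
}

# Relabeling vote by a full double loop over the disc.
oracle_relabel <- function(p, image, m1, m2, uncontested, radius = 12,
                           alpha = 1, beta = 1) {
  la <- m1[p[1L], p[2L]]
  lb <- m2[p[1L], p[2L]]
  sa <- 0
  sb <- 0
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (i == p[1L] && j == p[2L]) next
      d2 <- (i - p[1L])^2 + (j - p[2L])^2
      if (d2 > radius^2) next
      if (!uncontested[i, j]) next
      lab <- m1[i, j]
      if (lab != la && lab != lb) next
      sim <- exp(-(d2 / (2 * alpha^2) +
                     (as.numeric(image[p[1L], p[2L]]) -
                        as.numeric(image[i, j]))^2 / (2 * beta^2)))
      if (lab == la) sa <- sa + sim else sb <- sb + sim
    }
  }
  if (sa > sb) la else lb
}

# A brain-like phantom plus seeded noise, shared across tests.
test_phantom <- function(K, size = 96L, seed = 1L, jitter = 0,
                         noise = 0) {
  means <- as.integer(round(seq(15, 240, length.out = K + 1L)))
  ph <- generate_phantom(phantom_spec(size, size, means, jitter = jitter,
                                      seed = seed))
  if (noise > 0) {
    ph$image <- add_gaussian_noise(ph$image, noise, seed = seed + 5000L)
  }
  ph
}

# Vectorized exhaustive enumeration for corpus-scale checks: evaluates
# sum_i w_i (mu_i - mu_T)^2 for every strictly increasing K-tuple via prefix
# sums (a different formula path from the package's score-table DP). Tuple
# tables are cached per (K, tmax) since enumeration itself is the bottleneck.
.oracle_tuple_cache <- new.env(parent = emptyenv())

oracle_tuples <- function(tmax, K) {
  key <- paste0(K, ":", tmax)
  if (is.null(.oracle_tuple_cache[[key]])) {
    tuples <- utils::combn(0:tmax, K)
    if (K == 1L) tuples <- matrix(tuples, nrow = 1L)
    .oracle_tuple_cache[[key]] <- tuples
  }
  .oracle_tuple_cache[[key]]
}

oracle_otsu_fast <- function(p, K) {
  cp <- c(0, cumsum(p))
  cm <- c(0, cumsum((0:255) * p))
  mu_t <- cm[257L]
  tmax <- min(max(which(p > 0)) - 1L + K, 254L)
  tuples <- oracle_tuples(tmax, K)
  bounds <- rbind(rep(-1L, ncol(tuples)), tuples, rep(255L, ncol(tuples)))
  acc <- 0
  for (i in seq_len(K + 1L)) {
    w <- cp[bounds[i + 1L, ] + 2L] - cp[bounds[i, ] + 2L]
    m <- cm[bounds[i + 1L, ] + 2L] - cm[bounds[i, ] + 2L]
    # w (mu - mu_T)^2 = (m - w mu_T)^2 / w, empty classes contribute 0
    val <- (m - w * mu_t)^2 / w
    val[w == 0] <- 0
    acc <- acc + val
  }
  tuples[, which.max(acc)]  # combn order is lexicographic
}
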