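test_that("histograms count pixels and conserve mass", {
  h <- gray_histogram(matrix(c(0L, 0L, 128L, 255L), 2, 2))
  expect_equal(h$probabilities[c(1, 129, 256)], c(0.5, 0.25, 0.25))
  expect_equal(sum(h$probabilities), 1)

  hc <- gray_histogram(matrix(7L, 5, 3))
  expect_equal(hc$probabilities[8], 1)
  expect_equal(sum(hc$counts), 15)

  set.seed(11)
  hr <- gray_histogram(matrix(sample(0:255, 100, TRUE), 10, 10))
  expect_equal(sum(hr$counts), 100)
  expect_equal(sum(hr$probabilities), 1)

  expect_error(gray_histogram(matrix(c(0.5, 1, 2, 3), 2, 2)), "integer")
  expect_error(gray_histogram(matrix(c(-1L, 0L, 1L, 2L), 2, 2)), "0, 255")
})

test_that("class statistics match the defining sums", {
  spikes <- histogram_from_counts(c(10L, rep(0L, 254), 10L))
  st <- class_stats(spikes, 0L)
  expect_equal(st$weights, c(0.5, 0.5))
  expect_equal(st$means, c(0, 255))
  expect_equal(st$total_mean, 127.5)

  # degenerate empty class below all mass
  h100 <- histogram_from_counts({
    x <- integer(256)
    x[101] <- 9L
    x
  })
  st <- class_stats(h100, 50L)
  expect_equal(st$weights, c(0, 1))
  expect_equal(st$means, c(0, 100))
  expect_equal(st$total_mean, 100)

  uni <- histogram_from_counts(rep(1L, 256))
  st <- class_stats(uni, 127L)
  expect_equal(st$weights, c(0.5, 0.5))
  expect_equal(st$means, c(63.5, 191.5))

  # weights sum to total mass and reconstruct the total mean
  set.seed(21)
  for (k in 1:3) {
    h <- random_histogram(40)
    t <- sort(sample(0:254, k))
    st <- class_stats(h, t)
    expect_equal(sum(st$weights), 1)
    expect_equal(sum(st$weights * st$means), st$total_mean)
    expect_true(all(diff(st$means[st$weights > 0]) >= 0))
  }
})

test_that("between-class variance matches hand values and the variance law", {
  spikes <- histogram_from_counts(c(10L, rep(0L, 254), 10L))
  expect_equal(between_class_variance(spikes, 0L), 16256.25)
  # every separating threshold gives the same value
  vals <- vapply(0:254, function(t) between_class_variance(spikes, t),
                 numeric(1))
  expect_true(all(vals == vals[1]))

  one <- histogram_from_counts({
    x <- integer(256)
    x[43] <- 5L
    x
  })
  expect_equal(between_class_variance(one, 100L), 0)

  # law of total variance: sigma_B^2 + sum w_i Var(C_i) = Var(I)
  set.seed(31)
  for (rep in 1:20) {
    h <- random_histogram(32)
    k <- sample(1:3, 1)
    t <- sort(sample(0:254, k))
    p <- h$probabilities
    total_var <- sum((0:255)^2 * p) - sum((0:255) * p)^2
    bounds <- c(-1L, t, 255L)
    within <- 0
    for (i in seq_len(k + 1L)) {
      sel <- (bounds[i] + 1L):bounds[i + 1L] + 1L
      w <- sum(p[sel])
      if (w > 0) {
        mu <- sum((sel - 1L) * p[sel]) / w
        within <- within + w * (sum((sel - 1L)^2 * p[sel]) / w - mu^2)
      }
    }
    expect_equal(between_class_variance(h, t) + within, total_var,
                 tolerance = 1e-6)
  }
})

test_that("multilevel search equals exhaustive enumeration with lexicographic ties", {
  spikes <- histogram_from_counts(c(10L, rep(0L, 254), 10L))
  expect_identical(otsu_multilevel(spikes, 1), 0L)

  three <- histogram_from_counts({
    x <- integer(256)
    x[c(1, 129, 256)] <- 5L
    x
  })
  expect_identical(otsu_multilevel(three, 2), c(0L, 128L))

  set.seed(41)
  for (rep in 1:25) {
    h <- random_histogram(16, max_level = 63L)
    for (k in 1:3) {
      expect_identical(otsu_multilevel(h, k),
                       as.integer(oracle_otsu(h$probabilities, k)))
    }
  }

  expect_error(otsu_multilevel(spikes, 2), "infeasible")
})

test_that("variance depends only on the histogram, not pixel positions", {
  set.seed(51)
  img <- matrix(sample(0:255, 64, TRUE), 8, 8)
  shuffled <- matrix(sample(as.vector(img)), 8, 8)
  expect_equal(between_class_variance(gray_histogram(img), c(80L, 160L)),
               between_class_variance(gray_histogram(shuffled), c(80L, 160L)))
})

test_that("interval-restricted single Otsu handles restriction and degeneracy", {
  two <- histogram_from_counts({
    x <- integer(256)
    x[c(11, 21)] <- 3L
    x
  })
  res <- otsu_single_in_interval(two, 5, 25)
  expect_false(res$degenerate)
  expect_identical(res$threshold, 10L)
  expect_equal(res$mean_low, 10)
  expect_equal(res$mean_high, 20)

  one <- histogram_from_counts({
    x <- integer(256)
    x[43] <- 4L
    x
  })
  res <- otsu_single_in_interval(one, 40, 44)
  expect_true(res$degenerate)
  expect_identical(res$threshold, 42L)
  expect_equal(c(res$mean_low, res$mean_high), c(40, 44))

  # full interval is identical to the unrestricted search
  set.seed(61)
  for (rep in 1:10) {
    h <- random_histogram(24)
    expect_identical(otsu_single_in_interval(h, 0, 255)$threshold,
                     otsu_multilevel(h, 1))
  }

  expect_error(otsu_single_in_interval(two, 10, 5), "invalid interval")
})
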