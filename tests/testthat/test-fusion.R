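test_that("similarity kernel has its closed-form values and symmetry", {
  img <- matrix(0L, 5, 5)
  expect_equal(pixel_similarity(c(2, 2), c(2, 2), img), 1)
  expect_equal(pixel_similarity(c(2, 2), c(2, 3), img), exp(-0.5))
  img2 <- img
  img2[2, 2] <- 1L
  expect_equal(pixel_similarity(c(2, 2), c(2, 2) + 0L, img2), 1)
  expect_equal(pixel_similarity(c(2, 2), c(3, 2), img), exp(-0.5))
  # intensity-only difference of one gray level
  img3 <- matrix(c(10L, 11L), 1, 2)
  expect_equal(pixel_similarity(c(1, 1), c(1, 2), img3, alpha = 1e6),
               exp(-0.5), tolerance = 1e-9)
  # symmetry
  set.seed(111)
  img4 <- matrix(sample(0:255, 25, TRUE), 5, 5)
  expect_equal(pixel_similarity(c(1, 2), c(4, 5), img4, 2, 3),
               pixel_similarity(c(4, 5), c(1, 2), img4, 2, 3))
})

test_that("uncontested/controversial masks partition the image", {
  m1 <- matrix(sample(0:2, 100, TRUE), 10, 10)
  m2 <- m1
  expect_true(all(split_pixels(m1, m2)$uncontested))

  m2[4, 7] <- (m2[4, 7] + 1L) %% 3L
  parts <- split_pixels(m1, m2)
  expect_equal(sum(parts$controversial), 1)
  expect_true(all(xor(parts$uncontested, parts$controversial)))

  expect_error(split_pixels(m1, matrix(0L, 9, 10)), "incompatible")
})

test_that("relabeling matches the brute-force disc vote", {
  set.seed(121)
  for (rep in 1:8) {
    img <- matrix(sample(0:255, 400, TRUE), 20, 20)
    m1 <- matrix(sample(0:2, 400, TRUE), 20, 20)
    m2 <- m1
    flip <- sample(400, 60)
    m2[flip] <- (m2[flip] + sample(1:2, 60, TRUE)) %% 3L
    parts <- split_pixels(m1, m2)
    contested <- which(parts$controversial, arr.ind = TRUE)
    cfg <- fusion_config(radius = 5, beta = 50)
    for (i in seq_len(min(10L, nrow(contested)))) {
      p <- contested[i, ]
      expect_identical(
        relabel_pixel(p, img, m1, m2, parts$uncontested, cfg),
        oracle_relabel(p, img, m1, m2, parts$uncontested, radius = 5,
                       beta = 50)
      )
    }
  }
})

test_that("votes fall to the second map on ties and empty neighborhoods", {
  # mirror-symmetric fixture: equal similarity mass on both labels
  img <- matrix(100L, 5, 5)
  m1 <- matrix(0L, 5, 5)
  m2 <- matrix(1L, 5, 5)
  m1[3, 3] <- 0L
  m2[3, 3] <- 1L
  # uncontested ring: label 0 on the left of center, label 1 mirrored right
  m1[3, 2] <- m2[3, 2] <- 0L
  m1[3, 4] <- m2[3, 4] <- 1L
  parts <- split_pixels(m1, m2)
  cfg <- fusion_config(radius = 2)
  # independent double-loop sums confirm the tie
  sa <- pixel_similarity(c(3, 3), c(3, 2), img)
  sb <- pixel_similarity(c(3, 3), c(3, 4), img)
  expect_equal(sa, sb)
  expect_identical(relabel_pixel(c(3, 3), img, m1, m2, parts$uncontested,
                                 cfg), 1L)

  # no uncontested neighbor carries either label
  m1b <- matrix(2L, 5, 5)
  m2b <- matrix(2L, 5, 5)
  m1b[3, 3] <- 0L
  m2b[3, 3] <- 1L
  partsb <- split_pixels(m1b, m2b)
  expect_identical(relabel_pixel(c(3, 3), img, m1b, m2b, partsb$uncontested,
                                 cfg), 1L)

  # all agreeing neighbors carry l_a at identical intensity
  m2c <- m1
  m1c <- m1
  m1c[] <- 0L
  m2c[] <- 0L
  m2c[3, 3] <- 1L
  m1c[3, 3] <- 0L
  partsc <- split_pixels(m1c, m2c)
  expect_identical(relabel_pixel(c(3, 3), img, m1c, m2c, partsc$uncontested,
                                 cfg), 0L)
})

test_that("fusion is idempotent on agreement and stays within the label range", {
  set.seed(131)
  img <- matrix(sample(0:255, 144, TRUE), 12, 12)
  m <- matrix(sample(0:3, 144, TRUE), 12, 12)
  expect_identical(fuse_labels(m, m, img), m)

  m2 <- m
  flip <- sample(144, 20)
  m2[flip] <- (m2[flip] + 1L) %% 4L
  fused <- fuse_labels(m, m2, img, fusion_config(radius = 4))
  expect_true(all(fused >= 0 & fused <= 3))
  # every re-voted label comes from one of the two maps
  expect_true(all(fused == m | fused == m2))
})

test_that("fusion repairs sparse corruption inside homogeneous regions", {
  ph <- test_phantom(K = 3, seed = 9)
  truth <- ph$labels
  set.seed(141)
  m2 <- truth
  bad <- sample(length(truth), round(0.01 * length(truth)))
  m2[bad] <- (m2[bad] + sample(1:3, length(bad), TRUE)) %% 4L
  fused <- fuse_labels(truth, m2, ph$image)
  expect_gte(mean(fused == truth), 0.99)
})

test_that("fusing two corrupted maps rarely exceeds the worse input error", {
  ph <- test_phantom(K = 2, size = 48L, seed = 10)
  truth <- ph$labels
  n <- length(truth)
  set.seed(151)
  ok <- 0L
  trials <- 100L
  for (i in seq_len(trials)) {
    corrupt <- function() {
      m <- truth
      bad <- sample(n, round(0.01 * n))
      m[bad] <- (m[bad] + sample(1:2, length(bad), TRUE)) %% 3L
      m
    }
    m1 <- corrupt()
    m2 <- corrupt()
    fused <- fuse_labels(m1, m2, ph$image)
    me <- function(m) misclassification_error(m, truth)
    if (me(fused) <= max(me(m1), me(m2)) + 1e-12) ok <- ok + 1L
  }
  expect_gte(ok / trials, 0.95)
})
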