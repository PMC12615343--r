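test_that("image moments match hand-computed values", {
  m <- matrix(0, 6, 6)
  m[5, 4] <- 1                      # x = 3, y = 4 (0-based pixel centers)
  g <- image_moments(m)
  expect_equal(c(g$area, g$cx, g$cy, g$inertia), c(1, 3, 4, 0))
  m2 <- matrix(0, 3, 4)
  m2[1, 1] <- 1; m2[1, 3] <- 1       # pixels at (0,0) and (2,0)
  g2 <- image_moments(m2)
  expect_equal(c(g2$area, g2$cx, g2$m20, g2$m02), c(2, 1, 2, 0))
  expect_error(image_moments(matrix(0, 3, 3)), "empty")
})

test_that("moments of a rasterized annulus match the closed forms", {
  r1 <- 200; r2 <- 310
  mask <- render_annulus_mask(r1, r2, 640)
  g <- image_moments(mask)
  expect_lt(abs(g$area / (pi * (r2^2 - r1^2)) - 1), 0.005)
  expect_lt(abs(g$inertia / (pi / 2 * (r2^4 - r1^4)) - 1), 0.005)
  rad <- annulus_radii(g$area, g$inertia)
  expect_lt(abs(rad$r1 / r1 - 1), 0.01)
  expect_lt(abs(rad$r2 / r2 - 1), 0.01)
  # centroid sits at the frame center
  expect_equal(g$cx, 640 / 2 - 0.5, tolerance = 0.01)
})

test_that("exact annulus moments invert to the radii at machine precision", {
  for (rr in list(c(30, 60), c(1, 2), c(150, 151), c(100, 500))) {
    A <- pi * (rr[2]^2 - rr[1]^2)
    I <- pi / 2 * (rr[2]^4 - rr[1]^4)
    rad <- annulus_radii(A, I)
    expect_equal(c(rad$r1, rad$r2), rr, tolerance = 1e-12)
    expect_false(rad$clamped)
  }
  # solid-disk limit: R1 exactly 0
  R <- 42
  rad <- annulus_radii(pi * R^2, pi / 2 * R^4)
  expect_identical(rad$r1, 0)
  expect_equal(rad$r2, R, tolerance = 1e-12)
  # unphysical pair clamps and flags
  rad2 <- annulus_radii(pi * R^2, 0.1 * pi / 2 * R^4)
  expect_true(rad2$clamped)
  expect_identical(rad2$r1, 0)
  expect_error(annulus_radii(0, 1), "positive")
})

test_that("quarter binarization thresholds at a multiple of the mean", {
  expect_true(all(binarize_quarter(matrix(5, 10, 10)) == 0))
  q <- matrix(c(2, 0), 10, 10)       # mean 1: exactly the 2-valued pixels set
  expect_identical(binarize_quarter(q), (q == 2) * 1)
})

test_that("the deviation metric is zero for a perfect print and linear in one term", {
  perfect <- image_moments(matrix(1, 2, 2))
  perfect$r1 <- 100; perfect$r2 <- 134
  perfect$cx <- 134; perfect$cy <- 134
  expect_equal(dev_metric(perfect)$dev, 0)
  off <- perfect
  off$r1 <- 100; off$r2 <- 144       # ratio 1.44 = target + 0.1
  off$cx <- off$cy <- 144            # centroid still on target (R2, R2)
  expect_equal(dev_metric(off)$dev, 0.1, tolerance = 1e-12)
  # weight vector with equal entries reproduces the unweighted form
  off$cx <- 150; off$cy <- 140
  expect_equal(dev_metric(off, weights = c(5, 5, 5))$dev,
               dev_metric(off)$dev)
  # scale invariance: all pixel quantities scaled together
  sc <- off
  for (f in c("r1", "r2", "cx", "cy")) sc[[f]] <- off[[f]] * 3.7
  expect_equal(dev_metric(sc)$dev, dev_metric(off)$dev, tolerance = 1e-12)
  # r1 = 0 leaves Dev undefined but flagged
  off$r1 <- 0
  u <- dev_metric(off)
  expect_true(u$undefined)
  expect_true(is.na(u$dev))
})

test_that("entropy weights match an independent implementation", {
  # identical columns share the weight equally
  m <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)
  expect_equal(entropy_weights(m), rep(1 / 3, 3))
  # constant columns carry no information
  m2 <- cbind(c(1, 5, 2, 8), rep(2, 4), rep(7, 4))
  expect_equal(entropy_weights(m2), c(1, 0, 0))
  # all-zero column gets weight zero
  m3 <- cbind(c(1, 5, 2, 8), rep(0, 4), c(2, 1, 4, 3))
  expect_equal(sum(entropy_weights(m3)), 1)
  expect_identical(entropy_weights(m3)[2], 0)
  # independent oracle on a random matrix
  oracle <- function(mat) {
    n <- nrow(mat)
    e <- numeric(ncol(mat))
    for (j in seq_len(ncol(mat))) {
      p <- mat[, j] / sum(mat[, j])
      s <- 0
      for (i in seq_len(n)) if (p[i] > 0) s <- s - p[i] * log(p[i])
      e[j] <- s / log(n)
    }
    (1 - e) / sum(1 - e)
  }
  withr::with_seed(21, {
    mat <- matrix(runif(30), 10, 3)
    expect_equal(entropy_weights(mat), oracle(mat), tolerance = 1e-12)
    # permutation equivariance in columns
    perm <- c(3, 1, 2)
    expect_equal(entropy_weights(mat[, perm]), entropy_weights(mat)[perm],
                 tolerance = 1e-14)
    # invariance to positive rescaling of a column
    mat2 <- mat; mat2[, 2] <- mat2[, 2] * 17.3
    expect_equal(entropy_weights(mat2), entropy_weights(mat),
                 tolerance = 1e-12)
  })
  expect_error(entropy_weights(matrix(1, 1, 3)), "2 rows")
  expect_error(entropy_weights(matrix(-1, 3, 3)), "non-negative")
})
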