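# Bilinear fusion head: pooling identities, normalisation invariants, and
# agreement with the triple-loop oracle.

test_that("one-hot channel vectors at a single position give a one-hot outer product", {
  f <- array(0, c(1, 1, 4)); f[1, 1, 2] <- 1
  b <- bilinear_pool(f, f)
  expected <- matrix(0, 4, 4); expected[2, 2] <- 1
  expect_equal(b, expected)
})

test_that("constant feature maps give P times the outer product", {
  a <- c(1, -2, 3); b <- c(0.5, 2, -1, 4)
  f1 <- array(rep(a, each = 6), c(2, 3, 3))
  f2 <- array(rep(b, each = 6), c(2, 3, 4))
  expect_equal(bilinear_pool(f1, f2), 6 * outer(a, b), tolerance = 1e-12)
})

test_that("bilinear pooling matches the triple-loop oracle", {
  for (s in 1:5) {
    f1 <- rand_fm(2, 2, 3, seed = s)
    f2 <- rand_fm(2, 2, 4, seed = s + 100)
    expect_equal(bilinear_pool(f1, f2), oracle_bilinear(f1, f2),
                 tolerance = 1e-6)
  }
})

test_that("spatial mismatch is rejected naming both shapes", {
  f1 <- rand_fm(2, 3, 2, seed = 1)
  f2 <- rand_fm(3, 3, 2, seed = 2)
  expect_error(bilinear_pool(f1, f2), "2x3x2.*3x3x2")
})

test_that("signed square root handles perfect squares, oddness and zero", {
  expect_equal(signed_sqrt(4), 2)
  expect_equal(signed_sqrt(-9), -3)
  expect_equal(signed_sqrt(0), 0)
  set.seed(11)
  z <- rnorm(50)
  expect_identical(signed_sqrt(-z), -signed_sqrt(z))  # odd, exactly
  expect_true(all(diff(signed_sqrt(sort(z))) >= 0))   # order-preserving
})

test_that("l2 normalisation gives unit vectors and guards the zero vector", {
  expect_equal(l2_normalize(c(3, 4)), c(0.6, 0.8), tolerance = 1e-9)
  expect_equal(l2_normalize(c(0, 0, 0)), c(0, 0, 0))
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(20)
    expect_equal(sqrt(sum(l2_normalize(x)^2)), 1, tolerance = 1e-6)
  }
})

test_that("fused descriptor of two 128-channel maps has length 16384 and unit norm", {
  f1 <- rand_fm(15, 45, 128, seed = 21)
  f2 <- rand_fm(15, 45, 128, seed = 22)
  y <- fuse(f1, f2)
  expect_length(y, 16384L)
  expect_equal(sqrt(sum(y^2)), 1, tolerance = 1e-6)
})

test_that("fusing a map with itself gives a symmetric positive semidefinite matrix", {
  f <- rand_fm(3, 4, 5, seed = 23)
  b <- bilinear_pool(f, f)
  expect_equal(b, t(b), tolerance = 1e-10)
  expect_true(min(eigen(b, symmetric = TRUE, only.values = TRUE)$values) > -1e-8)
})

test_that("fuse equals composing pool, signed sqrt and normalisation", {
  f1 <- rand_fm(4, 5, 3, seed = 24)
  f2 <- rand_fm(4, 5, 6, seed = 25)
  manual <- l2_normalize(signed_sqrt(as.vector(bilinear_pool(f1, f2))))
  expect_equal(fuse(f1, f2), manual, tolerance = 1e-12)
})

test_that("the normalised descriptor is invariant to rescaling both inputs", {
  f1 <- rand_fm(3, 3, 4, seed = 26)
  f2 <- rand_fm(3, 3, 4, seed = 27)
  expect_equal(bilinear_pool(2.5 * f1, f2), 2.5 * bilinear_pool(f1, f2),
               tolerance = 1e-9)
  expect_equal(fuse(3 * f1, 3 * f2), fuse(f1, f2), tolerance = 1e-9)
})
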