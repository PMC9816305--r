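# Convolutional primitives: shape contracts, identity cases, and agreement
# with brute-force loop oracles.

test_that("conv_block preserves spatial size and sets the channel count", {
  x <- rand_fm(60, 180, 1, seed = 1)
  w <- conv_weights(kernel_spec(3), 1, 64, seed = 1)
  y <- conv_block(x, w)
  expect_identical(dim(y), c(60L, 180L, 64L))
})

test_that("conv_block with zero weights gives a zero pre-activation output", {
  x <- rand_fm(6, 9, 2, seed = 2)
  w <- conv_weights(kernel_spec(3), 2, 4, init = "zero")
  expect_true(all(conv_block(x, w, activation = "linear") == 0))
})

test_that("1x1 identity kernel reproduces the activated input", {
  x <- rand_fm(5, 7, 1, seed = 3)
  w <- conv_weights(kernel_spec(1), 1, 1, init = "zero")
  w$w[1, 1, 1, 1] <- 1
  expect_equal(conv_block(x, w), pmax(x, 0), tolerance = 1e-12)
  expect_equal(conv_block(x, w, activation = "linear"), x, tolerance = 1e-12)
})

test_that("conv_block matches the quadruple-loop oracle, incl. dilation", {
  cases <- expand.grid(k = c(1L, 3L), dil = c(1L, 2L), seed = 1:3)
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]; dil <- cases$dil[i]; s <- cases$seed[i]
    x <- rand_fm(7, 9, 3, seed = s)
    w <- conv_weights(kernel_spec(k, dil), 3, 2, seed = s + 10)
    set.seed(s); w$b <- rnorm(2)
    expect_equal(conv_block(x, w, activation = "linear"),
                 oracle_conv2d(x, w$w, w$b, dil), tolerance = 1e-6)
  }
})

test_that("depthwise-separable conv with delta/identity kernels is the identity", {
  x <- rand_fm(6, 8, 3, seed = 4)
  w <- dsconv_weights(kernel_spec(3), 3, 3, init = "zero")
  w$dw[2, 2, ] <- 1                    # centred delta per channel
  w$pw <- diag(3)                      # identity mixing
  expect_equal(depthwise_separable_conv(x, w, activation = "linear"), x,
               tolerance = 1e-12)
})

test_that("depthwise-separable conv matches the explicit channel-loop oracle", {
  for (s in 1:4) {
    x <- rand_fm(8, 8, 4, seed = s)
    w <- dsconv_weights(kernel_spec(3), 4, 5, seed = s)
    set.seed(s + 50); w$dw_b <- rnorm(4); w$pw_b <- rnorm(5)
    expect_equal(depthwise_separable_conv(x, w, activation = "linear"),
                 oracle_dsconv(x, w), tolerance = 1e-6)
  }
})

test_that("depthwise-separable parameter count follows the closed form", {
  w <- dsconv_weights(kernel_spec(3), 64, 64)
  n <- length(w$dw) + length(w$dw_b) + length(w$pw) + length(w$pw_b)
  expect_identical(n, 64L * 9L + 64L * 64L + 64L + 64L)
})

test_that("single-group mixconv equals depthwise-separable conv with the same weights", {
  x <- rand_fm(6, 10, 4, seed = 5)
  mw <- mixconv_weights(mixconv_spec(list(kernel_spec(3)), 4, 6), seed = 5)
  dw <- dsconv_weights(kernel_spec(3), 4, 6)
  dw$dw <- mw$groups[[1]]$dw; dw$dw_b <- mw$groups[[1]]$dw_b
  dw$pw <- mw$groups[[1]]$pw; dw$pw_b <- mw$groups[[1]]$pw_b
  expect_equal(mixconv(x, mw), depthwise_separable_conv(x, dw),
               tolerance = 1e-6)
})

test_that("mixconv with mixed dense/dilated groups keeps the published shape", {
  x <- rand_fm(15, 45, 64, seed = 6)
  spec <- mixconv_spec(list(kernel_spec(3), kernel_spec(3, 2)), 64, 128)
  y <- mixconv(x, mixconv_weights(spec, seed = 6))
  expect_identical(dim(y), c(15L, 45L, 128L))
})

test_that("mixconv matches the brute-force group oracle", {
  for (s in 1:4) {
    x <- rand_fm(6, 6, 4, seed = s + 20)
    spec <- mixconv_spec(list(kernel_spec(3), kernel_spec(3, 2)), 4, 6)
    w <- mixconv_weights(spec, seed = s)
    expect_equal(mixconv(x, w, activation = "linear"), oracle_mixconv(x, w),
                 tolerance = 1e-6)
  }
})

test_that("odd channel counts put the remainder in the first group", {
  idx <- msfbfnet:::split_channels(7L, 2L)
  expect_identical(idx[[1]], 1:4)
  expect_identical(idx[[2]], 5:7)
})

test_that("dilated 3x3 depthwise kernel equals a 5x5 kernel scattered on the dilation grid", {
  x <- rand_fm(9, 11, 2, seed = 7)
  set.seed(7)
  w3 <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  w5 <- array(0, c(5, 5, 2))
  w5[c(1, 3, 5), c(1, 3, 5), ] <- w3
  b <- rnorm(2)
  y3 <- msfbfnet:::cpp_dwconv_fwd(x, w3, b, 2L)
  y5 <- msfbfnet:::cpp_dwconv_fwd(x, w5, b, 1L)
  expect_equal(y3, y5, tolerance = 1e-6)
})

test_that("max pooling halves the grid and takes window maxima", {
  x <- rand_fm(60, 180, 64, seed = 8)
  expect_identical(dim(max_pool(x, 2)), c(30L, 90L, 64L))
  expect_equal(max_pool(array(3.5, c(4, 4, 2)), 2),
               array(3.5, c(2, 2, 2)))
  x1 <- array(c(1, 3, 5, 2), c(2, 2, 1))   # column-major: [[1,5],[3,2]]
  expect_equal(as.vector(max_pool(x1, 2)), 5)
  # spatial consistency: pooled value is the max of its window
  p <- max_pool(x, 2)
  expect_equal(p[1, 1, 1], max(x[1:2, 1:2, 1]))
  expect_equal(p[7, 11, 33], max(x[13:14, 21:22, 33]))
})

test_that("invalid inputs are rejected with clear diagnostics", {
  x <- rand_fm(4, 4, 2, seed = 9)
  xb <- x; xb[1] <- NA
  w <- conv_weights(kernel_spec(3), 2, 2)
  expect_error(conv_block(xb, w), "non-finite")
  expect_error(max_pool(x, 0), "positive integer")
  expect_error(kernel_spec(4), "odd")
  expect_error(mixconv_spec(list(kernel_spec(3)), 4, 0), "positive integer")
  expect_error(mixconv(x, mixconv_weights(mixconv_spec(list(kernel_spec(3)), 5, 4))),
               "channels")
  expect_error(conv_block(x, conv_weights(kernel_spec(3), 3, 2)), "channels")
})
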