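# Multiple attention mechanism: pooling arithmetic, gate range, the
# zero-initialisation fixed point, attenuation, and loop-oracle agreement.

test_that("coordinate pooling computes exact directional means", {
  x <- array(0, c(2, 2, 1))
  x[, , 1] <- matrix(c(1, 5, 3, 7), 2, 2)   # rows: [1,3], [5,7]
  d <- coord_pool(x)
  expect_equal(as.vector(d$s_h), c(2, 6))
  expect_equal(as.vector(d$s_w), c(3, 5))
})

test_that("coordinate pooling of a constant map is constant, and means agree globally", {
  xc <- array(2.25, c(4, 6, 3))
  d <- coord_pool(xc)
  expect_true(all(d$s_h == 2.25) && all(d$s_w == 2.25))
  x <- rand_fm(5, 7, 2, seed = 31)
  d <- coord_pool(x)
  expect_equal(mean(d$s_h), mean(x), tolerance = 1e-12)
  expect_equal(mean(d$s_w), mean(x), tolerance = 1e-12)
  o <- oracle_coord_pool(x)
  expect_equal(d$s_h, o$s_h, tolerance = 1e-12)
  expect_equal(d$s_w, o$s_w, tolerance = 1e-12)
})

test_that("zero-initialised attention convolutions give gates of exactly 0.5", {
  x <- rand_fm(4, 6, 8, seed = 32)
  w0 <- mam_weights(8, init = "zero")
  g <- coord_gates(coord_pool(x), w0)
  expect_true(all(g$g_h == 0.5) && all(g$g_w == 0.5))
  expect_true(all(spatial_gate(x, w0) == 0.5))
})

test_that("all gates lie strictly inside (0, 1)", {
  for (s in 1:5) {
    x <- rand_fm(4, 5, 8, seed = s + 40) * 3
    w <- mam_weights(8, seed = s)
    g <- coord_gates(coord_pool(x), w)
    sp <- spatial_gate(x, w)
    vals <- c(g$g_h, g$g_w, sp)
    expect_true(all(vals > 0 & vals < 1))
  }
})

test_that("channel-degenerate maps make the avg and max descriptors coincide", {
  x <- rand_fm(5, 6, 1, seed = 44)
  x <- array(rep(x[, , 1], 4), c(5, 6, 4))   # constant across channels
  m <- msfbfnet:::fm_mat(x)
  expect_equal(rowMeans(m), msfbfnet:::apply_rowmax(m), tolerance = 1e-12)
})

test_that("spatial gate has one channel and the input grid", {
  x <- rand_fm(15, 45, 64, seed = 45)
  g <- spatial_gate(x, mam_weights(64, seed = 1))
  expect_identical(dim(g), c(15L, 45L))
})

test_that("zero-initialised MAM halves its input exactly", {
  x <- rand_fm(6, 10, 8, seed = 46)
  y <- mam(x, mam_weights(8, init = "zero"))
  expect_identical(y, x / 2)
})

test_that("MAM preserves shape and attenuates elementwise", {
  shapes <- list(c(3, 5, 4), c(8, 6, 10), c(15, 45, 16))
  for (i in seq_along(shapes)) {
    d <- shapes[[i]]
    x <- rand_fm(d[1], d[2], d[3], seed = i + 50)
    y <- mam(x, mam_weights(d[3], seed = i))
    expect_identical(dim(y), dim(x))
    expect_true(all(abs(y) <= abs(x)))
  }
})

test_that("MAM matches the explicit-broadcast loop oracle", {
  for (s in 1:4) {
    x <- rand_fm(8, 6, 10, seed = s + 60)
    w <- mam_weights(10, seed = s)
    expect_equal(mam(x, w), oracle_mam(x, w), tolerance = 1e-6)
  }
})

test_that("attention overhead stays below 0.05 M parameters", {
  lw <- msfbf_audit("lightweight", num_classes = 492)
  ma <- msfbf_audit("lightweight_mam", num_classes = 492)
  expect_lt(ma$total_params - lw$total_params, 5e4)
})
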