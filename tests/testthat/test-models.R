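# Assembled variants: output shapes, branch geometry, determinism, and
# parameter ordering across variants.

test_that("both branches enter the fusion head as 15 x 45 x 128 maps", {
  m <- msfbf_build("lightweight", num_classes = 5, seed = 1)
  x <- array(runif(60 * 180), c(60, 180, 1))
  fw <- msfbfnet:::net_forward(m$params, m$config, x, keep = TRUE)
  expect_identical(dim(fw$cache$shallow_map), c(15L, 45L, 128L))
  expect_identical(dim(fw$cache$deep_map), c(15L, 45L, 128L))
  expect_length(fw$cache$feat, 16384L)
})

test_that("forward of a 492-class model yields 492 logits", {
  m <- msfbf_build("lightweight", num_classes = 492, seed = 2)
  set.seed(3)
  x <- array(runif(60 * 180), c(60, 180, 1))
  fw <- msfbfnet:::net_forward(m$params, m$config, x)
  expect_length(fw$logits, 492L)
  expect_true(all(is.finite(fw$logits)))
})

test_that("a batch gives one logit row per image, identical for duplicated images", {
  m <- tiny_model("lightweight_mam", nc = 4L, seed = 4L)
  set.seed(5)
  one <- matrix(runif(12 * 20), 12, 20)
  batch <- array(NA_real_, c(12, 20, 8))
  for (i in 1:8) batch[, , i] <- if (i %% 2 == 0) one else one * 0.5
  lg <- predict(m, batch, type = "logit")
  expect_identical(dim(lg), c(8L, 4L))
  expect_identical(lg[2, ], lg[4, ])   # duplicated images, identical rows
  expect_identical(lg[1, ], lg[7, ])
  expect_false(isTRUE(all.equal(lg[1, ], lg[2, ])))
})

test_that("forward is bit-identical across repeated runs", {
  m <- tiny_model("lightweight_mam", nc = 3L, seed = 6L)
  set.seed(7)
  x <- array(runif(12 * 20), c(12, 20, 1))
  a <- msfbfnet:::net_forward(m$params, m$config, x)$logits
  b <- msfbfnet:::net_forward(m$params, m$config, x)$logits
  expect_identical(a, b)
})

test_that("a zero final classifier yields uniform logits for any image", {
  m <- tiny_model("lightweight", nc = 5L, seed = 8L)
  m$params$fc$w[] <- 0
  m$params$fc$b[] <- 0
  x <- array(0, c(12, 20, 1))
  lg <- msfbfnet:::net_forward(m$params, m$config, x)$logits
  expect_true(all(lg == lg[1]))
})

test_that("wrong input size and unknown variants are rejected", {
  m <- msfbf_build("lightweight", num_classes = 3, seed = 1)
  expect_error(msfbfnet:::net_forward(m$params, m$config,
                                      array(0, c(30, 90, 1))),
               "60x180")
  expect_error(msfbf_build("resnet", num_classes = 3), "unknown variant")
  expect_error(msfbf_config("lightweight", num_classes = 1), "at least 2")
})

test_that("parameter counts order across variants as expected", {
  nf <- n_parameters(msfbf_build("full", 492, seed = 1))
  nl <- n_parameters(msfbf_build("lightweight", 492, seed = 1))
  nm <- n_parameters(msfbf_build("lightweight_mam", 492, seed = 1))
  expect_gte(nf, nl)
  expect_lte(nm - nl, 5e4)
})

test_that("checkpoints round-trip through save/load with identical predictions", {
  m <- tiny_model("lightweight_mam", nc = 3L, seed = 11L)
  path <- tempfile(fileext = ".rds")
  save_msfbf(m, path)
  m2 <- load_msfbf(path)
  set.seed(12)
  x <- array(runif(12 * 20), c(12, 20, 1))
  expect_identical(predict(m, x, type = "logit"),
                   predict(m2, x, type = "logit"))
  saveRDS(list(a = 1), path)
  expect_error(load_msfbf(path), "not an msfbf checkpoint")
})
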