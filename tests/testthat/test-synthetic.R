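# Synthetic vein-image generator: determinism, value range, split
# arithmetic, and class separability.

test_that("rendering is deterministic given template, params and seed", {
  tpl <- vein_template(3, seed = 7)
  pars <- sample_params(seed = 11)
  a <- render_vein(tpl, pars, seed = 5)
  b <- render_vein(tpl, pars, seed = 5)
  expect_identical(a, b)
})

test_that("zero jitter and zero noise make renders seed-independent", {
  tpl <- vein_template(1, seed = 2)
  pars <- sample_params(noise_sd = 0)
  a <- render_vein(tpl, pars, seed = 1)
  b <- render_vein(tpl, pars, seed = 99)
  expect_identical(a, b)
})

test_that("rendered images are 60 x 180 with values in [0, 1]", {
  img <- render_vein(vein_template(2, seed = 3), sample_params(seed = 4),
                     seed = 6)
  expect_identical(dim(img), c(60L, 180L))
  expect_true(all(img >= 0 & img <= 1))
  expect_gt(diff(range(img)), 0.1)   # veins actually darken the background
})

test_that("the 1:5 split is disjoint, exhaustive and exact per class", {
  ds <- generate_vein_dataset(10, 6, seed = 1)
  expect_length(ds$labels, 60L)
  expect_identical(as.vector(table(ds$split)), c(50L, 10L))
  per_class <- table(ds$labels, ds$split)
  expect_true(all(per_class[, "train"] == 5L))
  expect_true(all(per_class[, "test"] == 1L))
  expect_error(generate_vein_dataset(2, 5), "at least 6")
})

test_that("the full published protocol size is reproduced at manifest level", {
  ds <- generate_vein_dataset(492, 12, seed = 1, render = FALSE)
  expect_identical(nrow(ds$manifest), 5904L)
  per_class <- table(ds$labels, ds$split)
  expect_true(all(per_class[, "train"] == 10L))
  expect_true(all(per_class[, "test"] == 2L))
})

test_that("datasets are reproducible by seed and differ across seeds", {
  a <- generate_vein_dataset(3, 6, seed = 5)
  b <- generate_vein_dataset(3, 6, seed = 5)
  c <- generate_vein_dataset(3, 6, seed = 6)
  expect_identical(a$images, b$images)
  expect_gt(max(abs(a$images - c$images)), 0.05)
})

test_that("classes are separable: inter-class distance exceeds intra-class", {
  ds <- generate_vein_dataset(10, 6, seed = 3)
  X <- t(apply(ds$images, 3, c))
  D <- as.matrix(dist(X))
  same <- outer(ds$labels, ds$labels, "==") & upper.tri(D)
  diff_ <- !outer(ds$labels, ds$labels, "==") & upper.tri(D)
  expect_gt(mean(D[diff_]), mean(D[same]))
})

test_that("a nearest-centroid pixel baseline beats chance but stays imperfect", {
  ds <- generate_vein_dataset(10, 12, seed = 2)
  tr <- ds$split == "train"
  Xtr <- t(apply(ds$images[, , tr], 3, c)); ytr <- ds$labels[tr]
  Xte <- t(apply(ds$images[, , !tr], 3, c)); yte <- ds$labels[!tr]
  cent <- sapply(levels(ytr), function(l) colMeans(Xtr[ytr == l, , drop = FALSE]))
  pred <- levels(ytr)[apply(Xte, 1, function(v) which.min(colSums((cent - v)^2)))]
  acc <- mean(pred == as.character(yte))
  expect_gt(acc, 0.5)
})
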