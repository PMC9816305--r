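# Procedural generator of labelled finger-vein-like images.
#
# Each identity (class) owns a fixed template: a few smooth dark curvilinear
# strokes running along the long axis of the frame, like subcutaneous veins
# seen in near-infrared transmission. Each sample re-renders the template
# under small acquisition perturbations — translation, rotation, brightness/
# contrast jitter, blur and sensor noise — so that within-class variation is
# realistic while class identity is preserved. All randomness flows from
# explicit seeds; no global RNG state is consumed.

#' Create a per-class vein template
#'
#' Draws 2-5 smooth curves (cubic splines through 4-6 control points biased
#' to run along the 180-px axis), each with its own stroke width and
#' darkening, plus an occasional short branch. The template is a
#' deterministic function of `(class_id, seed)`.
#'
#' @param class_id integer identity label.
#' @param seed master seed; the template seed is derived from both.
#' @return Object of class `vein_template`.
#' @export
vein_template <- function(class_id, seed = 1L) {
  class_id <- check_positive_int(class_id, "class_id")
  tseed <- derive_seeds(seed, class_id + 1L)[class_id + 1L]
  curves <- with_seed(tseed, {
    n_curves <- sample(2:5, 1L)
    out <- vector("list", n_curves)
    for (i in seq_len(n_curves)) {
      n_ctrl <- sample(4:6, 1L)
      cx <- sort(runif(n_ctrl, 0.03, 0.97))
      y0 <- runif(1L, 0.15, 0.85)
      cy <- pmin(0.92, pmax(0.08, y0 + cumsum(c(0, rnorm(n_ctrl - 1L, 0, 0.12)))))
      out[[i]] <- list(cx = cx, cy = cy,
                       width = runif(1L, 2, 5),
                       darkening = runif(1L, 0.25, 0.45))
    }
    # occasional short branch forking off the first curve
    if (runif(1L) < 0.5) {
      base <- out[[1L]]
      j <- sample(seq_along(base$cx), 1L)
      bx <- sort(runif(3L, base$cx[j], min(1, base$cx[j] + 0.35)))
      by <- pmin(0.92, pmax(0.08, base$cy[j] + cumsum(c(0, rnorm(2L, 0, 0.1)))))
      out[[length(out) + 1L]] <- list(cx = bx, cy = by,
                                      width = runif(1L, 2, 3.5),
                                      darkening = runif(1L, 0.25, 0.4))
    }
    out
  })
  structure(list(class_id = class_id, seed = tseed, curves = curves),
            class = "vein_template")
}

#' Per-sample acquisition perturbations
#'
#' @param translation pixel shift `c(dy, dx)`; drawn uniformly in +/- 3 when
#'   sampled.
#' @param rotation degrees about the image centre; +/- 4 when sampled.
#' @param brightness additive offset; +/- 0.08 when sampled.
#' @param contrast multiplicative factor about mid-grey; 0.9-1.1 when sampled.
#' @param noise_sd standard deviation of additive Gaussian sensor noise.
#' @param blur_sigma Gaussian blur in pixels.
#' @param seed when given, the jitter fields are drawn at random from the
#'   ranges above instead of using the arguments.
#' @return Object of class `sample_params`.
#' @export
sample_params <- function(translation = c(0, 0), rotation = 0,
                          brightness = 0, contrast = 1,
                          noise_sd = 0.03, blur_sigma = 0.7, seed = NULL) {
  if (!is.null(seed)) {
    v <- with_seed(seed, c(runif(2L, -3, 3), runif(1L, -4, 4),
                           runif(1L, -0.08, 0.08), runif(1L, 0.9, 1.1)))
    translation <- v[1:2]; rotation <- v[3L]
    brightness <- v[4L]; contrast <- v[5L]
  }
  structure(list(translation = translation, rotation = rotation,
                 brightness = brightness, contrast = contrast,
                 noise_sd = noise_sd, blur_sigma = blur_sigma),
            class = "sample_params")
}

# Dense polyline along a template curve, in pixel coordinates of an h x w
# frame, after the rigid per-sample perturbation.
curve_points <- function(curve, params, h, w) {
  n <- max(16L, as.integer(4 * w * (max(curve$cx) - min(curve$cx))))
  sp <- stats::spline(curve$cx, curve$cy, n = n, method = "natural")
  px <- sp$x * (w - 1) + 1
  py <- sp$y * (h - 1) + 1
  th <- params$rotation * pi / 180
  cxp <- (w + 1) / 2; cyp <- (h + 1) / 2
  rx <- cos(th) * (px - cxp) - sin(th) * (py - cyp) + cxp + params$translation[2L]
  ry <- sin(th) * (px - cxp) + cos(th) * (py - cyp) + cyp + params$translation[1L]
  cbind(ry, rx)
}

# Stamp anti-aliased strokes: ink is the max over curve points of a Gaussian
# radial falloff, scaled by the curve's darkening.
rasterize_curves <- function(curves, params, h, w) {
  ink <- matrix(0, h, w)
  for (curve in curves) {
    pts <- curve_points(curve, params, h, w)
    sw <- curve$width / 2
    rad <- ceiling(2.5 * sw)
    for (i in seq_len(nrow(pts))) {
      cy <- pts[i, 1L]; cx <- pts[i, 2L]
      r0 <- max(1L, floor(cy - rad)); r1 <- min(h, ceiling(cy + rad))
      c0 <- max(1L, floor(cx - rad)); c1 <- min(w, ceiling(cx + rad))
      if (r0 > r1 || c0 > c1) next
      dy2 <- (r0:r1 - cy)^2
      dx2 <- (c0:c1 - cx)^2
      stamp <- curve$darkening * exp(-outer(dy2, dx2, "+") / (2 * sw^2))
      ink[r0:r1, c0:c1] <- pmax(ink[r0:r1, c0:c1], stamp)
    }
  }
  ink
}

# Smooth multiplicative background field: a coarse uniform grid upsampled
# with splines, mimicking uneven NIR illumination.
background_field <- function(h, w, seed) {
  with_seed(seed, {
    gh <- 5L; gw <- 9L
    coarse <- matrix(runif(gh * gw, 0.85, 1.15), gh, gw)
    rows <- t(apply(coarse, 1L, function(v)
      stats::spline(seq(0, 1, length.out = gw), v, n = w)$y))
    apply(rows, 2L, function(v)
      stats::spline(seq(0, 1, length.out = gh), v, n = h)$y)
  })
}

# Edge-corrected Gaussian blur via a depthwise convolution.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  half <- (k - 1L) / 2L
  g1 <- exp(-(-half:half)^2 / (2 * sigma^2))
  ker <- array(outer(g1, g1), c(k, k, 1L))
  ker <- ker / sum(ker)
  num <- cpp_dwconv_fwd(array(img, c(dim(img), 1L)), ker, 0, 1L)
  den <- cpp_dwconv_fwd(array(1, c(dim(img), 1L)), ker, 0, 1L)
  (num / den)[, , 1L]
}

#' Render one synthetic vein image
#'
#' Produces a 60 x 180 grayscale image in `[0, 1]`: a bright smooth
#' background (low-frequency multiplicative illumination field times base
#' intensity 0.7) with dark anti-aliased strokes along the perturbed
#' skeleton, followed by blur, brightness/contrast jitter and additive
#' Gaussian noise. Deterministic given `(template, params, seed)`.
#'
#' @param template a [vein_template()].
#' @param params a [sample_params()].
#' @param seed seed for the background field and sensor noise.
#' @param height,width image size in pixels.
#' @return `height x width` numeric matrix in `[0, 1]`.
#' @export
render_vein <- function(template, params = sample_params(), seed = 1L,
                        height = 60L, width = 180L) {
  stopifnot(inherits(template, "vein_template"),
            inherits(params, "sample_params"))
  # the illumination field belongs to the finger, not the acquisition:
  # it derives from the template seed so a class keeps its background
  bg <- 0.7 * background_field(height, width, template$seed)
  ink <- rasterize_curves(template$curves, params, height, width)
  img <- bg * (1 - ink)
  img <- gaussian_blur(img, params$blur_sigma)
  img <- (img - 0.5) * params$contrast + 0.5 + params$brightness
  if (params$noise_sd > 0)
    img <- img + with_seed(seed,
                           matrix(rnorm(height * width, 0, params$noise_sd),
                                  height, width))
  pmin(pmax(img, 0), 1)
}

#' Generate a labelled synthetic vein dataset
#'
#' Renders `n_per_class` images for each of `n_classes` identities and
#' splits them per class at the published 1:5 test:train ratio (one sixth of
#' the images held out). With `dir` set, images are also written as PNG in a
#' class-per-directory layout together with a `manifest.csv`
#' (path, class_id, split) — the same layout [read_image_folder()] consumes.
#'
#' @param n_classes number of identities.
#' @param n_per_class images per identity; at least 6, ideally a multiple
#'   of 6 (mirroring six acquisitions per finger).
#' @param seed master seed; templates and all per-sample jitter derive from
#'   it deterministically.
#' @param dir optional output directory for PNG files.
#' @param render set to `FALSE` to build only the manifest and split
#'   (no pixel data) — useful for protocol-level checks at large scale.
#' @return Object of class `vein_dataset`: `images` (`60 x 180 x N` array,
#'   or `NULL` when `render = FALSE`), `labels` (factor `class_###`),
#'   `split` (`"train"`/`"test"`), `manifest` (data frame).
#' @examples
#' ds <- generate_vein_dataset(3, 6, seed = 1)
#' table(ds$split)  # 15 train, 3 test
#' @export
generate_vein_dataset <- function(n_classes, n_per_class = 6L, seed = 1L,
                                  dir = NULL, render = TRUE) {
  n_classes <- check_positive_int(n_classes, "n_classes")
  n_per_class <- check_positive_int(n_per_class, "n_per_class")
  if (n_per_class < 6L)
    stop("`n_per_class` must be at least 6 for the 1:5 test:train split",
         call. = FALSE)
  n_test <- n_per_class %/% 6L
  n <- n_classes * n_per_class
  lv <- sprintf("class_%03d", seq_len(n_classes))
  labels <- factor(rep(lv, each = n_per_class), levels = lv)
  seeds <- derive_seeds(seed, 2L * n + n_classes)
  split <- character(n)
  images <- if (render) array(0, c(60L, 180L, n)) else NULL
  rows <- vector("list", n)
  i <- 0L
  for (cl in seq_len(n_classes)) {
    tpl <- if (render) vein_template(cl, seed = seed)
    test_idx <- with_seed(seeds[2L * n + cl],
                          sample.int(n_per_class, n_test))
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      split[i] <- if (j %in% test_idx) "test" else "train"
      if (render) {
        pars <- sample_params(seed = seeds[2L * i - 1L])
        images[, , i] <- render_vein(tpl, pars, seed = seeds[2L * i])
      }
      rows[[i]] <- data.frame(
        path = file.path(lv[cl], sprintf("img_%03d.png", j)),
        class_id = cl, split = split[i])
    }
  }
  manifest <- do.call(rbind, rows)
  ds <- structure(list(images = images, labels = labels,
                       split = factor(split, levels = c("train", "test")),
                       manifest = manifest, seed = as.integer(seed)),
                  class = "vein_dataset")
  if (!is.null(dir)) {
    if (!render) stop("`dir` requires render = TRUE", call. = FALSE)
    write_vein_dataset(ds, dir)
  }
  ds
}

write_vein_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$labels)) {
    path <- file.path(dir, ds$manifest$path[i])
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    # EBImage images are width x height; transpose our H x W matrix
    EBImage::writeImage(EBImage::Image(t(ds$images[, , i])), path)
  }
  utils::write.csv(ds$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.vein_dataset <- function(x, ...) {
  cat(sprintf("Synthetic vein dataset: %d classes, %d images (%s)\n",
              nlevels(x$labels), length(x$labels),
              paste(sprintf("%d %s", table(x$split), levels(x$split)),
                    collapse = ", ")))
  if (is.null(x$images)) cat("  (manifest only, no pixel data)\n")
  invisible(x)
}
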