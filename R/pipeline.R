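# Dataset IO and checkpointing.
#
# Images are consumed from a class-per-directory folder (one subdirectory
# per identity). Decoding, grayscale conversion and bilinear resizing to the
# fixed 60 x 180 input go through EBImage; resizing is the ONLY
# preprocessing applied.

IMAGE_EXTENSIONS <- c("png", "jpg", "jpeg", "tif", "tiff")

#' Read a class-per-directory image folder
#'
#' Each subdirectory of `path` is one class; labels are the subdirectory
#' names sorted lexicographically. Images are decoded, converted to a single
#' grayscale channel, resized to `target` with bilinear interpolation and
#' scaled to `[0, 1]`. Unreadable files are skipped with a warning and
#' counted in the `n_skipped` attribute; an empty class directory is an
#' error. If a `manifest.csv` written by [generate_vein_dataset()] is
#' present, its train/test split is attached.
#'
#' @param path folder with one subdirectory per class.
#' @param target output image size `c(height, width)`, default `c(60, 180)`.
#' @return A `vein_dataset` object (`images`, `labels`, optional `split`).
#' @export
read_image_folder <- function(path, target = c(60L, 180L)) {
  if (!dir.exists(path)) stop(sprintf("no such directory: %s", path),
                              call. = FALSE)
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L)
    stop(sprintf("%s contains no class subdirectories", path), call. = FALSE)
  images <- list(); labels <- character(); files <- character()
  n_skipped <- 0L
  for (cl in classes) {
    fs <- list.files(file.path(path, cl), full.names = TRUE)
    fs <- fs[tolower(tools::file_ext(fs)) %in% IMAGE_EXTENSIONS]
    if (length(fs) == 0L)
      stop(sprintf("class directory %s contains no images", cl), call. = FALSE)
    for (f in sort(fs)) {
      img <- tryCatch(load_gray_image(f, target), error = function(e) NULL)
      if (is.null(img)) {
        warning(sprintf("skipping unreadable image %s", f), call. = FALSE)
        n_skipped <- n_skipped + 1L
        next
      }
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cl)
      files <- c(files, f)
    }
  }
  arr <- array(unlist(images), c(target, length(images)))
  ds <- structure(list(images = arr,
                       labels = factor(labels, levels = classes),
                       split = NULL,
                       manifest = data.frame(path = files,
                                             class_id = as.integer(factor(labels, levels = classes)))),
                  class = "vein_dataset")
  mf <- file.path(path, "manifest.csv")
  if (file.exists(mf)) {
    m <- utils::read.csv(mf, stringsAsFactors = FALSE)
    key <- do.call(file.path, c(list(path), list(m$path)))
    split <- m$split[match(files, key)]
    if (!anyNA(split))
      ds$split <- factor(split, levels = c("train", "test"))
  }
  attr(ds, "n_skipped") <- n_skipped
  ds
}

load_gray_image <- function(file, target) {
  img <- EBImage::readImage(file)
  if (length(dim(img)) == 3L) img <- EBImage::channel(img, "gray")
  # EBImage arrays are width x height; resize, then transpose to H x W
  img <- EBImage::resize(img, w = target[2L], h = target[1L])
  m <- t(EBImage::imageData(img))
  pmin(1, pmax(0, m))
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with a versioned header and the full model
#' configuration embedded, so a loaded model rebuilds its architecture and
#' label order exactly.
#'
#' @param model an `msfbf` object.
#' @param path file path.
#' @export
save_msfbf <- function(model, path) {
  stopifnot(inherits(model, "msfbf"))
  saveRDS(list(format = "msfbf-checkpoint", version = 1L,
               config = model$config, params = model$params,
               labels = model$labels, history = model$history,
               fitted = model$fitted, seed = model$seed),
          path)
  invisible(path)
}

#' @rdname save_msfbf
#' @export
load_msfbf <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "msfbf-checkpoint"))
    stop(sprintf("%s is not an msfbf checkpoint", path), call. = FALSE)
  if (obj$version > 1L)
    stop(sprintf("checkpoint version %d is newer than this package supports",
                 obj$version), call. = FALSE)
  structure(list(config = obj$config, params = obj$params,
                 labels = obj$labels, history = obj$history,
                 fitted = obj$fitted, seed = obj$seed),
            class = "msfbf")
}
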