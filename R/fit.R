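# Model fitting: minibatch Adam on softmax cross-entropy, plus the S3
# methods of the fitted object.

#' Fit a multi-scale feature bilinear fusion network
#'
#' Trains an MSFBF-Net variant for closed-set identification with the
#' published protocol: Adam, minibatches of 8, cross-entropy on the logits.
#' Images are used as-is apart from the fixed 60 x 180 input size — resizing
#' at load time is the only preprocessing.
#'
#' @param x training images: an `H x W x N` array, an `H x W x 1 x N` array,
#'   or a [generate_vein_dataset()] / [read_image_folder()] object (whose
#'   train split and labels are then used, with the test split as
#'   validation).
#' @param y factor of class labels, one per image (ignored when `x` is a
#'   dataset object).
#' @param variant architecture variant; see [msfbf_config()].
#' @param epochs training epochs (the published schedule is 300; the default
#'   30 is a desk-scale preset).
#' @param batch_size minibatch size, default 8.
#' @param learning_rate Adam step size, default 1e-3.
#' @param validation optional list `list(x = , y = )` with held-out images
#'   and labels for per-epoch validation loss/accuracy.
#' @param seed seed controlling initialisation and batch shuffling; fits are
#'   bit-reproducible for a fixed seed on a single thread.
#' @param model optional pre-built or previously fitted `msfbf` object to
#'   continue training (its class count must match the data).
#' @param verbose print per-epoch progress.
#' @return An object of class `msfbf` with elements `config`, `params`,
#'   `labels` (factor levels) and `history` (per-epoch data frame with
#'   `train_loss` and, when validation data exist, `val_loss`/`val_accuracy`).
#' @examples
#' \donttest{
#' ds <- generate_vein_dataset(4, 6, seed = 1)
#' fit <- msfbf(ds, variant = "lightweight_mam", epochs = 2, seed = 1)
#' predict(fit, ds$images[, , ds$split == "test"])
#' }
#' @export
msfbf <- function(x, y = NULL, variant = "lightweight_mam", epochs = 30L,
                  batch_size = 8L, learning_rate = 1e-3, validation = NULL,
                  seed = 1L, model = NULL, verbose = FALSE) {
  if (inherits(x, "vein_dataset")) {
    ds <- x
    tr <- ds$split == "train"
    if (is.null(validation) && any(!tr))
      validation <- list(x = ds$images[, , !tr, drop = FALSE],
                         y = ds$labels[!tr])
    y <- ds$labels[tr]
    x <- ds$images[, , tr, drop = FALSE]
  }
  if (length(dim(x)) == 4L) {
    stopifnot(dim(x)[3L] == 1L)
    x <- array(x, dim(x)[c(1L, 2L, 4L)])
  }
  stopifnot(length(dim(x)) == 3L)
  n <- dim(x)[3L]
  if (is.null(y) || n == 0L) stop("training data are empty", call. = FALSE)
  y <- droplevels(as.factor(y))
  if (length(y) != n) stop("`y` must have one label per image", call. = FALSE)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  epochs <- check_positive_int(epochs, "epochs")
  batch_size <- check_positive_int(batch_size, "batch_size")

  if (is.null(model)) {
    model <- msfbf_build(variant, nlevels(y), input_shape = dim(x)[1:2],
                         seed = seed)
  } else {
    stopifnot(inherits(model, "msfbf"))
    if (model$config$num_classes != nlevels(y))
      stop(sprintf("model has %d classes but the data have %d",
                   model$config$num_classes, nlevels(y)), call. = FALSE)
  }
  config <- model$config
  params <- model$params
  labels <- as.integer(y)

  paths <- trainable_paths(params)
  state <- new.env(parent = emptyenv())
  state$s <- lapply(paths, function(p) {
    z <- pluck(params, p) * 0
    list(m = z, v = z)
  })
  tstep <- 0L
  hist <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                     val_loss = NA_real_, val_accuracy = NA_real_)

  set.seed(seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      grads <- NULL
      bl <- 0
      for (i in idx) {
        fw <- net_forward(params, config, x[, , i], keep = TRUE)
        ce <- softmax_ce(fw$logits, labels[i])
        bl <- bl + ce$loss
        g <- net_backward(params, config, fw$cache, ce$glogits)
        grads <- if (is.null(grads)) g else grads_add(grads, g, paths)
      }
      ep_loss <- ep_loss + bl
      tstep <- tstep + 1L
      params <- adam_update(params, grads, state, paths,
                            lr = learning_rate, t = tstep,
                            scale = 1 / length(idx))
    }
    hist$train_loss[ep] <- ep_loss / n
    if (!is.null(validation)) {
      ev <- eval_params(params, config, validation$x,
                        as.integer(factor(validation$y, levels = levels(y))))
      hist$val_loss[ep] <- ev$loss
      hist$val_accuracy[ep] <- ev$accuracy
    }
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f%s", ep, hist$train_loss[ep],
                      if (!is.null(validation))
                        sprintf("  val loss %.4f  val acc %.3f",
                                hist$val_loss[ep], hist$val_accuracy[ep])
                      else ""))
  }
  model$params <- params
  model$labels <- levels(y)
  model$history <- if (is.null(validation)) hist[, 1:2] else hist
  model$fitted <- TRUE
  model
}

grads_add <- function(a, b, paths) {
  for (p in paths) a <- poke(a, p, pluck(a, p) + pluck(b, p))
  a
}

# Adam step; `state` is an environment holding the first/second moment
# estimates so updates persist across calls.
adam_update <- function(params, grads, state, paths, lr, t,
                        scale = 1, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (j in seq_along(paths)) {
    p <- paths[[j]]
    g <- pluck(grads, p) * scale
    st <- state$s[[j]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    state$s[[j]] <- st
    upd <- lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    w <- pluck(params, p)
    params <- poke(params, p, w - array(upd, dim = dim(w) %||% length(w)))
  }
  params
}

eval_params <- function(params, config, x, labels) {
  x <- as_feature_map_batch(x)
  n <- dim(x)[3L]
  loss <- 0
  pred <- integer(n)
  for (i in seq_len(n)) {
    fw <- net_forward(params, config, x[, , i])
    pred[i] <- which.max(fw$logits)
    if (!is.na(labels[i]))
      loss <- loss + softmax_ce(fw$logits, labels[i])$loss
  }
  list(loss = loss / n, accuracy = mean(pred == labels), pred = pred)
}

as_feature_map_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) == 4L && dim(x)[3L] == 1L)
    x <- array(x, dim(x)[c(1L, 2L, 4L)])
  stopifnot(length(dim(x)) == 3L)
  x
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.msfbf <- function(x, ...) {
  a <- msfbf_audit(x)
  cat(sprintf("MSFBF-Net (%s), %d classes, input %dx%d\n",
              x$config$variant, x$config$num_classes,
              x$config$input_shape[1L], x$config$input_shape[2L]))
  cat(sprintf("  %s parameters (%.1f M), %.4g GFlops (MACs) per image\n",
              format(a$total_params, big.mark = ","), a$params_M, a$gflops))
  if (x$fitted) {
    h <- x$history
    cat(sprintf("  fitted: %d epochs, final train loss %.4f", nrow(h),
                h$train_loss[nrow(h)]))
    if ("val_accuracy" %in% names(h) && !all(is.na(h$val_accuracy)))
      cat(sprintf(", validation accuracy %.3f", h$val_accuracy[nrow(h)]))
    cat("\n")
  } else cat("  untrained (random initialisation)\n")
  invisible(x)
}

#' @export
summary.msfbf <- function(object, ...) {
  print(object)
  cat("\nPer-layer audit:\n")
  print(msfbf_audit(object))
  invisible(object)
}

#' @export
coef.msfbf <- function(object, ...) object$params

#' Predict identities for new images
#'
#' @param object a fitted `msfbf` model.
#' @param newdata images: `H x W` matrix, `H x W x N` array, or a
#'   `vein_dataset` (all of its images are scored).
#' @param type `"class"` (factor of predicted labels), `"prob"` (softmax
#'   matrix) or `"logit"` (raw score matrix, one row per image).
#' @param ... unused.
#' @export
predict.msfbf <- function(object, newdata,
                          type = c("class", "prob", "logit"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "vein_dataset")) newdata <- newdata$images
  x <- as_feature_map_batch(newdata)
  n <- dim(x)[3L]
  scores <- matrix(NA_real_, n, object$config$num_classes)
  for (i in seq_len(n))
    scores[i, ] <- net_forward(object$params, object$config, x[, , i])$logits
  lv <- object$labels %||% paste0("class_", seq_len(ncol(scores)))
  colnames(scores) <- lv
  switch(type,
         logit = scores,
         prob = t(apply(scores, 1L, function(z) {
           e <- exp(z - max(z)); e / sum(e)
         })),
         class = factor(lv[max.col(scores, ties.method = "first")],
                        levels = lv))
}

#' Plot training history
#'
#' Draws the per-epoch training (and, when present, validation) loss curves
#' of a fitted model.
#'
#' @param x a fitted `msfbf` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.msfbf <- function(x, ...) {
  if (!x$fitted || is.null(x$history))
    stop("model has no training history", call. = FALSE)
  h <- x$history
  cols <- intersect(c("train_loss", "val_loss"), names(h))
  graphics::matplot(h$epoch, as.matrix(h[, cols, drop = FALSE]), type = "l",
                    lty = 1, lwd = 2, col = c("#1b6ca8", "#c0392b"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", legend = cols, lty = 1, lwd = 2,
                   col = c("#1b6ca8", "#c0392b"), bty = "n")
  invisible(x)
}

#' Evaluate a fitted model on a held-out set
#'
#' Computes top-1 identification accuracy (`n_correct / n_total`) and the
#' per-class accuracy vector.
#'
#' @param object a fitted `msfbf` model.
#' @param newdata images (`H x W x N` array) or a `vein_dataset`, in which
#'   case its `split == "test"` images are used by default.
#' @param labels true labels (factor); taken from the dataset when omitted.
#' @param split which dataset split to score when `newdata` is a
#'   `vein_dataset`.
#' @return List of class `msfbf_eval` with `accuracy`, `n_correct`,
#'   `n_total`, `per_class` and `predicted`.
#' @export
msfbf_evaluate <- function(object, newdata, labels = NULL, split = "test") {
  stopifnot(inherits(object, "msfbf"))
  if (inherits(newdata, "vein_dataset")) {
    keep <- if (is.null(newdata$split)) rep(TRUE, length(newdata$labels))
            else newdata$split == split
    labels <- labels %||% newdata$labels[keep]
    newdata <- newdata$images[, , keep, drop = FALSE]
  }
  if (is.null(labels)) stop("`labels` are required", call. = FALSE)
  pred <- predict(object, newdata, type = "class")
  classification_result(pred, factor(labels, levels = levels(pred)))
}

classification_result <- function(predicted, truth) {
  n <- length(truth)
  if (n == 0L) stop("the evaluation set is empty", call. = FALSE)
  ok <- as.character(predicted) == as.character(truth)
  per_class <- tapply(ok, truth, mean)
  structure(list(accuracy = sum(ok) / n, n_correct = sum(ok), n_total = n,
                 per_class = per_class, predicted = predicted),
            class = "msfbf_eval")
}

#' @export
print.msfbf_eval <- function(x, ...) {
  cat(sprintf("Identification accuracy: %.4f (%d / %d correct)\n",
              x$accuracy, x$n_correct, x$n_total))
  invisible(x)
}
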