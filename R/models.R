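# Model assembly and the forward/backward engine.
#
# Topology (both branches meet at 15 x 45 when the input is 60 x 180):
#   Conv0(64) -> Max0(2) -> Conv1(64) -> Max1(2) --+--> 1x1 raise 64->128  (shallow)
#                                                  +--> Conv2(64) -> Conv3(128)
#                                                       -> Conv4(128) [-> MAM] (deep)
#   fuse(deep, shallow) -> 16384-dim descriptor -> FC -> logits
#
# The `full` variant uses plain convolutions; `lightweight` replaces them
# with MixConv blocks per the published lightweight structure (Conv2/Conv3
# mix a dense 3x3 with a dilated 3x3); `lightweight_mam` adds one multiple
# attention module on the deep branch after Conv4. Every convolution is
# followed by ReLU; gradients are derived by hand layer by layer.

MSFBF_VARIANTS <- c("full", "lightweight", "lightweight_mam")

#' Model configuration
#'
#' Fully determines an architecture: variant, class count and input size.
#' Layer widths are fixed at the published values (64, 64, 64, 128, 128 plus
#' a 1 x 1 shallow raise to 128), so the fused descriptor always has
#' 128 * 128 = 16384 dimensions.
#'
#' @param variant `"full"`, `"lightweight"` or `"lightweight_mam"`.
#' @param num_classes number of identities (>= 2).
#' @param input_shape height and width of the input image; both must be
#'   divisible by 4 (two 2x pooling stages). Default `c(60, 180)`.
#' @param r reduction ratio of the attention bottleneck.
#' @return List of class `msfbf_config`.
#' @export
msfbf_config <- function(variant = "lightweight_mam", num_classes,
                         input_shape = c(60L, 180L), r = 8L) {
  if (length(variant) != 1L || !variant %in% MSFBF_VARIANTS)
    stop(sprintf("unknown variant %s; expected one of %s",
                 deparse(variant), paste(MSFBF_VARIANTS, collapse = ", ")),
         call. = FALSE)
  num_classes <- check_positive_int(num_classes, "num_classes")
  if (num_classes < 2L) stop("`num_classes` must be at least 2", call. = FALSE)
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 2L || any(input_shape %% 4L != 0L) ||
      any(input_shape < 8L))
    stop("`input_shape` must be two multiples of 4 (two 2x pooling stages)",
         call. = FALSE)
  structure(list(variant = variant, num_classes = num_classes,
                 input_shape = input_shape, r = check_positive_int(r, "r"),
                 widths = c(conv0 = 64L, conv1 = 64L, conv2 = 64L,
                            conv3 = 128L, conv4 = 128L),
                 fused_dim = 128L * 128L),
            class = "msfbf_config")
}

init_params <- function(config, seed = 1L) {
  s <- derive_seeds(seed, 8L)
  k3 <- kernel_spec(3L); k3d2 <- kernel_spec(3L, 2L); k1 <- kernel_spec(1L)
  w <- config$widths
  if (config$variant == "full") {
    p <- list(
      conv0 = conv_weights(k3, 1L, w[["conv0"]], seed = s[1L]),
      conv1 = conv_weights(k3, w[["conv0"]], w[["conv1"]], seed = s[2L]),
      conv2 = conv_weights(k3, w[["conv1"]], w[["conv2"]], seed = s[3L]),
      conv3 = conv_weights(k3, w[["conv2"]], w[["conv3"]], seed = s[4L]),
      conv4 = conv_weights(k1, w[["conv3"]], w[["conv4"]], seed = s[5L]))
  } else {
    p <- list(
      conv0 = mixconv_weights(mixconv_spec(list(k3), 1L, w[["conv0"]]), seed = s[1L]),
      conv1 = mixconv_weights(mixconv_spec(list(k3), w[["conv0"]], w[["conv1"]]), seed = s[2L]),
      conv2 = mixconv_weights(mixconv_spec(list(k3, k3d2), w[["conv1"]], w[["conv2"]]), seed = s[3L]),
      conv3 = mixconv_weights(mixconv_spec(list(k3, k3d2), w[["conv2"]], w[["conv3"]]), seed = s[4L]),
      conv4 = mixconv_weights(mixconv_spec(list(k1), w[["conv3"]], w[["conv4"]]), seed = s[5L]))
  }
  p$shallow <- conv_weights(k1, w[["conv1"]], 128L, seed = s[6L])
  if (config$variant == "lightweight_mam")
    p$mam <- mam_weights(128L, r = config$r, seed = s[7L])
  fc_w <- with_seed(s[8L], matrix(stats::rnorm(config$fused_dim * config$num_classes,
                                               sd = sqrt(2 / config$fused_dim)),
                                  config$fused_dim, config$num_classes))
  p$fc <- structure(list(w = fc_w, b = numeric(config$num_classes)),
                    class = "fc_weights")
  p
}

#' Build an untrained model
#'
#' @inheritParams msfbf_config
#' @param seed RNG seed for weight initialisation.
#' @return An object of class `msfbf` (untrained; see [msfbf()] to fit).
#' @examples
#' m <- msfbf_build("lightweight", num_classes = 5, seed = 1)
#' @export
msfbf_build <- function(variant = "lightweight_mam", num_classes,
                        input_shape = c(60L, 180L), r = 8L, seed = 1L) {
  config <- msfbf_config(variant, num_classes, input_shape, r)
  structure(list(config = config, params = init_params(config, seed),
                 labels = NULL, history = NULL, fitted = FALSE,
                 seed = as.integer(seed)),
            class = "msfbf")
}

# ---- layer-level forward/backward (training tape) ------------------------

layer_fwd <- function(p, x) {
  if (inherits(p, "conv_weights")) {
    y <- cpp_relu(cpp_conv2d_fwd(x, p$w, p$b, p$spec$dilation))
    list(y = y, cache = list(x = x, y = y))
  } else if (inherits(p, "mixconv_weights")) {
    h <- dim(x)[1L]; w <- dim(x)[2L]
    ng <- length(p$groups)
    d <- vector("list", ng)
    outs <- vector("list", ng)
    for (g in seq_len(ng)) {
      pg <- p$groups[[g]]
      xs <- if (ng == 1L) x else x[, , pg$in_idx, drop = FALSE]
      dg <- cpp_dwconv_fwd(xs, pg$dw, pg$dw_b, pg$kernel$dilation)
      d[[g]] <- fm_mat(dg)
      outs[[g]] <- d[[g]] %*% pg$pw + rep(pg$pw_b, each = h * w)
    }
    ym <- cpp_relu(if (ng == 1L) outs[[1L]] else do.call(cbind, outs))
    list(y = mat_fm(ym, h, w),
         cache = list(x = x, d = d, ym = ym, h = h, w = w))
  } else stop("unsupported layer")
}

layer_bwd <- function(p, cache, gy) {
  if (inherits(p, "conv_weights")) {
    g0 <- cpp_relu_bwd(gy, cache$y)
    r <- cpp_conv2d_bwd(cache$x, p$w, g0, p$spec$dilation)
    list(gx = r$gx, grads = structure(list(w = r$gw, b = as.numeric(r$gb))))
  } else {
    h <- cache$h; w <- cache$w
    g0 <- cpp_relu_bwd(fm_mat(gy), cache$ym)
    ng <- length(p$groups)
    gx <- if (ng == 1L) NULL else array(0, dim(cache$x))
    out_idx <- split_channels(p$spec$out_channels, ng)
    ggroups <- vector("list", ng)
    for (g in seq_len(ng)) {
      pg <- p$groups[[g]]
      gyg <- if (ng == 1L) g0 else g0[, out_idx[[g]], drop = FALSE]
      gpw <- crossprod(cache$d[[g]], gyg)
      gpw_b <- colSums(gyg)
      gd <- mat_fm(gyg %*% t(pg$pw), h, w)
      xs <- if (ng == 1L) cache$x else cache$x[, , pg$in_idx, drop = FALSE]
      r <- cpp_dwconv_bwd(xs, pg$dw, gd, pg$kernel$dilation)
      if (ng == 1L) gx <- r$gx else gx[, , pg$in_idx] <- r$gx
      ggroups[[g]] <- list(dw = r$gw, dw_b = as.numeric(r$gb),
                           pw = gpw, pw_b = gpw_b)
    }
    list(gx = gx, grads = list(groups = ggroups))
  }
}

pool_fwd <- function(x, size = 2L) {
  r <- cpp_maxpool_fwd(x, size)
  list(y = r$y, cache = list(idx = r$idx, h = dim(x)[1L], w = dim(x)[2L]))
}

pool_bwd <- function(cache, gy) cpp_maxpool_bwd(cache$idx, gy, cache$h, cache$w)

mam_fwd <- function(p, x) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; ch <- dim(x)[3L]
  m <- fm_mat(x)
  s_h <- colMeans(aperm(x, c(2L, 1L, 3L)), dims = 1L)
  s_w <- colMeans(x, dims = 1L)
  u <- rbind(s_h, s_w) %*% p$w1 + rep(p$b1, each = h + w)
  f <- relu(u)
  a_h <- f[seq_len(h), , drop = FALSE] %*% p$wh + rep(p$bh, each = h)
  a_w <- f[-seq_len(h), , drop = FALSE] %*% p$ww + rep(p$bw, each = w)
  g_h <- sigmoid(a_h)
  g_w <- sigmoid(a_w)
  mxi <- max.col(m, ties.method = "first")
  s <- array(c(rowMeans(m), m[cbind(seq_len(h * w), mxi)]), dim = c(h, w, 2L))
  a <- cpp_conv2d_fwd(s, p$ws, p$bs, 1L)
  g <- sigmoid(a[, , 1L])
  gf <- mam_gate_field(g_h, g_w, g)
  list(y = x * gf,
       cache = list(x = x, m = m, u = u, f = f, g_h = g_h, g_w = g_w,
                    g = g, s = s, mxi = mxi, gf = gf, h = h, w = w, ch = ch))
}

mam_bwd <- function(p, cache, gy) {
  h <- cache$h; w <- cache$w; ch <- cache$ch
  gd <- gy * cache$gf                       # direct product term
  gG <- (gy * cache$x) / 3                  # gradient w.r.t. each gate copy
  gg_h <- colSums(aperm(gG, c(2L, 1L, 3L)), dims = 1L)  # H x C
  gg_w <- colSums(gG, dims = 1L)                        # W x C
  gg <- matrix(rowSums(fm_mat(gG)), h, w)               # H x W
  # spatial branch
  ga <- gg * cache$g * (1 - cache$g)
  rs <- cpp_conv2d_bwd(cache$s, p$ws, array(ga, c(h, w, 1L)), 1L)
  gs <- rs$gx
  gd <- gd + array(gs[, , 1L] / ch, c(h, w, ch))        # avg-pool path
  gmx <- matrix(0, h * w, ch)
  gmx[cbind(seq_len(h * w), cache$mxi)] <- as.vector(gs[, , 2L])
  gd <- gd + mat_fm(gmx, h, w)                          # max-pool path
  # coordinate branches
  ga_h <- gg_h * cache$g_h * (1 - cache$g_h)
  ga_w <- gg_w * cache$g_w * (1 - cache$g_w)
  f_h <- cache$f[seq_len(h), , drop = FALSE]
  f_w <- cache$f[-seq_len(h), , drop = FALSE]
  gwh <- crossprod(f_h, ga_h); gbh <- colSums(ga_h)
  gww <- crossprod(f_w, ga_w); gbw <- colSums(ga_w)
  gf <- rbind(ga_h %*% t(p$wh), ga_w %*% t(p$ww))
  gu <- gf * (cache$u > 0)
  gw1 <- crossprod(rbind(colMeans(aperm(cache$x, c(2L, 1L, 3L)), dims = 1L),
                         colMeans(cache$x, dims = 1L)), gu)
  gb1 <- colSums(gu)
  gt <- gu %*% t(p$w1)
  gs_h <- gt[seq_len(h), , drop = FALSE]
  gs_w <- gt[-seq_len(h), , drop = FALSE]
  gd <- gd + aperm(array(gs_h / w, c(h, ch, w)), c(1L, 3L, 2L))
  gd <- gd + aperm(array(gs_w / h, c(w, ch, h)), c(3L, 1L, 2L))
  list(gx = gd,
       grads = list(w1 = gw1, b1 = gb1, wh = gwh, bh = gbh,
                    ww = gww, bw = gbw, ws = rs$gw, bs = as.numeric(rs$gb)))
}

head_fwd <- function(fd, fs, eps = 1e-12) {
  dm <- fm_mat(fd); sm <- fm_mat(fs)
  z <- as.vector(crossprod(dm, sm))
  xs <- sign(z) * sqrt(abs(z))
  nrm <- sqrt(sum(xs^2) + eps)
  list(y = xs / nrm,
       cache = list(dm = dm, sm = sm, z = z, xs = xs, nrm = nrm,
                    dd = dim(fd), ds = dim(fs)))
}

head_bwd <- function(cache, gy) {
  y <- cache$xs / cache$nrm
  gxs <- (gy - y * sum(y * gy)) / cache$nrm
  # d/dz sign(z) sqrt(|z|) = 1 / (2 sqrt(|z|)); clamped near 0 for stability
  gz <- gxs * 0.5 / sqrt(pmax(abs(cache$z), 1e-8))
  gz[cache$z == 0] <- 0
  gb <- matrix(gz, dim(cache$dm)[2L], dim(cache$sm)[2L])
  list(gfd = mat_fm(cache$sm %*% t(gb), cache$dd[1L], cache$dd[2L]),
       gfs = mat_fm(cache$dm %*% gb, cache$ds[1L], cache$ds[2L]))
}

# ---- whole-network forward / backward -------------------------------------

check_input_image <- function(x, config) {
  x <- as_feature_map(x)
  d <- dim(x)
  is_ <- config$input_shape
  if (d[1L] != is_[1L] || d[2L] != is_[2L] || d[3L] != 1L)
    stop(sprintf(
      "input image is %dx%d with %d channel(s); expected a single-channel %dx%d image",
      d[1L], d[2L], d[3L], is_[1L], is_[2L]), call. = FALSE)
  if (!all(is.finite(x))) stop("input image contains non-finite values",
                               call. = FALSE)
  x
}

net_forward <- function(params, config, x, keep = FALSE) {
  x <- check_input_image(x, config)
  cc <- list()
  l0 <- layer_fwd(params$conv0, x)
  p0 <- pool_fwd(l0$y)
  l1 <- layer_fwd(params$conv1, p0$y)
  p1 <- pool_fwd(l1$y)
  sh <- layer_fwd(params$shallow, p1$y)
  l2 <- layer_fwd(params$conv2, p1$y)
  l3 <- layer_fwd(params$conv3, l2$y)
  l4 <- layer_fwd(params$conv4, l3$y)
  deep <- l4$y
  ma <- NULL
  if (!is.null(params$mam)) {
    ma <- mam_fwd(params$mam, deep)
    deep <- ma$y
  }
  hd <- head_fwd(deep, sh$y)
  logits <- as.vector(crossprod(params$fc$w, hd$y)) + params$fc$b
  if (keep)
    cc <- list(l0 = l0, p0 = p0, l1 = l1, p1 = p1, sh = sh, l2 = l2,
               l3 = l3, l4 = l4, ma = ma, hd = hd, feat = hd$y,
               shallow_map = sh$y, deep_map = deep)
  list(logits = logits, cache = cc)
}

net_backward <- function(params, config, cache, glogits) {
  gfc <- list(w = cache$feat %o% glogits, b = glogits)
  gy <- as.vector(params$fc$w %*% glogits)
  hb <- head_bwd(cache$hd$cache, gy)
  gdeep <- hb$gfd
  grads <- list()
  if (!is.null(params$mam)) {
    mb <- mam_bwd(params$mam, cache$ma$cache, gdeep)
    grads$mam <- mb$grads
    gdeep <- mb$gx
  }
  b4 <- layer_bwd(params$conv4, cache$l4$cache, gdeep)
  b3 <- layer_bwd(params$conv3, cache$l3$cache, b4$gx)
  b2 <- layer_bwd(params$conv2, cache$l2$cache, b3$gx)
  bsh <- layer_bwd(params$shallow, cache$sh$cache, hb$gfs)
  gp1 <- b2$gx + bsh$gx
  b1 <- layer_bwd(params$conv1, cache$l1$cache, pool_bwd(cache$p1$cache, gp1))
  b0 <- layer_bwd(params$conv0, cache$l0$cache, pool_bwd(cache$p0$cache, b1$gx))
  grads$conv0 <- b0$grads; grads$conv1 <- b1$grads; grads$conv2 <- b2$grads
  grads$conv3 <- b3$grads; grads$conv4 <- b4$grads; grads$shallow <- bsh$grads
  grads$fc <- gfc
  grads
}

# Cross-entropy on softmax logits for one image; returns loss, probabilities
# and the logit gradient.
softmax_ce <- function(logits, label) {
  m <- max(logits)
  e <- exp(logits - m)
  p <- e / sum(e)
  g <- p
  g[label] <- g[label] - 1
  list(loss = -(logits[label] - m - log(sum(e))), p = p, glogits = g)
}

# ---- parameter tree utilities ---------------------------------------------

TRAINABLE_LEAVES <- c("w", "b", "dw", "dw_b", "pw", "pw_b",
                      "w1", "b1", "wh", "bh", "ww", "bw", "ws", "bs")

trainable_paths <- function(p, path = list()) {
  out <- list()
  keys <- names(p)
  if (is.null(keys)) keys <- seq_along(p)
  for (i in seq_along(p)) {
    key <- if (is.character(keys)) keys[[i]] else i
    el <- p[[i]]
    if (is.list(el)) out <- c(out, trainable_paths(el, c(path, key)))
    else if (is.character(key) && key %in% TRAINABLE_LEAVES && is.numeric(el))
      out <- c(out, list(c(path, key)))
  }
  out
}

pluck <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}

poke <- function(x, path, value) {
  if (length(path) == 1L) x[[path[[1L]]]] <- value
  else x[[path[[1L]]]] <- poke(x[[path[[1L]]]], path[-1L], value)
  x
}

#' Number of trainable parameters
#'
#' Enumerates every trainable weight and bias array in a model, counting each
#' element once. The closed-form totals reported by [msfbf_audit()] agree
#' with this enumeration exactly.
#'
#' @param object an `msfbf` model.
#' @export
n_parameters <- function(object) {
  stopifnot(inherits(object, "msfbf"))
  sum(vapply(trainable_paths(object$params),
             function(p) length(pluck(object$params, p)), 1))
}
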