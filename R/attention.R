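# Multiple attention mechanism (MAM): two coordinate-attention branches
# (height- and width-pooled descriptors with position-aware channel gates)
# plus a spatial-attention branch, averaged:
#
#   Y = (X * g_h + X * g_w + X * g) / 3
#
# g_h gates (height, channel) pairs and broadcasts along width, g_w gates
# (width, channel) pairs and broadcasts along height, and g is a single
# spatial map broadcast across channels. All gates pass through a sigmoid,
# so every gate lies strictly in (0, 1) and |Y| <= |X| elementwise.

#' Create weights for the multiple attention mechanism
#'
#' The coordinate branch concatenates the two pooled descriptors, reduces
#' channels `C -> ceiling(C / r)` with a shared 1 x 1 convolution + ReLU,
#' then restores `C` channels per direction with separate 1 x 1 convolutions
#' ahead of the sigmoid. The spatial branch applies a 7 x 7 convolution to
#' the stacked channel-average and channel-max maps.
#'
#' @param channels input channel count `C`.
#' @param r bottleneck reduction ratio for the coordinate branch (default 8;
#'   the reduced width is at least 1).
#' @param init `"he"` or `"zero"` (zero weights give every gate 0.5, so the
#'   block halves its input).
#' @param seed RNG seed.
#' @return List of class `mam_weights`.
#' @export
mam_weights <- function(channels, r = 8L, init = c("he", "zero"), seed = 1L) {
  init <- match.arg(init)
  channels <- check_positive_int(channels, "channels")
  r <- check_positive_int(r, "r")
  cr <- max(1L, as.integer(ceiling(channels / r)))
  if (init == "zero") {
    w1 <- matrix(0, channels, cr)
    wh <- matrix(0, cr, channels)
    ww <- matrix(0, cr, channels)
    ws <- array(0, c(7L, 7L, 2L, 1L))
  } else {
    ss <- derive_seeds(seed, 4L)
    w1 <- with_seed(ss[1L], matrix(stats::rnorm(channels * cr, sd = sqrt(2 / channels)),
                                   channels, cr))
    wh <- with_seed(ss[2L], matrix(stats::rnorm(cr * channels, sd = sqrt(2 / cr)),
                                   cr, channels))
    ww <- with_seed(ss[3L], matrix(stats::rnorm(cr * channels, sd = sqrt(2 / cr)),
                                   cr, channels))
    ws <- with_seed(ss[4L], he_init(c(7L, 7L, 2L, 1L), 7 * 7 * 2))
  }
  structure(list(channels = channels, r = r, cr = cr,
                 w1 = w1, b1 = numeric(cr),
                 wh = wh, bh = numeric(channels),
                 ww = ww, bw = numeric(channels),
                 ws = ws, bs = numeric(1L)),
            class = "mam_weights")
}

#' Directional average pooling
#'
#' Aggregates a feature map along each spatial axis: `s_h[h, c]` is the mean
#' over width of `x[h, , c]` and `s_w[w, c]` the mean over height of
#' `x[, w, c]`, preserving positional information per direction.
#'
#' @inheritParams conv_block
#' @return List of class `coord_descriptors` with matrices `s_h` (`H x C`)
#'   and `s_w` (`W x C`).
#' @export
coord_pool <- function(x) {
  x <- assert_feature_map(x)
  s_h <- colMeans(aperm(x, c(2L, 1L, 3L)), dims = 1L)  # H x C
  s_w <- colMeans(x, dims = 1L)                        # W x C
  structure(list(s_h = s_h, s_w = s_w), class = "coord_descriptors")
}

#' Coordinate attention gates
#'
#' Concatenates the two directional descriptors, reduces channels with a
#' shared 1 x 1 convolution and ReLU, splits back into the height and width
#' parts, restores the channel count per part with separate 1 x 1
#' convolutions, and applies a sigmoid.
#'
#' @param d a [coord_pool()] result.
#' @param weights a [mam_weights()] object matching the channel count.
#' @return List with gate matrices `g_h` (`H x C`) and `g_w` (`W x C`), all
#'   values strictly in (0, 1).
#' @export
coord_gates <- function(d, weights) {
  stopifnot(inherits(d, "coord_descriptors"), inherits(weights, "mam_weights"))
  if (ncol(d$s_h) != weights$channels)
    stop(sprintf("descriptors have %d channels but weights expect %d",
                 ncol(d$s_h), weights$channels), call. = FALSE)
  h <- nrow(d$s_h)
  u <- rbind(d$s_h, d$s_w) %*% weights$w1
  f <- relu(u + rep(weights$b1, each = nrow(u)))
  a_h <- f[seq_len(h), , drop = FALSE] %*% weights$wh
  a_w <- f[-seq_len(h), , drop = FALSE] %*% weights$ww
  list(g_h = sigmoid(a_h + rep(weights$bh, each = nrow(a_h))),
       g_w = sigmoid(a_w + rep(weights$bw, each = nrow(a_w))))
}

#' Spatial attention gate
#'
#' Channel-wise average and max pooling give two `H x W` descriptor maps;
#' their stack is filtered by a 7 x 7 same-padded convolution to one channel
#' and passed through a sigmoid, yielding a positional gate map.
#'
#' @inheritParams conv_block
#' @param weights a [mam_weights()] object.
#' @return An `H x W` matrix with entries strictly in (0, 1).
#' @export
spatial_gate <- function(x, weights) {
  x <- assert_feature_map(x)
  stopifnot(inherits(weights, "mam_weights"))
  m <- fm_mat(x)
  h <- dim(x)[1L]; w <- dim(x)[2L]
  s <- array(c(rowMeans(m), apply_rowmax(m)), dim = c(h, w, 2L))
  a <- cpp_conv2d_fwd(s, weights$ws, weights$bs, 1L)
  sigmoid(a[, , 1L])
}

apply_rowmax <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}

#' Multiple attention mechanism block
#'
#' Applies the three attention branches to `x` and averages the gated
#' copies: `Y = (X * g_h + X * g_w + X * g) / 3`, with each gate broadcast
#' along its free axis. Output shape equals input shape and, because every
#' gate is below 1, `|Y| <= |X|` elementwise. With zero-initialised weights
#' every gate is exactly 0.5 and `Y = X / 2`.
#'
#' @inheritParams conv_block
#' @param weights a [mam_weights()] object matching the channel count.
#' @param return_gates if `TRUE`, attach the three gates as an attribute.
#' @return An array shaped like `x`.
#' @export
mam <- function(x, weights, return_gates = FALSE) {
  x <- assert_feature_map(x)
  stopifnot(inherits(weights, "mam_weights"))
  if (dim(x)[3L] != weights$channels)
    stop(sprintf("input has %d channels but weights expect %d",
                 dim(x)[3L], weights$channels), call. = FALSE)
  cg <- coord_gates(coord_pool(x), weights)
  g <- spatial_gate(x, weights)
  y <- x * mam_gate_field(cg$g_h, cg$g_w, g)
  if (return_gates) attr(y, "gates") <- list(g_h = cg$g_h, g_w = cg$g_w, g = g)
  y
}

# Combined broadcast gate field (H x W x C): (g_h + g_w + g) / 3.
mam_gate_field <- function(g_h, g_w, g) {
  h <- nrow(g_h); w <- nrow(g_w); ch <- ncol(g_h)
  a1 <- aperm(array(g_h, c(h, ch, w)), c(1L, 3L, 2L))
  a2 <- aperm(array(g_w, c(w, ch, h)), c(3L, 1L, 2L))
  a3 <- array(g, c(h, w, ch))
  (a1 + a2 + a3) / 3
}
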