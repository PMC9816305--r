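# Convolutional building blocks: plain conv, depthwise-separable conv,
# mixed depthwise-separable conv (MixConv), max pooling.
#
# All convolutions are stride-1 cross-correlations with zero same-padding,
# so spatial size is preserved; downsampling happens only in pooling layers.

#' Kernel specification
#'
#' Describes a square convolution kernel by its size and dilation. The
#' effective receptive field is `dilation * (size - 1) + 1`, so a 3 x 3
#' kernel with dilation 2 covers a 5 x 5 window with 3 x 3 parameters.
#'
#' @param size odd positive kernel size in pixels.
#' @param dilation positive integer dilation (1 = dense kernel).
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec(3, dilation = 2)  # effective field 5
#' @export
kernel_spec <- function(size = 3L, dilation = 1L) {
  size <- check_positive_int(size, "size")
  dilation <- check_positive_int(dilation, "dilation")
  if (size %% 2L == 0L)
    stop("`size` must be odd so that same-padding is symmetric", call. = FALSE)
  structure(list(size = size, dilation = dilation), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("kernel %dx%d (dilation %d, effective field %d)\n",
              x$size, x$size, x$dilation, x$dilation * (x$size - 1L) + 1L))
  invisible(x)
}

#' MixConv specification
#'
#' A mixed depthwise-separable convolution partitions its input channels into
#' contiguous groups, filters each group depthwise with its own kernel
#' (different sizes/dilations capture different receptive fields in one
#' layer), and mixes each group to its share of the output channels with a
#' per-group pointwise 1 x 1 convolution.
#'
#' @param groups list of [kernel_spec()] objects, one per channel group.
#' @param in_channels,out_channels positive channel counts.
#' @return An object of class `mixconv_spec`.
#' @examples
#' mixconv_spec(list(kernel_spec(3), kernel_spec(3, 2)), 64, 128)
#' @export
mixconv_spec <- function(groups, in_channels, out_channels) {
  if (inherits(groups, "kernel_spec")) groups <- list(groups)
  stopifnot(length(groups) >= 1L)
  lapply(groups, function(g) {
    if (!inherits(g, "kernel_spec"))
      stop("each element of `groups` must be a kernel_spec", call. = FALSE)
  })
  in_channels <- check_positive_int(in_channels, "in_channels")
  out_channels <- check_positive_int(out_channels, "out_channels")
  if (length(groups) > in_channels)
    stop("more kernel groups than input channels", call. = FALSE)
  structure(list(groups = groups, in_channels = in_channels,
                 out_channels = out_channels),
            class = "mixconv_spec")
}

# Contiguous channel split; the first group absorbs any remainder.
split_channels <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  sizes[1L] <- sizes[1L] + n - base * k
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  Map(function(a, b) seq.int(a, b), starts, ends)
}

#' Create weights for a plain convolution
#'
#' @param spec a [kernel_spec()].
#' @param in_channels,out_channels channel counts.
#' @param init `"he"` (Kaiming-normal, the ReLU default) or `"zero"`.
#' @param seed RNG seed for reproducible initialisation.
#' @return List of class `conv_weights` with the kernel array `w`
#'   (`k x k x in x out`) and bias vector `b`.
#' @export
conv_weights <- function(spec, in_channels, out_channels, init = c("he", "zero"),
                         seed = 1L) {
  init <- match.arg(init)
  stopifnot(inherits(spec, "kernel_spec"))
  in_channels <- check_positive_int(in_channels, "in_channels")
  out_channels <- check_positive_int(out_channels, "out_channels")
  k <- spec$size
  dims <- c(k, k, in_channels, out_channels)
  w <- if (init == "zero") array(0, dims)
       else with_seed(seed, he_init(dims, k * k * in_channels))
  structure(list(w = w, b = numeric(out_channels), spec = spec,
                 in_channels = in_channels, out_channels = out_channels),
            class = "conv_weights")
}

#' Create weights for a depthwise-separable convolution
#'
#' The depthwise stage has one `k x k` kernel per input channel; the
#' pointwise stage is a dense 1 x 1 convolution mixing channels. Both stages
#' carry biases.
#'
#' @inheritParams conv_weights
#' @return List of class `dsconv_weights` with `dw` (`k x k x in`), `dw_b`,
#'   `pw` (`in x out` matrix) and `pw_b`.
#' @export
dsconv_weights <- function(spec, in_channels, out_channels, init = c("he", "zero"),
                           seed = 1L) {
  init <- match.arg(init)
  stopifnot(inherits(spec, "kernel_spec"))
  in_channels <- check_positive_int(in_channels, "in_channels")
  out_channels <- check_positive_int(out_channels, "out_channels")
  k <- spec$size
  if (init == "zero") {
    dw <- array(0, c(k, k, in_channels))
    pw <- matrix(0, in_channels, out_channels)
  } else {
    seeds <- derive_seeds(seed, 2L)
    dw <- with_seed(seeds[1L], he_init(c(k, k, in_channels), k * k))
    pw <- with_seed(seeds[2L], he_init(c(in_channels, out_channels), in_channels))
    dim(pw) <- c(in_channels, out_channels)
  }
  structure(list(dw = dw, dw_b = numeric(in_channels), pw = pw,
                 pw_b = numeric(out_channels), spec = spec,
                 in_channels = in_channels, out_channels = out_channels),
            class = "dsconv_weights")
}

#' Create weights for a mixed depthwise-separable convolution
#'
#' One depthwise kernel stack and one pointwise mixer per channel group; the
#' group structure comes from a [mixconv_spec()]. Input and output channels
#' are split into equal contiguous groups (the first group takes any
#' remainder).
#'
#' @param spec a [mixconv_spec()].
#' @inheritParams conv_weights
#' @return List of class `mixconv_weights`.
#' @export
mixconv_weights <- function(spec, init = c("he", "zero"), seed = 1L) {
  init <- match.arg(init)
  stopifnot(inherits(spec, "mixconv_spec"))
  ng <- length(spec$groups)
  in_idx <- split_channels(spec$in_channels, ng)
  out_sz <- vapply(split_channels(spec$out_channels, ng), length, 1L)
  seeds <- derive_seeds(seed, ng)
  groups <- vector("list", ng)
  for (g in seq_len(ng)) {
    ks <- spec$groups[[g]]
    cg <- length(in_idx[[g]])
    og <- out_sz[g]
    k <- ks$size
    if (init == "zero") {
      dw <- array(0, c(k, k, cg)); pw <- matrix(0, cg, og)
    } else {
      ss <- derive_seeds(seeds[g], 2L)
      dw <- with_seed(ss[1L], he_init(c(k, k, cg), k * k))
      pw <- with_seed(ss[2L], he_init(c(cg, og), cg))
      dim(pw) <- c(cg, og)
    }
    groups[[g]] <- list(kernel = ks, in_idx = in_idx[[g]], dw = dw,
                        dw_b = numeric(cg), pw = pw, pw_b = numeric(og))
  }
  structure(list(spec = spec, groups = groups), class = "mixconv_weights")
}

apply_activation <- function(y, activation) {
  switch(activation, relu = relu(y), linear = y,
         stop("unknown activation", call. = FALSE))
}

#' Plain convolution block
#'
#' Same-padded stride-1 convolution plus bias and (by default) a ReLU
#' activation; spatial size is preserved and the channel count becomes the
#' kernel count of `weights`.
#'
#' @param x feature map, an `H x W x C` numeric array (a matrix is treated as
#'   single-channel).
#' @param weights a [conv_weights()] object.
#' @param activation `"relu"` (default) or `"linear"` for the pre-activation
#'   output.
#' @return An `H x W x out_channels` array.
#' @export
conv_block <- function(x, weights, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  x <- assert_feature_map(x)
  stopifnot(inherits(weights, "conv_weights"))
  if (dim(x)[3L] != weights$in_channels)
    stop(sprintf("input has %d channels but weights expect %d",
                 dim(x)[3L], weights$in_channels), call. = FALSE)
  y <- cpp_conv2d_fwd(x, weights$w, weights$b, weights$spec$dilation)
  apply_activation(y, activation)
}

#' Depthwise-separable convolution block
#'
#' Each input channel is convolved independently with its own spatial kernel
#' (depthwise stage), then a 1 x 1 pointwise convolution mixes channels to
#' `out_channels`.
#'
#' @inheritParams conv_block
#' @param weights a [dsconv_weights()] object.
#' @export
depthwise_separable_conv <- function(x, weights,
                                     activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  x <- assert_feature_map(x)
  stopifnot(inherits(weights, "dsconv_weights"))
  if (dim(x)[3L] != weights$in_channels)
    stop(sprintf("input has %d channels but weights expect %d",
                 dim(x)[3L], weights$in_channels), call. = FALSE)
  d <- cpp_dwconv_fwd(x, weights$dw, weights$dw_b, weights$spec$dilation)
  m <- fm_mat(d) %*% weights$pw
  m <- m + rep(weights$pw_b, each = nrow(m))
  apply_activation(mat_fm(m, dim(x)[1L], dim(x)[2L]), activation)
}

#' Mixed depthwise-separable convolution (MixConv)
#'
#' Input channels are partitioned into contiguous groups; group `k` is
#' filtered depthwise with its own kernel (size/dilation from the spec) and
#' mixed to its share of the output channels by a per-group pointwise 1 x 1
#' convolution; group outputs are concatenated in order. With a single group
#' this is exactly [depthwise_separable_conv()].
#'
#' @inheritParams conv_block
#' @param weights a [mixconv_weights()] object.
#' @export
mixconv <- function(x, weights, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  x <- assert_feature_map(x)
  stopifnot(inherits(weights, "mixconv_weights"))
  if (dim(x)[3L] != weights$spec$in_channels)
    stop(sprintf("input has %d channels but the MixConv spec expects %d",
                 dim(x)[3L], weights$spec$in_channels), call. = FALSE)
  h <- dim(x)[1L]; w <- dim(x)[2L]
  outs <- lapply(weights$groups, function(g) {
    xs <- x[, , g$in_idx, drop = FALSE]
    d <- cpp_dwconv_fwd(xs, g$dw, g$dw_b, g$kernel$dilation)
    m <- fm_mat(d) %*% g$pw
    m + rep(g$pw_b, each = nrow(m))
  })
  y <- mat_fm(do.call(cbind, outs), h, w)
  apply_activation(y, activation)
}

#' Spatial max pooling
#'
#' Per-channel maximum over non-overlapping `size x size` windows; height and
#' width are divided by `size` (any remainder rows/columns are dropped).
#'
#' @inheritParams conv_block
#' @param size pooling window edge, a positive integer.
#' @export
max_pool <- function(x, size = 2L) {
  x <- assert_feature_map(x)
  size <- check_positive_int(size, "size")
  if (any(dim(x)[1:2] < size))
    stop("pooling window larger than the feature map", call. = FALSE)
  cpp_maxpool_fwd(x, size)$y
}
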