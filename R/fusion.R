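# Bilinear fusion head: position-wise outer product of two feature maps,
# sum-pooled over positions, then signed square root and L2 normalisation.
# The result is a second-order (covariance-like) descriptor of length
# M1 * M2 that couples every deep channel with every shallow channel.

#' Bilinear pooling of two feature maps
#'
#' Computes `b[u, v] = sum_p f1[p, u] * f2[p, v]` over all `H * W` spatial
#' positions `p`: the channel-by-channel outer product at each position,
#' aggregated by sum pooling. The two maps must share their spatial grid;
#' channel counts may differ.
#'
#' @param f1,f2 feature maps (`H x W x M1`, `H x W x M2`) on the same grid.
#' @return An `M1 x M2` numeric matrix.
#' @examples
#' f <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
#' g <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
#' dim(bilinear_pool(f, g))  # 3 x 4
#' @export
bilinear_pool <- function(f1, f2) {
  f1 <- assert_feature_map(f1, "f1")
  f2 <- assert_feature_map(f2, "f2")
  d1 <- dim(f1); d2 <- dim(f2)
  if (!identical(d1[1:2], d2[1:2]))
    stop(sprintf("spatial grids differ: f1 is %dx%dx%d, f2 is %dx%dx%d",
                 d1[1], d1[2], d1[3], d2[1], d2[2], d2[3]), call. = FALSE)
  crossprod(fm_mat(f1), fm_mat(f2))
}

#' Signed square root
#'
#' Elementwise `sign(z) * sqrt(|z|)`, the variance-stabilising normalisation
#' applied to bilinear features. It is an odd, order-preserving function with
#' fixed point 0.
#'
#' @param z numeric vector, matrix or array of finite values.
#' @export
signed_sqrt <- function(z) {
  if (!all(is.finite(z))) stop("`z` must be finite", call. = FALSE)
  sign(z) * sqrt(abs(z))
}

#' L2 normalisation
#'
#' `x / ||x||_2`, guarded by a tiny epsilon inside the norm so that an
#' all-zero input maps to an all-zero output rather than an error, and so
#' that gradients stay finite during training.
#'
#' @param x numeric vector of finite values.
#' @param eps non-negative guard added to the squared norm.
#' @export
l2_normalize <- function(x, eps = 1e-12) {
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  x / sqrt(sum(x^2) + eps)
}

#' Bilinear fusion descriptor
#'
#' Full fusion head: [bilinear_pool()], flattened (column-major) to a vector
#' of length `M1 * M2`, then [signed_sqrt()] and [l2_normalize()]. For the
#' published models both branches carry 128 channels, so the descriptor has
#' length 16384 and unit Euclidean norm.
#'
#' @inheritParams bilinear_pool
#' @return Numeric vector of length `M1 * M2`.
#' @export
fuse <- function(f1, f2) {
  b <- bilinear_pool(f1, f2)
  l2_normalize(signed_sqrt(as.vector(b)))
}
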