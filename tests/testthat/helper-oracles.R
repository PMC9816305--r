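# Brute-force loop oracles, independent of the package's fast paths, plus
# small fixture builders. Everything is generated in code under fixed seeds.

rand_fm <- function(h, w, c, seed = 1) {
  set.seed(seed)
  array(rnorm(h * w * c), c(h, w, c))
}

# Plain same-padded cross-correlation by explicit quadruple loop.
oracle_conv2d <- function(x, w, b, dilation = 1L) {
  k <- dim(w)[1L]; cin <- dim(w)[3L]; cout <- dim(w)[4L]
  h <- dim(x)[1L]; wd <- dim(x)[2L]
  c0 <- (k - 1L) / 2L
  y <- array(0, c(h, wd, cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(h)) for (j in seq_len(wd)) {
      acc <- b[co]
      for (ti in seq_len(k)) for (tj in seq_len(k)) {
        ii <- i + dilation * (ti - 1L - c0)
        jj <- j + dilation * (tj - 1L - c0)
        if (ii >= 1L && ii <= h && jj >= 1L && jj <= wd)
          for (ci in seq_len(cin))
            acc <- acc + x[ii, jj, ci] * w[ti, tj, ci, co]
      }
      y[i, j, co] <- acc
    }
  }
  y
}

# Depthwise convolution by explicit loops (one kernel per channel).
oracle_dwconv <- function(x, w, b, dilation = 1L) {
  k <- dim(w)[1L]; ch <- dim(w)[3L]
  h <- dim(x)[1L]; wd <- dim(x)[2L]
  c0 <- (k - 1L) / 2L
  y <- array(0, c(h, wd, ch))
  for (c in seq_len(ch)) {
    for (i in seq_len(h)) for (j in seq_len(wd)) {
      acc <- b[c]
      for (ti in seq_len(k)) for (tj in seq_len(k)) {
        ii <- i + dilation * (ti - 1L - c0)
        jj <- j + dilation * (tj - 1L - c0)
        if (ii >= 1L && ii <= h && jj >= 1L && jj <= wd)
          acc <- acc + x[ii, jj, c] * w[ti, tj, c]
      }
      y[i, j, c] <- acc
    }
  }
  y
}

# Depthwise-separable conv: loop channels for the depthwise stage, then mix
# with an explicit 1x1 loop.
oracle_dsconv <- function(x, wts) {
  d <- oracle_dwconv(x, wts$dw, wts$dw_b, wts$spec$dilation)
  h <- dim(x)[1L]; wd <- dim(x)[2L]
  cout <- ncol(wts$pw)
  y <- array(0, c(h, wd, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(wts$pw_b[co], h, wd)
    for (ci in seq_len(dim(d)[3L]))
      acc <- acc + d[, , ci] * wts$pw[ci, co]
    y[, , co] <- acc
  }
  y
}

# MixConv: process each channel group independently, concatenate outputs.
oracle_mixconv <- function(x, wts) {
  outs <- lapply(wts$groups, function(g) {
    xs <- x[, , g$in_idx, drop = FALSE]
    d <- oracle_dwconv(xs, g$dw, g$dw_b, g$kernel$dilation)
    h <- dim(x)[1L]; wd <- dim(x)[2L]
    og <- ncol(g$pw)
    y <- array(0, c(h, wd, og))
    for (co in seq_len(og)) {
      acc <- matrix(g$pw_b[co], h, wd)
      for (ci in seq_len(dim(d)[3L]))
        acc <- acc + d[, , ci] * g$pw[ci, co]
      y[, , co] <- acc
    }
    y
  })
  out <- array(0, c(dim(x)[1:2], wts$spec$out_channels))
  at <- 0L
  for (o in outs) {
    out[, , at + seq_len(dim(o)[3L])] <- o
    at <- at + dim(o)[3L]
  }
  out
}

# Bilinear pooling by triple loop over (u, v, position).
oracle_bilinear <- function(f1, f2) {
  m1 <- dim(f1)[3L]; m2 <- dim(f2)[3L]
  h <- dim(f1)[1L]; w <- dim(f1)[2L]
  b <- matrix(0, m1, m2)
  for (u in seq_len(m1)) for (v in seq_len(m2))
    for (i in seq_len(h)) for (j in seq_len(w))
      b[u, v] <- b[u, v] + f1[i, j, u] * f2[i, j, v]
  b
}

# Directional means by explicit loops.
oracle_coord_pool <- function(x) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; ch <- dim(x)[3L]
  s_h <- matrix(0, h, ch); s_w <- matrix(0, w, ch)
  for (c in seq_len(ch)) {
    for (i in seq_len(h)) s_h[i, c] <- mean(x[i, , c])
    for (j in seq_len(w)) s_w[j, c] <- mean(x[, j, c])
  }
  list(s_h = s_h, s_w = s_w)
}

# Full attention block recomputed with plain loops and explicit broadcasting
# from the same weights.
oracle_mam <- function(x, wts) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; ch <- dim(x)[3L]
  cp <- oracle_coord_pool(x)
  tmat <- rbind(cp$s_h, cp$s_w)
  u <- tmat %*% wts$w1
  for (j in seq_len(ncol(u))) u[, j] <- u[, j] + wts$b1[j]
  f <- pmax(u, 0)
  f_h <- f[seq_len(h), , drop = FALSE]
  f_w <- f[-seq_len(h), , drop = FALSE]
  a_h <- f_h %*% wts$wh; a_w <- f_w %*% wts$ww
  for (j in seq_len(ch)) {
    a_h[, j] <- a_h[, j] + wts$bh[j]
    a_w[, j] <- a_w[, j] + wts$bw[j]
  }
  g_h <- 1 / (1 + exp(-a_h))
  g_w <- 1 / (1 + exp(-a_w))
  avg <- matrix(0, h, w); mx <- matrix(-Inf, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    avg[i, j] <- mean(x[i, j, ])
    mx[i, j] <- max(x[i, j, ])
  }
  s <- array(c(avg, mx), c(h, w, 2L))
  a <- oracle_conv2d(s, wts$ws, wts$bs, 1L)[, , 1L]
  g <- 1 / (1 + exp(-a))
  y <- array(0, dim(x))
  for (i in seq_len(h)) for (j in seq_len(w)) for (c in seq_len(ch))
    y[i, j, c] <- x[i, j, c] * (g_h[i, c] + g_w[j, c] + g[i, j]) / 3
  y
}

# Tiny trained-model fixture shared by model tests (small input keeps the
# conv stack cheap while exercising every layer).
tiny_model <- function(variant = "lightweight_mam", nc = 3L, seed = 3L) {
  msfbf_build(variant, num_classes = nc, input_shape = c(12L, 20L), seed = seed)
}
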