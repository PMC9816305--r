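# Shared internal helpers: validation, activations, seeded RNG.

# Coerce a matrix (single channel) or 3-d array to an H x W x C feature map.
as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  x
}

assert_feature_map <- function(x, what = "x") {
  x <- as_feature_map(x)
  if (!is.array(x) || length(dim(x)) != 3L || !is.numeric(x))
    stop(sprintf("`%s` must be an H x W x C numeric array", what), call. = FALSE)
  if (any(dim(x) < 1L))
    stop(sprintf("`%s` has a zero-length dimension", what), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values (NA/NaN/Inf are rejected)", what),
         call. = FALSE)
  x
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Flatten an H x W x C array to an (H*W) x C matrix (positions by channels).
fm_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L] * d[2L], d[3L])
  x
}

mat_fm <- function(m, h, w) {
  dim(m) <- c(h, w, ncol(m))
  m
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic stream of sub-seeds (< 2^31) derived from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

check_positive_int <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != round(x))
    stop(sprintf("`%s` must be a positive integer", what), call. = FALSE)
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
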