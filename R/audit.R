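# Closed-form architecture audit: trainable parameters and multiply-
# accumulate operations per layer and in total.
#
# Conventions (the ones under which the published budgets reproduce):
#   * one MAC is reported as one Flop (common profiler convention);
#   * a conv layer costs k^2 * (Cin/groups) * Cout * Hout * Wout MACs,
#     a depthwise stage k^2 * Cin * H * W, a fully connected layer in * out;
#   * pooling, activations, sigmoid gates, the elementwise attention
#     average and the bilinear sqrt/L2 head cost zero MACs; the bilinear
#     sum-pooling itself is likewise not a weighted layer and counts zero;
#   * biases contribute parameters but no MACs.

conv_count <- function(k, cin, cout, hw, dilated = FALSE) {
  list(params = k * k * cin * cout + cout, macs = k * k * cin * cout * hw)
}

dsconv_count <- function(k, cin, cout, hw) {
  list(params = k * k * cin + cin + cin * cout + cout,
       macs = k * k * cin * hw + cin * cout * hw)
}

mixconv_count <- function(sizes, cin, cout, hw) {
  ng <- length(sizes)
  ins <- vapply(split_channels(cin, ng), length, 1L)
  outs <- vapply(split_channels(cout, ng), length, 1L)
  p <- 0; m <- 0
  for (g in seq_len(ng)) {
    k <- sizes[g]
    p <- p + k * k * ins[g] + ins[g] + ins[g] * outs[g] + outs[g]
    m <- m + k * k * ins[g] * hw + ins[g] * outs[g] * hw
  }
  list(params = p, macs = m)
}

mam_count <- function(ch, r, h, w) {
  cr <- max(1L, as.integer(ceiling(ch / r)))
  p <- ch * cr + cr +          # shared 1x1 reduction
    2 * (cr * ch + ch) +       # per-direction 1x1 restore
    7 * 7 * 2 * 1 + 1          # spatial 7x7, 2 -> 1 channels
  m <- ch * cr * (h + w) + cr * ch * h + cr * ch * w + 7 * 7 * 2 * h * w
  list(params = p, macs = m)
}

#' Audit a model architecture
#'
#' Computes, per layer and in total, the number of trainable parameters and
#' multiply-accumulate operations (MACs) of an architecture from closed
#' forms, without touching any weights. `params_M` is the total in millions
#' rounded to one decimal; `gflops` is MACs / 1e9 rounded to two significant
#' digits, the precision at which such budgets are conventionally printed.
#'
#' @param x an `msfbf` model, an `msfbf_config`, or a variant name
#'   (`"full"`, `"lightweight"`, `"lightweight_mam"`).
#' @param num_classes class count used when `x` is a variant name
#'   (default 492).
#' @param input_shape input height/width used when `x` is a variant name.
#' @param r attention reduction ratio (variant-name form only).
#' @return Object of class `msfbf_audit`: a per-layer data frame plus exact
#'   integer totals, `params_M` and `gflops`.
#' @examples
#' msfbf_audit("lightweight", num_classes = 492)
#' @export
msfbf_audit <- function(x, num_classes = 492L, input_shape = c(60L, 180L),
                        r = 8L) {
  config <- if (inherits(x, "msfbf")) x$config
            else if (inherits(x, "msfbf_config")) x
            else msfbf_config(x, num_classes, input_shape, r)
  hs <- config$input_shape
  hw0 <- prod(hs)                 # 60 x 180
  hw1 <- prod(hs %/% 2L)          # 30 x 90
  hw2 <- prod(hs %/% 4L)          # 15 x 45
  wd <- config$widths
  lw <- config$variant != "full"
  row <- function(name, cnt) data.frame(layer = name, params = cnt$params,
                                        macs = cnt$macs)
  cnt <- function(sizes, cin, cout, hw) {
    if (lw) mixconv_count(sizes, cin, cout, hw)
    else conv_count(max(sizes), cin, cout, hw)
  }
  rows <- rbind(
    row("Conv0", cnt(3L, 1L, wd[["conv0"]], hw0)),
    row("Max0", list(params = 0, macs = 0)),
    row("Conv1", cnt(3L, wd[["conv0"]], wd[["conv1"]], hw1)),
    row("Max1", list(params = 0, macs = 0)),
    row("Shallow1x1", conv_count(1L, wd[["conv1"]], 128L, hw2)),
    row("Conv2", cnt(c(3L, 3L), wd[["conv1"]], wd[["conv2"]], hw2)),
    row("Conv3", cnt(c(3L, 3L), wd[["conv2"]], wd[["conv3"]], hw2)),
    row("Conv4", cnt(1L, wd[["conv3"]], wd[["conv4"]], hw2)))
  if (config$variant == "lightweight_mam") {
    d2 <- hs %/% 4L
    rows <- rbind(rows, row("MAM", mam_count(128L, config$r, d2[1L], d2[2L])))
  }
  rows <- rbind(rows,
                row("BilinearFusion", list(params = 0, macs = 0)),
                row("FC", list(params = (config$fused_dim + 1) * config$num_classes,
                               macs = config$fused_dim * config$num_classes)))
  # `full` uses a plain 3x3 for Conv2/Conv3 (single kernel size); the
  # `cnt(c(3,3), ...)` call above passes max(sizes) = 3 in that case.
  total_params <- sum(rows$params)
  total_macs <- sum(rows$macs)
  structure(list(layers = rows, total_params = total_params,
                 total_macs = total_macs,
                 params_M = round(total_params / 1e6, 1L),
                 gflops = signif(total_macs / 1e9, 2L),
                 config = config),
            class = "msfbf_audit")
}

#' @export
print.msfbf_audit <- function(x, ...) {
  cat(sprintf("Architecture audit: %s, %d classes, input %dx%d\n",
              x$config$variant, x$config$num_classes,
              x$config$input_shape[1L], x$config$input_shape[2L]))
  df <- x$layers
  df$params <- format(df$params, big.mark = ",")
  df$macs <- format(df$macs, big.mark = ",")
  print(df, row.names = FALSE)
  cat(sprintf("Total: %s parameters (%.1f M), %s MACs (%.4g GFlops)\n",
              format(x$total_params, big.mark = ","), x$params_M,
              format(x$total_macs, big.mark = ","), x$gflops))
  invisible(x)
}

#' Audit report as a JSON-ready list
#'
#' @param x an `msfbf_audit` object.
#' @keywords internal
audit_as_list <- function(x) {
  list(variant = x$config$variant,
       num_classes = x$config$num_classes,
       input_shape = x$config$input_shape,
       layers = x$layers,
       total_params = x$total_params,
       total_macs = x$total_macs,
       params_M = x$params_M,
       gflops = x$gflops)
}
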