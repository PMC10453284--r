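# Multi-scale Vessel Extraction: a U-shaped encoder/decoder whose encoder
# stages are split-concat residual blocks in the Res2Net style.  Each block
# passes a 1x1-conv'd feature map through a cascade of small 3x3
# convolutions: subset i is concatenated with the output of the previous
# small conv before its own conv, so late subsets see an increasingly large
# receptive field at a fraction of the parameters of one wide convolution.

#' Configuration of the vessel-extraction network
#'
#' @param base_width channels at the first encoder stage (doubling per
#'   stage); 64 at full scale, reduce for desk-scale runs
#' @param depth number of 2x down-samplings
#' @param n_subsets number of channel subsets in the split-concat block
#' @param kernel small-convolution kernel size
#' @param block encoder stage type: `"res2net"` (default) or `"conv"` (plain
#'   double-conv U-Net stage, used by the ablation machinery)
#' @return an `mve_config` list
#' @export
mve_config <- function(base_width = 64, depth = 4, n_subsets = 4, kernel = 3,
                       block = c("res2net", "conv")) {
  block <- match.arg(block)
  if (base_width %% n_subsets != 0) {
    stop(sprintf("base_width (%d) must be divisible by n_subsets (%d)",
                 base_width, n_subsets))
  }
  structure(list(base_width = base_width, depth = depth,
                 n_subsets = n_subsets, kernel = as.integer(kernel),
                 block = block),
            class = "mve_config")
}

res2net_block_new <- function(cin, cout, n_subsets, kernel = 3L) {
  if (cout %% n_subsets != 0) {
    stop(sprintf("block width %d not divisible into %d subsets", cout, n_subsets))
  }
  cs <- cout %/% n_subsets
  list(
    type = "res2net",
    n_subsets = n_subsets,
    conv_in = cbr_layer(1L, cin, cout),
    fi = lapply(seq_len(n_subsets - 1L), function(i) cbr_layer(kernel, 2L * cs, cs)),
    conv_out = list(conv = conv_layer(1L, cout, cout), bn = bn_new(cout)),
    shortcut = if (cin != cout) {
      list(conv = conv_layer(1L, cin, cout), bn = bn_new(cout))
    } else NULL
  )
}

#' Forward pass of one split-concat residual block
#'
#' Computes `u = relu(bn(conv1x1(x)))`, splits `u` into `s` channel subsets,
#' sets `y_1 = u_1` and `y_i = F_i(concat(u_i, y_{i-1}))` for `i > 1` where
#' each `F_i` is a 3x3 conv + BN + ReLU, then applies a 1x1 conv + BN to the
#' concatenated `y_i` and adds a (projected) residual shortcut of the input.
#'
#' @param blk a block created by the network constructor
#' @param x input node or (H, W, C, N) array
#' @param training batch-norm mode
#' @return output node, same spatial size, `cout` channels
#' @keywords internal
res2net_block_fwd <- function(blk, x, training = FALSE) {
  u <- cbr_apply(blk$conv_in, x, training)
  s <- blk$n_subsets
  cout <- dim(u$v)[3]
  cs <- cout %/% s
  ys <- vector("list", s)
  ys[[1]] <- nn_slice_c(u, seq_len(cs))
  for (i in 2:s) {
    ui <- nn_slice_c(u, (i - 1L) * cs + seq_len(cs))
    ys[[i]] <- cbr_apply(blk$fi[[i - 1L]], nn_concat(list(ui, ys[[i - 1L]])), training)
  }
  out <- nn_bn(conv_apply(blk$conv_out$conv, nn_concat(ys)), blk$conv_out$bn, training)
  sh <- if (is.null(blk$shortcut)) as_node(x) else {
    nn_bn(conv_apply(blk$shortcut$conv, x), blk$shortcut$bn, training)
  }
  nn_relu(nn_add(out, sh))
}

stage_block_new <- function(type, cin, cout, n_subsets, kernel) {
  if (type == "res2net") res2net_block_new(cin, cout, n_subsets, kernel)
  else c(double_conv_layer(cin, cout), type = "conv")
}

stage_block_fwd <- function(blk, x, training) {
  if (identical(blk$type, "res2net")) res2net_block_fwd(blk, x, training)
  else double_conv_apply(blk, x, training)
}

# shared U-Net decoder: upsample, 1x1 conv, concat skip, double conv
decoder_new <- function(widths) {
  depth <- length(widths) - 1L
  lapply(seq_len(depth), function(i) {
    list(up = conv_layer(1L, widths[i + 1L], widths[i]),
         conv = double_conv_layer(2L * widths[i], widths[i]))
  })
}

decoder_fwd <- function(dec, bottom, skips, training) {
  x <- bottom
  for (i in seq(length(dec), 1L)) {
    x <- conv_apply(dec[[i]]$up, nn_up2(x))
    x <- double_conv_apply(dec[[i]]$conv, nn_concat(list(x, skips[[i]])), training)
  }
  x
}

check_pool_compatible <- function(d, depth, what = "input") {
  div <- 2L^depth
  if (d[1] %% div != 0L || d[2] %% div != 0L) {
    stop(sprintf(
      "%s size %dx%d is not divisible by 2^depth = %d; pad or resize first",
      what, d[1], d[2], div))
  }
}

mve_new <- function(cfg, in_channels = 1L) {
  stopifnot(inherits(cfg, "mve_config"))
  widths <- cfg$base_width * 2L^(0:cfg$depth)
  cins <- c(in_channels, widths[-length(widths)])
  list(
    cfg = cfg,
    enc = lapply(seq_len(cfg$depth), function(i) {
      stage_block_new(cfg$block, cins[i], widths[i], cfg$n_subsets, cfg$kernel)
    }),
    bottleneck = stage_block_new(cfg$block, widths[cfg$depth],
                                 widths[cfg$depth + 1L], cfg$n_subsets, cfg$kernel),
    dec = decoder_new(widths),
    final = conv_layer(1L, widths[1], 1L)
  )
}

#' Vessel-extraction forward pass
#'
#' @param model the `mve` component of an [msc_new()] model
#' @param x (H, W, 1, N) array or node; H and W must be divisible by
#'   2^depth
#' @param training batch-norm mode
#' @return node with per-pixel vessel probabilities in [0, 1], shape
#'   (H, W, 1, N)
#' @keywords internal
mve_forward <- function(model, x, training = FALSE) {
  x <- as_node(x)
  check_pool_compatible(dim(x$v), model$cfg$depth)
  skips <- vector("list", model$cfg$depth)
  for (i in seq_len(model$cfg$depth)) {
    skips[[i]] <- stage_block_fwd(model$enc[[i]], x, training)
    x <- nn_maxpool2(skips[[i]])
  }
  x <- stage_block_fwd(model$bottleneck, x, training)
  x <- decoder_fwd(model$dec, x, skips, training)
  nn_sigmoid(conv_apply(model$final, x))
}
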