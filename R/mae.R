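# Multi-structure A/V Extraction: a U-shaped hybrid whose encoder stages are
# followed by a contextual-attention ("transformer-like") block.  Instead of
# a global query-key product, queries are concatenated with a statically
# convolved key representation; two 1x1 convolutions turn that into per-pixel
# softmax weights over a small local neighborhood, which aggregate the value
# map (a local matrix multiplication).  Cost is therefore linear in the
# pixel count rather than quadratic.

#' Reference scaled dot-product attention
#'
#' The standard formulation `softmax(Q K^T / sqrt(d_k)) V` over token
#' matrices.  This is a small readable oracle used in the tests and
#' documentation to contrast with the local contextual attention the network
#' actually uses; it is not part of the production forward pass.
#'
#' @param Q,K,V numeric matrices (tokens x dim); Q and K share `d_k` columns
#'   and K and V share their token count
#' @return matrix of attended values, `nrow(Q)` x `ncol(V)`
#' @export
standard_attention <- function(Q, K, V) {
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension")
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of tokens")
  s <- Q %*% t(K) / sqrt(ncol(K))
  w <- exp(s - apply(s, 1, max))
  w <- w / rowSums(w)
  w %*% V
}

#' Configuration of the contextual-attention block
#'
#' @param channels feature channels C
#' @param key_kernel kernel of the grouped static-context convolution on K
#' @param groups channel groups sharing one set of attention weights;
#'   must divide `channels`
#' @param attn_kernel local aggregation neighborhood side k_a (odd); the
#'   attention softmax runs over the k_a^2 offsets
#' @return a `cot_config` list
#' @export
cot_config <- function(channels, key_kernel = 3, groups = 4, attn_kernel = 3) {
  if (channels %% groups != 0) {
    stop(sprintf("channels (%d) must be divisible by groups (%d)", channels, groups))
  }
  if (key_kernel %% 2 == 0 || attn_kernel %% 2 == 0) stop("kernels must be odd")
  structure(list(channels = as.integer(channels),
                 key_kernel = as.integer(key_kernel),
                 groups = as.integer(groups),
                 attn_kernel = as.integer(attn_kernel)),
            class = "cot_config")
}

cot_new <- function(cfg) {
  stopifnot(inherits(cfg, "cot_config"))
  C <- cfg$channels
  k2 <- cfg$attn_kernel^2
  list(
    cfg = cfg,
    conv_x = cbr_layer(3L, C, C),                    # X = Conv3x3(input); Q = K = X
    conv_v = conv_layer(1L, C, C),                   # V = W_v(X)
    conv_k = cbr_layer(cfg$key_kernel, C, C, groups = cfg$groups),  # static context
    attn1 = conv_layer(1L, 2L * C, C),               # W_theta, ReLU-activated
    attn2 = conv_layer(1L, C, cfg$groups * k2)       # W_delta, linear
  )
}

#' Forward pass of the contextual-attention block
#'
#' `X = conv3x3(input)`; `V = 1x1 conv of X`; static context
#' `K_s = grouped conv(K)` with `Q = K = X`; attention logits
#' `W_delta(relu(W_theta(concat(K_s, Q))))` are softmaxed over the local
#' k_a x k_a offsets per group and aggregate V into the dynamic context `D`
#' (zero padding outside the image).  Output is `K_s + D`, the sum of the
#' static and dynamic representations.
#'
#' @param blk block from `cot_new()`
#' @param x node or array (H, W, C, N) with `C = cfg$channels`
#' @param training batch-norm mode
#' @param return_attention also return the attention weight node (tests)
#' @keywords internal
cot_block_fwd <- function(blk, x, training = FALSE, return_attention = FALSE) {
  x <- as_node(x)
  if (dim(x$v)[3] != blk$cfg$channels) {
    stop(sprintf("cot block expects %d channels, got %d",
                 blk$cfg$channels, dim(x$v)[3]))
  }
  k2 <- blk$cfg$attn_kernel^2
  X <- cbr_apply(blk$conv_x, x, training)
  V <- conv_apply(blk$conv_v, X)
  Ks <- cbr_apply(blk$conv_k, X, training)
  logits <- conv_apply(blk$attn2, nn_relu(conv_apply(blk$attn1, nn_concat(list(Ks, X)))))
  A <- nn_softmax_offsets(logits, k2, blk$cfg$groups)
  D <- nn_local_attn(A, V, blk$cfg$attn_kernel, blk$cfg$groups)
  out <- nn_add(Ks, D)
  if (return_attention) list(out = out, attention = A) else out
}

#' Configuration of the A/V-extraction network
#'
#' Same U-shaped scaffold as the vessel network; `attention = FALSE` turns
#' every encoder stage into a plain double-conv U-Net stage (ablation).
#'
#' @param base_width,depth as in [mve_config()]
#' @param key_kernel,groups,attn_kernel contextual-attention settings
#' @param attention use contextual-attention blocks in the encoder
#' @param n_classes output classes (background / artery / vein)
#' @return an `mae_config` list
#' @export
mae_config <- function(base_width = 64, depth = 4, key_kernel = 3, groups = 4,
                       attn_kernel = 3, attention = TRUE, n_classes = 3) {
  structure(list(base_width = base_width, depth = depth,
                 key_kernel = key_kernel, groups = groups,
                 attn_kernel = attn_kernel, attention = attention,
                 n_classes = as.integer(n_classes)),
            class = "mae_config")
}

mae_new <- function(cfg, in_channels = 4L) {
  stopifnot(inherits(cfg, "mae_config"))
  widths <- cfg$base_width * 2L^(0:cfg$depth)
  cins <- c(in_channels, widths[-length(widths)])
  stage <- function(cin, cout) {
    if (cfg$attention) {
      list(pre = cbr_layer(3L, cin, cout),
           cot = cot_new(cot_config(cout, cfg$key_kernel, cfg$groups, cfg$attn_kernel)))
    } else {
      double_conv_layer(cin, cout)
    }
  }
  list(
    cfg = cfg,
    enc = lapply(seq_len(cfg$depth), function(i) stage(cins[i], widths[i])),
    bottleneck = stage(widths[cfg$depth], widths[cfg$depth + 1L]),
    dec = decoder_new(widths),
    final = conv_layer(1L, widths[1], cfg$n_classes)
  )
}

mae_stage_fwd <- function(cfg, st, x, training) {
  if (cfg$attention) cot_block_fwd(st$cot, cbr_apply(st$pre, x, training), training)
  else double_conv_apply(st, x, training)
}

#' A/V-extraction forward pass
#'
#' @param model the `mae` component of an [msc_new()] model
#' @param x (H, W, 4, N) node or array: raw RGB in [0,1] concatenated with
#'   the vessel probability map
#' @param training batch-norm mode
#' @return list with `logits` (H, W, n_classes, N) and `features`, the
#'   penultimate decoder feature map consumed by the fusion module
#' @keywords internal
mae_forward <- function(model, x, training = FALSE) {
  x <- as_node(x)
  check_pool_compatible(dim(x$v), model$cfg$depth)
  skips <- vector("list", model$cfg$depth)
  for (i in seq_len(model$cfg$depth)) {
    skips[[i]] <- mae_stage_fwd(model$cfg, model$enc[[i]], x, training)
    x <- nn_maxpool2(skips[[i]])
  }
  x <- mae_stage_fwd(model$cfg, model$bottleneck, x, training)
  feats <- decoder_fwd(model$dec, x, skips, training)
  list(logits = conv_apply(model$final, feats), features = feats)
}
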