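# Differentiable tensor operations.  Each op takes nodes (or nn_param /
# plain arrays, which are wrapped), computes the value eagerly, and when a
# tape is active registers a backward closure returning one gradient per
# parent, in order.

nn_conv2d <- function(x, w, b, pad = NULL, groups = 1L) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  k <- dim(w$v)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  v <- conv2d_fwd(x$v, w$v, b$v, pad, groups)
  if (!recording()) return(node_new(v))
  xv <- x$v; wv <- w$v
  node_new(v, parents = list(x, w, b), bw = function(g) {
    r <- conv2d_bwd(xv, wv, g, pad, groups)
    list(r$dx, r$dw, r$db)
  })
}

# Batch normalisation over (H, W, N) per channel.  `st` is a bn state created
# by bn_new(); running statistics are updated in training mode.
bn_new <- function(channels, momentum = 0.1, eps = 1e-5) {
  st <- new.env(parent = emptyenv())
  st$gamma <- nn_param(rep(1, channels))
  st$beta <- nn_param(rep(0, channels))
  st$rm <- rep(0, channels)
  st$rv <- rep(1, channels)
  st$momentum <- momentum
  st$eps <- eps
  class(st) <- "nn_bn"
  st
}

nn_bn <- function(x, st, training) {
  x <- as_node(x)
  d <- dim(x$v)
  gnode <- as_node(st$gamma); bnode <- as_node(st$beta)
  if (training) {
    m <- channel_mean(x$v)
    v <- channel_dot(x$v, x$v) - m * m
    v[v < 0] <- 0
    st$rm <- (1 - st$momentum) * st$rm + st$momentum * m
    st$rv <- (1 - st$momentum) * st$rv + st$momentum * v
  } else {
    m <- st$rm; v <- st$rv
  }
  inv <- 1 / sqrt(v + st$eps)
  xhat <- scale_shift(x$v, inv, -m * inv)
  out <- scale_shift(xhat, st$gamma$v, st$beta$v)
  if (!recording()) return(node_new(out))
  gam <- st$gamma$v
  n_per_c <- d[1] * d[2] * d[4]
  node_new(out, parents = list(x, gnode, bnode), bw = function(g) {
    dgamma <- channel_dot(g, xhat) * n_per_c
    dbeta <- channel_mean(g) * n_per_c
    dxhat <- scale_shift(g, gam, numeric(d[3]))
    if (training) {
      # standard batch-norm backward through the batch statistics
      mu_dxhat <- channel_mean(dxhat)
      mu_dxhat_xhat <- channel_dot(dxhat, xhat)
      dx <- scale_shift(dxhat - xhat * rep(mu_dxhat_xhat, each = d[1] * d[2]),
                        inv, -mu_dxhat * inv)
    } else {
      dx <- scale_shift(dxhat, inv, numeric(d[3]))
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

nn_relu <- function(x) {
  x <- as_node(x)
  v <- x$v
  v[v < 0] <- 0
  if (!recording()) return(node_new(v))
  mask <- x$v > 0
  node_new(v, parents = list(x), bw = function(g) list(g * mask))
}

nn_sigmoid <- function(x) {
  x <- as_node(x)
  v <- 1 / (1 + exp(-x$v))
  if (!recording()) return(node_new(v))
  node_new(v, parents = list(x), bw = function(g) list(g * v * (1 - v)))
}

nn_maxpool2 <- function(x) {
  x <- as_node(x)
  r <- maxpool2_fwd(x$v)
  if (!recording()) return(node_new(r$v))
  H <- dim(x$v)[1]; W <- dim(x$v)[2]
  node_new(r$v, parents = list(x), bw = function(g) list(maxpool2_bwd(g, r$idx, H, W)))
}

nn_up2 <- function(x) {
  x <- as_node(x)
  v <- up2_fwd(x$v)
  if (!recording()) return(node_new(v))
  H <- dim(x$v)[1]; W <- dim(x$v)[2]
  node_new(v, parents = list(x), bw = function(g) list(up2_bwd(g, H, W)))
}

nn_add <- function(x, y) {
  x <- as_node(x); y <- as_node(y)
  v <- x$v + y$v
  if (!recording()) return(node_new(v))
  node_new(v, parents = list(x, y), bw = function(g) list(g, g))
}

# Concatenate along the channel axis (3rd dim).
nn_concat <- function(xs) {
  xs <- lapply(xs, as_node)
  ds <- lapply(xs, function(x) dim(x$v))
  cs <- vapply(ds, `[`, 0, 3)
  d1 <- ds[[1]]
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    out[, , off + seq_len(cs[i]), ] <- xs[[i]]$v
    off <- off + cs[i]
  }
  if (!recording()) return(node_new(out))
  node_new(out, parents = xs, bw = function(g) {
    dim(g) <- dim(out)
    res <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- g[, , off + seq_len(cs[i]), , drop = FALSE]
      off <- off + cs[i]
    }
    res
  })
}

nn_slice_c <- function(x, idx) {
  x <- as_node(x)
  v <- x$v[, , idx, , drop = FALSE]
  if (!recording()) return(node_new(v))
  d <- dim(x$v)
  node_new(v, parents = list(x), bw = function(g) {
    dx <- array(0, dim = d)
    dx[, , idx, ] <- g
    list(dx)
  })
}

# Softmax over the local-offset axis of an attention logit tensor shaped
# (H, W, groups * k2, N) with the offset index fastest within each group.
nn_softmax_offsets <- function(x, k2, groups) {
  x <- as_node(x)
  stopifnot(dim(x$v)[3] == k2 * groups)
  y <- softmax_offsets_fwd(x$v, k2, groups)
  if (!recording()) return(node_new(y))
  node_new(y, parents = list(x), bw = function(g) {
    list(softmax_offsets_bwd(y, g, k2, groups))
  })
}

nn_local_attn <- function(a, v, k, groups) {
  a <- as_node(a); v <- as_node(v)
  out <- local_attn_fwd(a$v, v$v, k, groups)
  if (!recording()) return(node_new(out))
  av <- a$v; vv <- v$v
  node_new(out, parents = list(a, v), bw = function(g) {
    r <- local_attn_bwd(av, vv, g, k, groups)
    list(r$da, r$dv)
  })
}

# The enhancement activation F(x) = exp(-|x - 0.5|) - exp(-0.5), applied to a
# vessel probability map; differentiable (subgradient 0 at x = 0.5).
nn_enhance <- function(x) {
  x <- as_node(x)
  v <- exp(-abs(x$v - 0.5)) - exp(-0.5)
  if (!recording()) return(node_new(v))
  xv <- x$v
  node_new(v, parents = list(x), bw = function(g) {
    list(g * (-sign(xv - 0.5)) * exp(-abs(xv - 0.5)))
  })
}
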