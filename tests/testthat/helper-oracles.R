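# Independent oracles and small fixtures, written without reference to the
# package's compiled kernels: plain R loops only.

# nested-loop 2-d convolution on an (H, W, C, N) array; weights (k, k, Cg, Cout)
naive_conv_r <- function(x, w, b, pad, groups = 1L) {
  d <- dim(x); k <- dim(w)[1]; Cg <- dim(w)[3]; Cout <- dim(w)[4]
  Og <- Cout / groups
  out <- array(0, c(d[1], d[2], Cout, d[4]))
  for (n in seq_len(d[4])) for (o in seq_len(Cout)) {
    g <- ceiling(o / Og)
    for (hh in seq_len(d[1])) for (ww in seq_len(d[2])) {
      s <- b[o]
      for (ci in seq_len(Cg)) for (dy in seq_len(k)) for (dx in seq_len(k)) {
        sh <- hh + dy - 1 - pad; sw <- ww + dx - 1 - pad
        if (sh >= 1 && sh <= d[1] && sw >= 1 && sw <= d[2]) {
          s <- s + w[dy, dx, ci, o] * x[sh, sw, (g - 1) * Cg + ci, n]
        }
      }
      out[hh, ww, o, n] <- s
    }
  }
  out
}

# eval-mode batch norm with a fresh state (running mean 0, running var 1)
bn_eval_r <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  out <- x
  for (c in seq_len(d[3])) {
    out[, , c, ] <- (x[, , c, ] - 0) / sqrt(1 + eps) * gamma[c] + beta[c]
  }
  out
}

relu_r <- function(x) { x[x < 0] <- 0; x }

# conv + BN(eval, fresh) + ReLU using the layer's own weights, naive path
naive_cbr_r <- function(ly, x) {
  relu_r(bn_eval_r(naive_conv_r(x, ly$conv$w$v, ly$conv$b$v, ly$conv$pad,
                                ly$conv$groups),
                   ly$bn$gamma$v, ly$bn$beta$v, ly$bn$eps))
}

# small labeled synthetic sample used across tests
tiny_sample <- function(seed = 5, size = 128) {
  cfg <- synth_config(height = size, width = size, seed = seed)
  generate_sample(cfg)
}

# reduced model config for fast forward tests
tiny_msc_config <- function(...) {
  msc_config(base_width = 8, depth = 2, patch_size = 32, batch_size = 2,
             seed = 7, ...)
}

expect_max_abs <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
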