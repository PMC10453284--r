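# Oracle for one split-concat residual block, built purely from R loops over
# the block's own weights: 1x1 conv in, split into s subsets, cascade of
# small convs on concat(u_i, y_{i-1}), 1x1 conv out, projected shortcut.
res2net_oracle <- function(blk, x) {
  u <- naive_cbr_r(blk$conv_in, x)
  s <- blk$n_subsets
  cs <- dim(u)[3] / s
  ys <- vector("list", s)
  ys[[1]] <- u[, , seq_len(cs), , drop = FALSE]
  for (i in 2:s) {
    ui <- u[, , (i - 1) * cs + seq_len(cs), , drop = FALSE]
    cat_in <- array(c(ui, ys[[i - 1]]), c(dim(ui)[1:2], 2 * cs, dim(ui)[4]))
    ys[[i]] <- naive_cbr_r(blk$fi[[i - 1]], cat_in)
  }
  ally <- array(unlist(ys), c(dim(u)[1:2], s * cs, dim(u)[4]))
  out <- bn_eval_r(naive_conv_r(ally, blk$conv_out$conv$w$v,
                                blk$conv_out$conv$b$v, 0, 1),
                   blk$conv_out$bn$gamma$v, blk$conv_out$bn$beta$v)
  sh <- if (is.null(blk$shortcut)) x else {
    bn_eval_r(naive_conv_r(x, blk$shortcut$conv$w$v, blk$shortcut$conv$b$v, 0, 1),
              blk$shortcut$bn$gamma$v, blk$shortcut$bn$beta$v)
  }
  relu_r(out + sh)
}

test_that("the split-concat block matches an independent nested-loop oracle", {
  set.seed(101)
  for (case in list(list(cin = 8, cout = 8, s = 4, hw = 5),
                    list(cin = 3, cout = 8, s = 2, hw = 6),
                    list(cin = 8, cout = 8, s = 4, hw = 8))) {
    blk <- with_seed(case$cin * 100 + case$s,
                     mscnet:::res2net_block_new(case$cin, case$cout, case$s))
    x <- array(rnorm(case$hw^2 * case$cin), c(case$hw, case$hw, case$cin, 1))
    got <- mscnet:::res2net_block_fwd(blk, x, training = FALSE)$v
    want <- res2net_oracle(blk, x)
    expect_max_abs(got, want, 1e-5)
  }
})

test_that("a 64-channel block splits into four 16-channel subsets and keeps shape", {
  blk <- with_seed(1, mscnet:::res2net_block_new(64, 64, 4))
  expect_length(blk$fi, 3)
  expect_equal(dim(blk$fi[[1]]$conv$w$v), c(3, 3, 32, 16))  # 2*C/s -> C/s
  x <- array(rnorm(6 * 7 * 64), c(6, 7, 64, 1))
  out <- mscnet:::res2net_block_fwd(blk, x)$v
  expect_equal(dim(out), c(6, 7, 64, 1))
})

test_that("zero input with zero biases maps to zero", {
  blk <- with_seed(2, mscnet:::res2net_block_new(8, 8, 4))
  x <- array(0, c(4, 4, 8, 1))
  expect_true(all(mscnet:::res2net_block_fwd(blk, x)$v == 0))
})

test_that("the split path uses fewer parameters than one wide 3x3 conv", {
  for (C in c(16, 64)) {
    blk <- with_seed(3, mscnet:::res2net_block_new(C, C, 4))
    split_params <- count_params(blk$fi)
    single_conv_params <- 3 * 3 * C * C + C
    expect_lt(split_params, single_conv_params)
  }
})

test_that("the vessel network outputs probabilities of the input size", {
  cfg <- mve_config(base_width = 8, depth = 3)
  m <- with_seed(4, mscnet:::mve_new(cfg, in_channels = 1L))
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  t0 <- Sys.time()
  p <- mscnet:::mve_forward(m, x)$v
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
  expect_equal(dim(p), c(64, 64, 1, 1))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(is.finite(p)))
  expect_error(mscnet:::mve_forward(m, array(0, c(60, 60, 1, 1))), "divisible")
  expect_error(mve_config(base_width = 6, n_subsets = 4), "divisible")
})

test_that("the encoder is translation-covariant away from boundaries", {
  cfg <- mve_config(base_width = 8, depth = 2)
  m <- with_seed(6, mscnet:::mve_new(cfg, in_channels = 1L))
  set.seed(9)
  base <- array(runif(48 * 48), c(48, 48, 1, 1))
  stride <- 2^cfg$depth  # one full pooling stride
  shifted <- base
  shifted[] <- 0
  shifted[(stride + 1):48, , , ] <- base[1:(48 - stride), , , ]
  p0 <- mscnet:::mve_forward(m, base)$v
  p1 <- mscnet:::mve_forward(m, shifted)$v
  # interior crop, away from both the padding boundary and the shift edge
  core0 <- p0[9:32, 9:40, 1, 1]
  core1 <- p1[(9 + stride):(32 + stride), 9:40, 1, 1]
  expect_lt(mean(abs(core0 - core1)), 0.02)
})

test_that("every weight receives gradient from the vessel loss", {
  cfg <- mve_config(base_width = 8, depth = 2)
  m <- with_seed(8, mscnet:::mve_new(cfg, in_channels = 1L))
  params <- mscnet:::collect_params(m)
  set.seed(10)
  x <- array(runif(16 * 16), c(16, 16, 1, 2))
  y <- array((runif(16 * 16 * 2) > 0.7) * 1, c(16, 16, 1, 2))
  mscnet:::tape_start()
  p <- mscnet:::mve_forward(m, x, training = TRUE)
  loss <- mscnet:::nn_add(mscnet:::nn_bce(p, y),
                          mscnet:::nn_scale(mscnet:::nn_dice(p, y), 0.1))
  mscnet:::nn_backward(loss)
  mscnet:::tape_stop()
  zero_grad <- vapply(params, function(pp) is.null(pp$grad) || all(pp$grad == 0), TRUE)
  expect_false(any(zero_grad))
  mscnet:::zero_grads(params)
})
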