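test_that("binary cross-entropy matches hand arithmetic", {
  y <- c(1, 0)
  expect_lt(bce_loss(y, y), 1e-6)                      # perfect (clamped)
  expect_equal(bce_loss(0.5, 1), -log(0.5))            # single pixel: ln 2
  expect_equal(round(bce_loss(0.5, 1), 4), 0.6931)
  set.seed(70)
  p <- runif(20); yy <- rbinom(20, 1, 0.5)
  expect_equal(bce_loss(p, yy), bce_loss(1 - p, 1 - yy))   # symmetry
  expect_equal(bce_loss(p, yy, "sum"), bce_loss(p, yy) * 20)
  expect_error(bce_loss(p, yy[1:3]), "shape mismatch")
})

test_that("dice loss matches hand arithmetic and its conventions", {
  y <- c(1, 0, 1, 1, 0)
  expect_lt(dice_loss(y, y), 1e-6)
  expect_equal(dice_loss(numeric(4), numeric(4)), 0)   # empty/empty -> 0 via eps
  # y = [1, 0], p = [0.5, 0.5]: 1 - (2*0.5 + eps) / (1 + 1 + eps)
  expect_equal(dice_loss(c(0.5, 0.5), c(1, 0)),
               1 - (2 * 0.5 + 1e-6) / (2 + 1e-6))
  expect_equal(round(dice_loss(c(0.5, 0.5), c(1, 0)), 4), 0.5)
  set.seed(71)
  for (i in 1:10) {
    p <- runif(30); yy <- rbinom(30, 1, 0.3)
    d <- dice_loss(p, yy)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("A/V cross-entropy handles classes and uncertain masking", {
  av <- matrix(c(AV_BACKGROUND, AV_ARTERY, AV_VEIN, AV_UNCERTAIN), 2, 2)
  # near-one-hot logits with a large margin
  lg <- array(0, c(2, 2, 3))
  lg[1, 1, 1] <- 20; lg[2, 1, 2] <- 20; lg[1, 2, 3] <- 20
  expect_lt(av_ce_loss(lg, av), 1e-3)
  # uniform logits: ln(3) per evaluated pixel
  expect_equal(av_ce_loss(array(0, c(2, 2, 3)), av), log(3))
  expect_equal(round(av_ce_loss(array(1, c(2, 2, 3)), av), 4), 1.0986)
  # masking: changing scores only at uncertain pixels leaves the loss unchanged
  lg2 <- lg; lg2[2, 2, ] <- c(-9, 4, 2)
  expect_equal(av_ce_loss(lg2, av), av_ce_loss(lg, av))
  expect_error(av_ce_loss(lg, matrix(AV_UNCERTAIN, 2, 2)), "uncertain")
})

test_that("loss-term invariants hold exactly", {
  set.seed(72)
  vp <- matrix(runif(64), 8, 8)
  vg <- matrix(rbinom(64, 1, 0.4), 8, 8)
  lg <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  av <- matrix(sample(0:3, 64, TRUE), 8, 8)
  lt <- total_loss(vp, vg, lg, av)
  expect_identical(lt$epsilon, 1e-6)
  expect_identical(lt$l_v, lt$l_bce + 0.1 * lt$l_dice)
  expect_identical(lt$total, lt$l_v + lt$l_a)
  expect_identical(lt$l_bce, bce_loss(vp, vg))
  expect_identical(lt$l_a, av_ce_loss(lg, av))
  expect_gte(lt$l_dice, 0); expect_lte(lt$l_dice, 1)
  # perfect predictions: total below 1e-3
  one_hot <- array(-20, c(8, 8, 3))
  av2 <- matrix(sample(0:2, 64, TRUE), 8, 8)
  for (code in 0:2) one_hot[, , code + 1][av2 == code] <- 20
  perfect <- total_loss((av2 > 0) * 1, (av2 > 0) * 1, one_hot, av2)
  expect_lt(perfect$total, 1e-3)
})

test_that("loss gradients agree with finite differences", {
  set.seed(73)
  p <- array(runif(3), c(1, 3, 1, 1))
  y <- array(c(1, 0, 1), c(1, 3, 1, 1))
  lg <- array(rnorm(9), c(1, 3, 3, 1))
  av <- array(c(0L, 1L, 2L), c(1, 3, 1))
  fd <- function(f, x, i, eps = 1e-6) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }
  grads <- function(op, x, ...) {
    p <- mscnet:::nn_param(x)
    mscnet:::tape_start()
    l <- op(p, ...)
    mscnet:::nn_backward(l)
    mscnet:::tape_stop()
    p$grad
  }
  g_bce <- grads(mscnet:::nn_bce, p, y)
  g_dice <- grads(mscnet:::nn_dice, p, y)
  g_ce <- grads(mscnet:::nn_ce_av, lg, av)
  for (i in 1:3) {
    expect_lt(abs(g_bce[i] - fd(function(x) bce_loss(x, y), p, i)), 1e-4)
    expect_lt(abs(g_dice[i] - fd(function(x) dice_loss(x, y), p, i)), 1e-4)
  }
  for (i in seq_along(lg)) {
    expect_lt(abs(g_ce[i] - fd(function(x) av_ce_loss(x, av), lg, i)), 1e-4)
  }
})

test_that("confusion counts match constructed fixtures", {
  s <- tiny_sample(seed = 74, size = 96)
  cm <- confusion(s$vessel_mask, s, "vessel")
  expect_identical(cm$fp, 0L); expect_identical(cm$fn, 0L)
  expect_identical(cm$tp + cm$tn, as.integer(96 * 96))

  # A/V: gt = [A, A, V, V], pred = [A, V, V, A]
  gt <- matrix(c(AV_ARTERY, AV_ARTERY, AV_VEIN, AV_VEIN), 1)
  pr <- matrix(c(AV_ARTERY, AV_VEIN, AV_VEIN, AV_ARTERY), 1)
  cm2 <- confusion(pr, gt, "av")
  expect_identical(cm2[c("tp", "fn", "tn", "fp")],
                   list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))

  # vessel: a 20-pixel toy built to have tp=8 fp=2 fn=1 tn=9
  gt3 <- matrix(c(rep(1, 9), rep(0, 11)), 4, 5)
  pr3 <- matrix(c(rep(1, 8), 0, rep(0, 9), 1, 1), 4, 5)
  cm3 <- confusion(pr3, gt3, "vessel")
  expect_identical(cm3[c("tp", "fp", "fn", "tn")],
                   list(tp = 8L, fp = 2L, fn = 1L, tn = 9L))

  expect_error(confusion(pr, matrix(AV_BACKGROUND, 1, 4), "av"), "empty")
  expect_error(confusion(matrix(0.5, 2, 2), matrix(0, 2, 2), "vessel"), "binary")
})

test_that("metric formulas match their printed definitions", {
  m <- compute_metrics(list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  expect_equal(unlist(m), c(sen = 1, spe = 1, acc = 1, f1 = 1))
  m2 <- compute_metrics(list(tp = 8L, fp = 2L, fn = 1L, tn = 9L))
  expect_equal(round(m2$sen, 4), 0.8889)
  expect_equal(round(m2$spe, 4), 0.8182)
  expect_equal(m2$acc, 0.85)
  expect_equal(round(m2$f1, 4), 0.8421)
  # accuracy is invariant under swapping the positive/negative roles
  m3 <- compute_metrics(list(tp = 9L, fp = 1L, fn = 2L, tn = 8L))
  expect_equal(m3$acc, m2$acc)
  expect_false(isTRUE(all.equal(m3$sen, m2$sen)))
  expect_warning(compute_metrics(list(tp = 0L, fn = 0L, fp = 1L, tn = 1L)),
                 "sensitivity undefined")
})

test_that("metrics equal brute-force counting on random label maps", {
  set.seed(75)
  for (rep in 1:5) {
    gt <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
    pr <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
    cm <- confusion(pr, gt, "vessel")
    tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
    for (i in 1:32) for (j in 1:32) {
      if (pr[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1L
      if (pr[i, j] == 0 && gt[i, j] == 0) tn <- tn + 1L
      if (pr[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1L
      if (pr[i, j] == 0 && gt[i, j] == 1) fn <- fn + 1L
    }
    expect_identical(cm[c("tp", "tn", "fp", "fn")],
                     list(tp = tp, tn = tn, fp = fp, fn = fn))
    m <- compute_metrics(cm)
    expect_equal(m$sen, tp / (tp + fn))
    expect_equal(m$spe, tn / (tn + fp))
    expect_equal(m$acc, (tp + tn) / 1024)
    expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))

    gav <- matrix(sample(0:3, 1024, TRUE), 32, 32)
    pav <- matrix(sample(1:2, 1024, TRUE), 32, 32)
    cma <- confusion(pav, gav, "av")
    tp <- sum(pav == 1 & gav == 1); tn <- sum(pav == 2 & gav == 2)
    fp <- sum(pav == 1 & gav == 2); fn <- sum(pav == 2 & gav == 1)
    expect_identical(unlist(cma[c("tp", "tn", "fp", "fn")]),
                     c(tp = tp, tn = tn, fp = fp, fn = fn))
  }
})
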