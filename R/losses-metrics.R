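# Composite training objective and evaluation metrics.
#
# Vessel loss: L_v = L_bce + 0.1 * L_dice with Dice smoothing eps = 1e-6.
# A/V loss: multi-class cross-entropy over {background, artery, vein} with
# uncertain pixels excluded.  Total = L_v + L_a.  The printed formulas are
# per-pixel sums; the default reduction here is the per-pixel mean so the
# 0.1 weight on the bounded Dice term keeps its meaning across patch sizes
# (`reduction = "sum"` restores the literal sums).
#
# Metrics: Sen = TP/(TP+FN), Spe = TN/(TN+FP), Acc = (TP+TN)/total,
# F1 = 2TP/(2TP+FP+FN).  Vessel convention: positives are vessel pixels,
# evaluated everywhere.  A/V convention: positives are artery pixels,
# negatives vein pixels, evaluated only where the ground truth is artery or
# vein, with predictions restricted to an artery-vs-vein argmax.

DICE_EPS <- 1e-6
PROB_CLAMP <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, PROB_CLAMP), 1 - PROB_CLAMP)

check_same_shape <- function(p, y) {
  if (!identical(length(p), length(y))) {
    stop(sprintf("shape mismatch: prediction has %d values, target %d",
                 length(p), length(y)))
  }
}

#' Binary cross-entropy loss
#'
#' Probabilities are clamped to [1e-7, 1 - 1e-7] for log stability.
#' @param p probability array
#' @param y binary array of the same shape
#' @param reduction `"mean"` (default) or `"sum"` over pixels
#' @return nonnegative scalar
#' @export
bce_loss <- function(p, y, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  check_same_shape(p, y)
  pc <- clamp_prob(p)
  v <- -(y * log(pc) + (1 - y) * log(1 - pc))
  if (reduction == "mean") mean(v) else sum(v)
}

#' Dice loss
#'
#' `1 - (2 * sum(p*y) + eps) / (sum(p) + sum(y) + eps)` with eps = 1e-6;
#' always in [0, 1], and 0 for two empty maps by the eps convention.
#' @inheritParams bce_loss
#' @export
dice_loss <- function(p, y) {
  check_same_shape(p, y)
  1 - (2 * sum(p * y) + DICE_EPS) / (sum(p) + sum(y) + DICE_EPS)
}

softmax3 <- function(logits) {
  # softmax over the 3rd (class) axis of (H, W, C, N)
  d <- dim(logits)
  nc <- d[3]
  m <- logits[, , 1, , drop = FALSE]
  for (c in 2:nc) m <- pmax(m, logits[, , c, , drop = FALSE])
  e <- exp(logits - rep_class(m, nc))
  s <- e[, , 1, , drop = FALSE]
  for (c in 2:nc) s <- s + e[, , c, , drop = FALSE]
  e / rep_class(s, nc)
}

# replicate an (H, W, 1, N) slab across nc classes to match (H, W, nc, N)
rep_class <- function(m, nc) {
  d <- dim(m)
  out <- array(0, dim = c(d[1], d[2], nc, d[4]))
  for (c in seq_len(nc)) out[, , c, ] <- m
  out
}

as_hw1n <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d[1], d[2], d[3], 1L)
  x
}

#' Multi-class A/V cross-entropy loss
#'
#' Softmax over the class axis followed by the negative log-probability of
#' the true class, averaged (or summed) over pixels whose ground truth is
#' not uncertain.  Classes: background, artery, vein; uncertain pixels are
#' never a prediction target and are excluded.
#'
#' @param logits (H, W, 3) or (H, W, 3, N) array of unnormalized scores
#' @param av matching (H, W) / (H, W, N) array of label codes
#' @inheritParams bce_loss
#' @export
av_ce_loss <- function(logits, av, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  logits <- as_hw1n(logits)
  d <- dim(logits)
  av <- array(av, dim = c(d[1], d[2], d[4]))
  valid <- av != AV_UNCERTAIN
  if (!any(valid)) stop("A/V loss undefined: every pixel is labeled uncertain")
  p <- softmax3(logits)
  nll <- 0
  for (code in 0:(d[3] - 1L)) {
    sel <- valid & av == code
    if (!any(sel)) next
    pc <- p[, , code + 1L, , drop = FALSE]
    dim(pc) <- dim(av)
    nll <- nll - sum(log(pmax(pc[sel], PROB_CLAMP)))
  }
  if (reduction == "mean") nll / sum(valid) else nll
}

#' Composite loss terms
#'
#' `l_v = l_bce + 0.1 * l_dice` on the vessel head and `total = l_v + l_a`
#' with the A/V cross-entropy.
#'
#' @param vessel_prob vessel probability array
#' @param vessel_gt binary vessel mask of the same shape
#' @param final_logits A/V logits, (H, W, 3[, N])
#' @param av_gt A/V label codes
#' @inheritParams bce_loss
#' @return list with `l_bce`, `l_dice`, `l_v`, `l_a`, `total`, `epsilon`
#' @export
total_loss <- function(vessel_prob, vessel_gt, final_logits, av_gt,
                       reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  l_bce <- bce_loss(vessel_prob, vessel_gt, reduction)
  l_dice <- dice_loss(vessel_prob, vessel_gt)
  l_a <- av_ce_loss(final_logits, av_gt, reduction)
  l_v <- l_bce + 0.1 * l_dice
  list(l_bce = l_bce, l_dice = l_dice, l_v = l_v, l_a = l_a,
       total = l_v + l_a, epsilon = DICE_EPS)
}

#' Class predictions from A/V logits
#'
#' @param logits (H, W, 3) array
#' @param av_only if TRUE, argmax over the artery and vein channels only
#'   (the convention used for A/V evaluation); otherwise over all classes
#' @return H x W matrix of label codes
#' @export
av_argmax <- function(logits, av_only = FALSE) {
  d <- dim(logits)
  if (av_only) {
    out <- matrix(AV_ARTERY, d[1], d[2])
    out[logits[, , AV_VEIN + 1L] > logits[, , AV_ARTERY + 1L]] <- AV_VEIN
  } else {
    out <- matrix(AV_BACKGROUND, d[1], d[2])
    best <- logits[, , 1]
    for (code in 1:2) {
      b <- logits[, , code + 1L]
      sel <- b > best
      out[sel] <- code
      best[sel] <- b[sel]
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Confusion counts under a stated convention
#'
#' `convention = "vessel"`: positives are vessel pixels, `pred` is a binary
#' map and every pixel is evaluated.  `convention = "av"`: positives are
#' artery pixels and negatives vein pixels; evaluation is restricted to
#' pixels whose ground truth is artery or vein, and `pred` must contain only
#' artery/vein codes there (see [av_argmax()] with `av_only = TRUE`).
#'
#' @param pred predicted binary map (vessel) or label codes (av)
#' @param gt a [fundus_sample()] or a matching label array
#' @param convention `"vessel"` or `"av"`
#' @return list of integer `tp`, `tn`, `fp`, `fn` plus the convention
#' @export
confusion <- function(pred, gt, convention = c("vessel", "av")) {
  convention <- match.arg(convention)
  if (inherits(gt, "fundus_sample")) {
    gt <- if (convention == "vessel") gt$vessel_mask else gt$av_labels
  }
  if (!identical(dim(pred)[1:2], dim(gt)[1:2])) {
    stop("prediction and ground truth are not pixel-aligned")
  }
  if (convention == "vessel") {
    if (!all(pred %in% c(0, 1))) stop("vessel prediction must be binary (threshold first)")
    tp <- sum(pred == 1 & gt == 1)
    tn <- sum(pred == 0 & gt == 0)
    fp <- sum(pred == 1 & gt == 0)
    fn <- sum(pred == 0 & gt == 1)
  } else {
    eval_mask <- gt == AV_ARTERY | gt == AV_VEIN
    if (!any(eval_mask)) stop("empty A/V evaluation mask: no artery/vein ground truth")
    pe <- pred[eval_mask]
    ge <- gt[eval_mask]
    if (!all(pe %in% c(AV_ARTERY, AV_VEIN))) {
      stop("A/V predictions at evaluated pixels must be artery or vein; ",
           "use av_argmax(logits, av_only = TRUE)")
    }
    tp <- sum(pe == AV_ARTERY & ge == AV_ARTERY)
    tn <- sum(pe == AV_VEIN & ge == AV_VEIN)
    fp <- sum(pe == AV_ARTERY & ge == AV_VEIN)
    fn <- sum(pe == AV_VEIN & ge == AV_ARTERY)
  }
  list(tp = as.integer(tp), tn = as.integer(tn), fp = as.integer(fp),
       fn = as.integer(fn), convention = convention)
}

#' Sensitivity, specificity, accuracy and F1 from confusion counts
#'
#' Undefined metrics (zero denominator) are returned as NaN with a warning.
#' @param counts list with `tp`, `tn`, `fp`, `fn` (see [confusion()]);
#'   multiple counts may be pooled first with [pool_counts()]
#' @return list with `sen`, `spe`, `acc`, `f1`
#' @export
compute_metrics <- function(counts) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting NaN")
      return(NaN)
    }
    num / den
  }
  with(counts, list(
    sen = safe_div(tp, tp + fn, "sensitivity"),
    spe = safe_div(tn, tn + fp, "specificity"),
    acc = safe_div(tp + tn, tp + tn + fp + fn, "accuracy"),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn, "F1")
  ))
}

#' Pool confusion counts across samples
#' @param counts_list list of count lists from [confusion()]
#' @return a single pooled count list
#' @export
pool_counts <- function(counts_list) {
  out <- list(tp = 0L, tn = 0L, fp = 0L, fn = 0L,
              convention = counts_list[[1]]$convention)
  for (cl in counts_list) {
    stopifnot(identical(cl$convention, out$convention))
    out$tp <- out$tp + cl$tp; out$tn <- out$tn + cl$tn
    out$fp <- out$fp + cl$fp; out$fn <- out$fn + cl$fn
  }
  out
}

# ---- differentiable node versions used by the training loop ----

nn_bce <- function(p, y, reduction = "mean") {
  p <- as_node(p)
  pc <- clamp_prob(p$v)
  n <- if (reduction == "mean") length(pc) else 1
  v <- sum(-(y * log(pc) + (1 - y) * log(1 - pc))) / n
  if (!recording()) return(node_new(v))
  inb <- p$v > PROB_CLAMP & p$v < 1 - PROB_CLAMP
  node_new(v, parents = list(p), bw = function(g) {
    list(g * inb * (pc - y) / (pc * (1 - pc)) / n)
  })
}

nn_dice <- function(p, y) {
  p <- as_node(p)
  spy <- sum(p$v * y); sp <- sum(p$v); sy <- sum(y)
  den <- sp + sy + DICE_EPS
  v <- 1 - (2 * spy + DICE_EPS) / den
  if (!recording()) return(node_new(v))
  node_new(v, parents = list(p), bw = function(g) {
    list(g * (-(2 * y * den - (2 * spy + DICE_EPS)) / den^2))
  })
}

nn_ce_av <- function(logits, av, reduction = "mean") {
  logits <- as_node(logits)
  d <- dim(logits$v)
  av <- array(av, dim = c(d[1], d[2], d[4]))
  valid <- av != AV_UNCERTAIN
  if (!any(valid)) stop("A/V loss undefined: every pixel is labeled uncertain")
  p <- softmax3(logits$v)
  onehot <- array(0, dim = d)
  for (code in 0:(d[3] - 1L)) onehot[, , code + 1L, ] <- (av == code) * valid
  n <- if (reduction == "mean") sum(valid) else 1
  v <- -sum(onehot * log(pmax(p, PROB_CLAMP))) / n
  if (!recording()) return(node_new(v))
  vmask <- rep_class(array(valid * 1, dim = c(d[1], d[2], 1L, d[4])), d[3])
  node_new(v, parents = list(logits), bw = function(g) {
    # at valid pixels: softmax - onehot; zero elsewhere
    list(g * (p * vmask - onehot) / n)
  })
}

nn_scale <- function(x, a) {
  x <- as_node(x)
  v <- a * x$v
  if (!recording()) return(node_new(v))
  node_new(v, parents = list(x), bw = function(g) list(a * g))
}
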