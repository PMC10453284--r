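# Multi-source Feature Integration: the vessel probability map is passed
# through an enhancement activation that peaks where the segmentation is
# uncertain (vessel boundaries and micro-vessels, p near 0.5) and vanishes
# for confident background and thick-vessel pixels; the enhanced map is then
# fused with the A/V logits and penultimate features by a light refinement
# head that is an exact identity at initialization.

#' Enhancement activation for vessel probability maps
#'
#' Elementwise `F(x) = exp(-|x - 0.5|) - exp(-0.5)` applied to a vessel
#' probability map.  `F(0) = F(1) = 0` and the maximum `F(0.5) = 1 -
#' exp(-0.5)` (about 0.3935), so confidently classified pixels are
#' suppressed while boundary and micro-vessel pixels are emphasised.
#'
#' @param p numeric array of probabilities; values outside [0, 1] by more
#'   than 1e-6 are an error (the activation must see probabilities, not
#'   logits)
#' @return array of the same shape with values in [0, 1 - exp(-0.5)]
#' @export
vessel_enhance <- function(p) {
  rng <- range(p)
  if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6) {
    stop(sprintf(paste0("vessel_enhance() expects probabilities in [0, 1]; got ",
                        "values in [%.4g, %.4g] (did you pass logits?)"),
                 rng[1], rng[2]))
  }
  exp(-abs(p - 0.5)) - exp(-0.5)
}

mfi_new <- function(feat_channels, n_classes = 3L, hidden = 16L) {
  cin <- n_classes + feat_channels + 1L
  list(
    conv1 = cbr_layer(3L, cin, hidden),
    conv2 = conv_layer(3L, hidden, hidden),
    # zero-initialized head: the fused output equals the A/V logits exactly
    # at initialization, so fusion can only refine from there
    conv3 = conv_layer(1L, hidden, n_classes, zero_init = TRUE)
  )
}

#' Fusion head forward pass
#'
#' Concatenates A/V logits, penultimate A/V features and the enhanced vessel
#' map, applies two 3x3 convolutions (BN + ReLU after the first) and a
#' zero-initialized 1x1 convolution, and adds the result to the incoming
#' logits (residual identity).
#'
#' @param blk the `mfi` component of an [msc_new()] model
#' @param av_logits (H, W, n_classes, N) node
#' @param av_features (H, W, C_feat, N) node
#' @param enhanced (H, W, 1, N) node from the enhancement activation
#' @param training batch-norm mode
#' @return refined logits node, same shape as `av_logits`
#' @keywords internal
mfi_fwd <- function(blk, av_logits, av_features, enhanced, training = FALSE) {
  d1 <- dim(as_node(av_logits)$v)[1:2]
  d2 <- dim(as_node(enhanced)$v)[1:2]
  if (!identical(d1, d2)) {
    stop(sprintf("fusion inputs are misaligned: logits %dx%d vs enhanced %dx%d",
                 d1[1], d1[2], d2[1], d2[2]))
  }
  h <- cbr_apply(blk$conv1, nn_concat(list(av_logits, av_features, enhanced)), training)
  h <- conv_apply(blk$conv2, h)
  nn_add(conv_apply(blk$conv3, h), av_logits)
}
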