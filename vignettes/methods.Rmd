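---
title: "Methods: multi-task vessel segmentation and artery/vein classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task vessel segmentation and artery/vein classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model implemented by `mscnet`, its assumptions,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the architecture left
genuine freedom.

## The task and the three-stage decomposition

Given an RGB fundus photograph, the goal is a per-pixel decision among
*background*, *artery* and *vein* (a fourth ground-truth category,
*uncertain*, marks pixels human graders would not commit to — typically
artery-vein crossings — and is never a prediction target). The pipeline
decomposes this into:

1. **Vessel extraction (MVE)** — a binary segmentation U-Net whose encoder
   stages are split-concat residual blocks. Each block applies a 1×1
   convolution, splits the result into `n_subsets` channel groups, and
   chains them: subset $i$ is concatenated with the output of the previous
   small 3×3 convolution before its own, so the last subset has passed
   through $s-1$ stacked convolutions. The cascade widens the receptive
   field without wide kernels, which matters for thin, elongated vessels.
   The head is a 1×1 convolution plus sigmoid: a vessel probability map.

2. **A/V extraction (MAE)** — the same U-shaped scaffold on the 4-channel
   concatenation of the raw RGB image and the vessel probability. Every
   encoder stage ends in a contextual-attention block: features $X$ act as
   both queries and keys; a grouped convolution over $K$ produces a static
   context $K_s$; two 1×1 convolutions on $[K_s; Q]$ (first ReLU-activated,
   second linear) produce, per pixel and channel group, softmax weights
   over the $k_a \times k_a$ local offsets; these aggregate the value map
   $V$ into a dynamic context $D$; the block returns $K_s + D$. Replacing
   the query-key matrix product with concatenation keeps the cost linear in
   pixel count.

3. **Fusion (MFI)** — the vessel probability is transformed by
   $F(x) = e^{-|x-0.5|} - e^{-0.5}$, which suppresses confident pixels and
   peaks (at $1 - e^{-0.5}$) exactly where the segmentation hesitates:
   vessel boundaries and micro-vessels. A small head (3×3 conv + BN + ReLU,
   3×3 conv, zero-initialized 1×1 conv) refines the A/V logits residually;
   at initialization fusion is an exact identity, so it can only move away
   from the A/V network's answer as far as training warrants. The final
   vessel output is the MVE map passed through unchanged — no second vessel
   supervision exists in the objective.

Both losses backpropagate jointly from the first step; there is no
stage-wise pre-training.

## Objective and evaluation conventions

$\mathrm{Loss} = L_v + L_a$ with $L_v = L_{bce} + 0.1\,L_{dice}$,
$\varepsilon = 10^{-6}$ in the Dice term, and $L_a$ a 3-class
cross-entropy with uncertain pixels excluded. The printed formulas are
per-pixel *sums*; this implementation defaults to per-pixel *means* so that
the 0.1 weight on the bounded Dice term keeps a stable meaning across patch
sizes — `reduction = "sum"` restores the literal sums. Probabilities are
clamped to $[10^{-7}, 1-10^{-7}]$ inside the logs.

Metrics are Sen, Spe, Acc and F1 from pooled confusion counts. For vessels,
positives are vessel pixels and every pixel is evaluated (no field-of-view
restriction: none is specified for the reference results, so none is
applied). For A/V, positives are artery and negatives vein pixels;
evaluation is restricted to pixels whose *ground truth* is artery or vein,
and the prediction there is the argmax over the artery/vein channels only —
the dominant convention in this literature. Alternative masks (e.g.
predicted-vessel) would change the numbers and are deliberately not
offered as defaults.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `base_width` | 64 | channels | stated width of the first stage; 8 for desk-scale runs |
| `depth` | 4 | poolings | standard U-Net depth; 3 at desk scale |
| `n_subsets` | 4 | — | stated split count of the residual block |
| `cot_groups` | 4 | — | channel groups sharing attention weights (reference design) |
| `cot_key_kernel`, `cot_attn_kernel` | 3, 3 | px | static-context kernel and local attention neighborhood |
| `lr` | 0.001 | — | stated Adam learning rate |
| `epochs` | 100 | — | stated training length ("iterations" read as epochs) |
| `patch_size` | 256 | px | stated training crop; must divide by `2^depth` |
| `batch_size` | 4 | patches | unstated; desk-friendly choice |
| `clahe_clip`, `clahe_grid` | 2.0, 8×8 | — | unstated; the library defaults widely used on fundus images |
| `noise_sd_max` | 0.02 | normalized intensity | unstated; small relative to vessel/background contrast |

## Preprocessing

The vessel branch consumes the CLAHE-equalized green channel (the green
channel carries the most vessel contrast in fundus photography); the A/V
branch consumes the raw RGB image, since color is the primary artery/vein
cue. CLAHE is reimplemented in R (tile histograms, clip limit as a multiple
of the uniform bin height, excess redistributed uniformly, per-tile CDFs
bilinearly interpolated between tile centers) because no offline image
library provides it here.

Augmentation rotates image and labels jointly by a random right angle and
adds Gaussian noise to the image only. Right angles, rather than arbitrary
ones, keep categorical labels exact without interpolation — "random
rotation" is otherwise unconstrained. Tiling is non-overlapping with
bottom/right zero padding ("in order" reads as a simple raster);
`stitch(tile(x))` is exactly `x`.

## The synthetic generator: what a green test establishes

`generate_sample()` draws binary-branching vessel trees as hard
(non-anti-aliased) thickened polylines with per-level caliber taper, half
arteries (brighter, more orange) and half veins (darker), on a mid-gray
Gaussian-textured background inside a circular field of view with black
corners. Artery-vein overlaps are labeled *uncertain*, mirroring crossing
ambiguity; one crossing is forced whenever at least two trees are drawn.
Ground truth is exact by construction.

What it emulates: branching geometry with tapering calibers, distinct A/V
color statistics, crossings, FOV edges, label noise-free masks. What it
does **not** emulate: lesions and pathology, the optic disc and macula,
central light reflex on arteries, caliber-dependent color variation, JPEG
artifacts, or inter-grader label noise. A passing parameter-recovery test
therefore establishes that the pipeline can learn geometry + color-based
A/V separation end to end — not that it reaches any particular accuracy on
clinical images.

Setting `artery_color_mean = vein_color_mean` removes the color cue
entirely; this is used in the tests to verify that evaluation code cannot
leak labels.

## Numerical choices

* **Initialization** He-normal for convolutions; the fusion head's last
  1×1 conv is zero-initialized (exact identity at start). Batch norm
  starts at $\gamma = 1, \beta = 0$ with running stats $(0, 1)$ and
  momentum 0.1; inference always uses running statistics.
* **Down/up-sampling** 2×2 max pooling; bilinear ×2 upsampling
  (`align_corners = FALSE`) followed by a 1×1 convolution — standard U-Net
  choices where the architecture is silent.
* **Attention ties** softmax is computed with max-subtraction; exact ties
  in max pooling resolve to the first (top-left) maximum.
* **Degenerate inputs** empty Dice ($\Sigma y = \Sigma p = 0$) is 0 by the
  $\varepsilon$ convention; all-uncertain A/V targets are an error rather
  than a silent 0; metrics with empty denominators return NaN with a
  warning.
* **Tiling boundary effects** the receptive field at depth 3 exceeds a
  64-px tile, so zero padding at tile seams perturbs raw logits everywhere
  in a tile; tiled and whole-image passes agree closely on the bounded
  probability outputs (mean absolute difference on the order of $10^{-3}$
  for a trained network, checked in the tests at 16 px from seams) but not
  to arbitrary precision on the scale-free logits. Overlap-and-average
  tiling would reduce this further and is intentionally out of scope.

## Design decisions where the architecture was open

* The split-concat recurrence is implemented as $F_i([u_i; y_{i-1}])$
  (subset $i$ with the previous output), matching the Res2Net convention
  and the prose description of the block, over a variant reading in which
  every $F_i$ sees the first subset.
* Decoder stages are plain double-conv blocks; the multi-scale residual
  blocks appear in the encoder only. Attention blocks likewise sit in the
  encoder stages (and bottleneck) only.
* The attention map has $k_a^2 = 9$ local offsets shared across 4 channel
  groups, following the contextual-transformer design the block derives
  from; a global $HW \times HW$ product would reintroduce the quadratic
  cost the design avoids.
* The fusion operator is the least constrained part of the architecture
  ("employed to operate" the A/V results). Concatenation + residual conv
  refinement was chosen because it is identity-at-init (cannot hurt the
  A/V logits at start) and lets the enhanced boundary/micro-vessel signal
  modulate the final decision, which is the module's stated purpose.
* Only the final (fused) logits are supervised by $L_a$; ablations with the
  fusion module disabled supervise the A/V network's own logits, which the
  module-toggle design requires anyway. `aux_mae_supervision = TRUE`
  enables auxiliary supervision of the pre-fusion logits.
* The enhancement activation is applied to the sigmoid *probability* map,
  which is the stated domain of $F$ and gives the advertised values
  $F(0) = F(1) = 0$, $F(0.5) = 1 - e^{-0.5}$.
* "100 iterations" is read as 100 epochs; the desk-scale tests use an
  explicit step budget instead.
* Validation split for checkpoint selection: 20% of the training manifest,
  seeded (unstated in the reference setup).

## Known limitations

* CPU-only: full-scale training (base width 64, 256-px patches, external
  datasets) is out of reach of this implementation's intended use; its
  tests and acceptance runs use the reduced configuration.
* No overlap-averaged tiling, deep supervision, CRF post-processing, or
  centerline-based evaluation.
* Only PNG/JPEG I/O is available offline; TIFF/GIF sources must be
  converted first.
* The synthetic world is a testing instrument, not a clinical surrogate;
  see above for what a green test does and does not establish.
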