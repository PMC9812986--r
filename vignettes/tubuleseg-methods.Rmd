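---
title: "Methods: patch-based tubule segmentation with tubuleseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based tubule segmentation with tubuleseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tubule formation is one of the three components of Nottingham histological
grading of breast carcinoma. A tubule appears in an H&E section as a clear
central lumen surrounded by a ring of epithelial nuclei; other lumen-bearing
structures — blood vessels wrapped in a thin endothelial layer, adipocytes
with their signet-ring membrane — are the classic false-positive confusers.
Whole-slide images are far too large for a segmentation network, so the
practical unit of work is the patch (here 900×900 pixels at a 20×-like
appearance), and the practical difficulties are (a) tubules truncated at
patch borders, which deprive the network of the closed lumen-plus-ring
evidence it needs, and (b) recombining per-patch predictions into a
seamless whole-image mask.

`tubuleseg` implements a complete patch-based framework around these two
difficulties: patch-enhancement padding, overlap tiling with stitching,
symmetric and asymmetric U-Net segmentation models on a compact CPU engine,
a training loop with the standard recipe, pixel-level evaluation, and a
seeded synthetic phantom generator that stands in for clinical data in all
tests and demonstrations.

## Patch-enhancement padding

Two operators enlarge a training patch so that border-truncated structures
gain mirrored context:

* **Reflection padding** tiles a 2×2 canvas with the patch and its flips —
  original top-left, left-right flip top-right, top-bottom flip bottom-left,
  double flip bottom-right — doubling the side (900 → 1800). Every internal
  seam mirrors, so the canvas contains no artificial edge, and each
  truncated tubule is completed across a seam. The quadrant layout (original
  in a corner rather than centred) is a declared convention; the doubled
  side forces a 2×2 grid either way.
* **Mirror padding** reflects a `margin`-wide band (default 100 px) outward
  across each edge (900 → 1100), corners by double reflection. We reflect
  *without* repeating the edge pixel; either convention meets the printed
  sizes, so this is a declared dialect.

Both transform the ground-truth mask identically and record a `core_box`, so
`crop_core()` inverts them bit-exactly — the padded-domain prediction maps
cleanly back onto the original patch. Padded canvases are downsampled to the
network input size (default 512) with bilinear interpolation; masks always
resample nearest-neighbour so labels stay in {0, 1}.

The training loss is computed on the full padded canvas by default; a
`loss_on_core` switch restricts it to the core region (the choice is not
dictated by the method, so both are available).

## Overlap tiling and stitching

A large image is covered by a grid of `core`-sized cells (default 900);
each tile extends `overlap_fraction × core` pixels (default 25%, i.e. 225)
into its neighbours per side, so tiles are 1350 px and every core pixel is
classified with surrounding context. We read "25% overlap" as a per-side
context band because 900 × 1.5 = 1350 matches the stated tile size; a
stride-based reading does not. The parent is extended by reflection so
border tiles are full size. Stitching is `core_crop` by default — each tile
contributes exactly its core cell, so the cores partition the parent and
`stitch(extract(x)) == x` holds bit-exactly at any overlap — with per-pixel
`mean` blending available by flag. The per-tile inference order is
extract 1350 → resize 512 → predict → resize back → stitch, mirroring the
training-time downsample.

## Segmentation models

All networks share the U-Net shape: five encoder stages at strides
2, 4, 8, 16, 32; a decoder that at each stage upsamples by a 2×2 transposed
convolution, concatenates stride-matched encoder features through a skip
connection and applies two 3×3 convolution+ReLU layers; and a 1×1
convolution with sigmoid producing the per-pixel tubule probability.
The `basic` backbone is the classic symmetric encoder (two 3×3
convolutions + ReLU + max-pool per stage). The asymmetric variants replace
it with classification-style hierarchies: residual blocks (`resnet34`),
dense bottleneck blocks with growth 48 (`densenet161`), and
inverted-bottleneck blocks with expansion 3 (`efficientnetb3`). These are
structurally analogous, randomly initialised encoders built on the package's
own engine — no pretrained weights are distributed, and `pretrained = TRUE`
errors rather than silently downloading anything. Skip connections tap the
last feature map at each stride; the stride-1 skip comes from a pre-pool
stem block. Decoder widths are fixed at (256, 128, 64, 32, 16) for the
full-size backbones; stage widths were chosen so parameter counts order
basic < resnet34 < efficientnetb3 < densenet161 within this registry.
`tiny` (five thin stages, ≈0.13M parameters, scaled decoder) exists for
CPU-scale experiments and tests.

The engine itself is a small static graph of primitives (stride-1 'same'
3×3/1×1 convolution via im2col, 2×2 max-pool, 2×2 stride-2 transposed
convolution, ReLU, concatenation, addition, sigmoid) with reverse-mode
backpropagation, implemented in RcppArmadillo and verified against finite
differences in the test suite.

## Training

`fit()` minimises mean per-pixel binary cross entropy with Adam
(β₁ = 0.9, β₂ = 0.999). Defaults follow the standard recipe: 50 epochs,
initial learning rate 1e-4, batch size 16, a single ×0.1 learning-rate step
after epoch 30, and early stopping when the validation loss has not
improved by more than `loss_tolerance` (1e-4) for `patience` (15)
consecutive epochs. "Loss remains constant" is interpreted on the
*validation* loss with that tolerance, and the returned weights are those
of the best validation epoch — both choices the method leaves open.
Gradients are evaluated at the logit head in the numerically stable
"BCE-with-logits" form; differentiating through a clamped sigmoid output
can silently stall a run that saturates to the all-background prediction
early (vanishing-gradient plateau), which we observed and eliminated this
way. The loss value itself is unchanged.

Twelve augmentations are registered, matching the conventional menu:
shift-scale-rotate, elastic transform, grid distortion, optical distortion
(geometric: image and mask warped identically, mask nearest-neighbour),
random gamma, random brightness, RGB shift, hue-saturation-value, color
jitter, defocus blur, motion blur, Gaussian blur (image only). Parameter
ranges follow the augmentation ecosystem's common defaults (rotation ±45°,
scale ±10%, shift ±6.25%, gamma 0.8–1.25, …) and every transform accepts
overrides.

## Evaluation

With A the predicted and B the true tubule pixel sets,
DSC = 2|A∩B|/(|A|+|B|) = 2TP/(2TP+FP+FN);
recall = 100·TP/(TP+FN); specificity = 100·TN/(FP+TN); FPR is reported as
exactly 100 − specificity (published tables sometimes round the two
independently; we do not). Conventions the formulas leave open: empty
prediction vs empty truth scores DSC 1 (correctly predicting nothing is
not an error); recall/specificity are `NA` when their denominator is zero;
probability maps binarize at threshold 0.5 with the ≥ convention.
Aggregation is `micro` (pooled pixel counts) within an image and `macro`
(unweighted mean) across images — the only reading consistent with
averaging scores over several whole-slide images. The overlay renderer
tints true positives green, false negatives blue and false positives red
(alpha 0.5, configurable) over the source image.

## The phantom generator

Clinical datasets of annotated tubules are not redistributable, so the
package generates its own study material. A phantom patch is a pink
stromal background on which each tubule is drawn as a random rotated
ellipse: a pale lumen of semi-major axis 30–80 px (at 900 px scale) ringed
by an annulus of dark nucleus-coloured discs 12–22 px thick. The
ground-truth mask is the filled outer ellipse (lumen ∪ ring), recorded
per instance so component-count and footprint oracles are exact even when
instances overlap. A configurable fraction of tubules (`incomplete_fraction`)
is centred within one lumen radius of a patch edge — close enough that the
footprint always crosses it — emulating border-truncated tubules.
Vessel-like distractors (thin dark ring, ≤2 px wall) and adipocyte-like
distractors (white blob, faint membrane) appear in the image but never in
the mask, so false-positive behaviour is measurable. Colours are flat
fills plus Gaussian channel noise (σ = 4/255 per channel); 20% of patches
are empty by default (the class balance is not prescribed anywhere, so it
is a configurable default). Identical parameters and seed give
bit-identical patches; datasets derive disjoint per-patch seed streams
from one master seed.

What the phantom does *not* emulate: stain physics and colour variation
between laboratories, cribriform/multi-lumen architecture, sectioning and
fixation artifacts, nuclear pleomorphism, or the long-tailed size
distribution of real glands. Passing tests on phantoms therefore
demonstrate that the pipeline's mechanics (padding, tiling, learning,
evaluation) are correct and that the models can learn lumen-plus-ring
morphology against confusers — not clinical-grade accuracy.

## Desk-scale benchmark protocols

Two experiment protocols are exported so tests and the acceptance script
share one definition:

* `learning_benchmark()` — the `tiny` backbone trained on 64 phantom
  patches of 128 px (geometry scaled by 128/900 from the full-size
  defaults) with 16 held-out patches, at most 15 epochs. The optimiser
  recipe is learning rate 2e-3 with batch size 4: at this data scale the
  default 1e-4/16 recipe (tuned for thousands of patches over 50 epochs)
  leaves far too few optimisation steps inside the epoch cap. Held-out
  DSC is reported pooled (micro) per the package's within-image
  convention. Typical pooled DSC across master seeds: 0.85–0.98.
* `padding_effect_benchmark()` — matched reflection-padding vs no-padding
  training runs on phantoms with `incomplete_fraction = 0.8`, three master
  seeds, equal budget (24 training patches, 12 epochs), each arm evaluated
  with its own padding mode. Tubule geometry here is scaled by 256/900 on
  128-px patches — coarser than the learning benchmark — because the
  reflection arm downsamples its doubled canvas two-fold, and with finer
  geometry the nuclear rings drop below one pixel and the comparison
  measures resolution loss instead of boundary completion. The expected
  outcome is a non-negative mean DSC difference in favour of reflection;
  at this scale the effect is a weak trend, not a fixed margin.

Problem sizes in both protocols (and in the test suite: metric oracle on
16×16 masks, stitch round-trips up to 2700², schedule contracts on 32-px
patches) were chosen so every check runs in minutes on one CPU.

## Known limitations

* The CPU engine has no batch normalisation, depthwise convolution or
  squeeze-excitation; the asymmetric encoders are structural analogues of
  their namesakes, suitable for comparing the framework's moving parts,
  not for transferring published weights.
* Full-size backbones at 512-px input are buildable and correct but slow
  on CPU; the intended full-scale use is via small inputs or the `tiny`
  backbone unless substantial compute is available.
* Whole-slide container formats are out of scope; images enter as PNG or
  TIFF.
* The directional padding-effect benchmark is a trend assertion on a
  stochastic quantity; individual seed pairs can go either way.
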