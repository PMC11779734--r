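---
title: "Methods: seedling segmentation and length measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seedling segmentation and length measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Germination assays score seed viability by the lengths of the embryonic
shoot (hypocotyl) and root (radicle) a few days after imbibition. Scoring by
ruler is slow and subjective. This package automates the measurement from
photographs of germination boards: a semantic segmentation network labels
every pixel as background, shoot, root or seed, and a geometric pipeline
converts the class masks into per-seedling lengths in millimetres using a
coin of known diameter as the in-frame scale reference.

## The segmentation model

The network (DFMA) is a DeepLabv3+-style encoder–decoder assembled from
four components.

**Backbone (partial convolutions).** A FasterNet-style feature extractor: a
4×4 stride-4 patch embedding followed by four stages of residual blocks
separated by 2×2 stride-2 merging convolutions, so the stages run at strides
4, 8, 16 and 32. Each block is
`x + PWConv2(ReLU(BN(PWConv1(PConv(x)))))`, where the partial convolution
(PConv) applies an ordinary 3×3 convolution to only the first `c_p` of `c`
channels and passes the rest through untouched. A PConv costs
`h·w·k²·c_p²` multiply-accumulates against `h·w·k²·c²` for the full
convolution — a `(c_p/c)²` reduction; the two pointwise convolutions still
mix all channels. Defaults: stage depths (1, 2, 8, 2), widths
(40, 80, 160, 320), `c_p/c = 1/4`, convolving the *first* `c_p` contiguous
channels. The published description names the embedding/merging layers and
the block structure but not the exact variant; depths, widths and the
partial ratio are therefore configuration knobs with these defaults.
Normalization is batch normalization and the activation is ReLU. The
stage-1 (stride-4) map is retained as the decoder's low-level feature.

**EMA attention.** Before the pyramid, the stride-32 map passes through
Efficient Multi-scale Attention. Channels fold into `g` groups (default 8)
treated as extra batch entries; per group, two directional global-average
poolings (along height and along width) feed a shared 1×1 convolution whose
split outputs gate the features per direction, followed by group
normalization; a parallel 3×3 convolution provides a second descriptor;
softmax-pooled descriptors of each route weight the pixels of the other,
and a sigmoid fuses the two maps into one per-pixel weight in (0, 1) that
multiplies the group. The wiring diagram in the source description is
partial, so the implementation follows the published EMA design it cites.
Where the attention sits is config-gated: on the backbone output before the
pyramid by default (`ema_pre_aspp`), optionally after fusion
(`ema_post_aspp`, off by default).

**PSPA-ASPP pyramid.** Four parallel branches over the stride-32 map:
(A) a 3×3 partial convolution followed by a 1×1 projection to 256 channels
(the PConv replaces the classical 1×1 first branch; since a PConv preserves
its channel count, the projection supplies the branch width — the source
gives widths only for the dilated branches); (B) two 3×3 dilated
convolutions at rates 2 and 3, 128 kernels each, concatenated;
(C) the same at rates 5 and 7; (D) global average pooling, a 1×1
convolution, and nearest-neighbour broadcast back to the grid. The four
outputs concatenate and a 1×1 convolution fuses them to 256 channels; every
convolution is followed by BN + ReLU. Rates within a pair are required to
be coprime: stacked dilated convolutions whose rates share a divisor leave
periodic sampling gaps (the gridding effect), and `grid_coverage()`
quantifies this by brute-force influence propagation — a stack at rates
(2, 2, 2) reaches only 49/169 of its receptive field, while (2, 3) reaches
(9/11)². Whether the two rate pairs run in parallel or chained is not
stated in the text; the default is parallel (consistent with every textual
statement), and `aspp.serial = TRUE` chains pair (5, 7) onto pair (2, 3)'s
output for comparison.

**CARAFE upsampling.** Content-aware reassembly replaces bilinear
upsampling at two places: an 8× stage after the pyramid
(256×16×16 → 256×128×128 for a 512×512 input) and the final 4× stage before
the classifier. A 1×1 compressor (to `c_m = 64` channels) and a
`k_encoder × k_encoder` content encoder predict `σ²·k_up²` channels that
pixel-shuffle into one `k_up × k_up` kernel per output position; a softmax
over each kernel makes every output a convex combination of the
`k_up × k_up` source neighbourhood around `floor(output/σ)`, all channels
sharing the kernel. `k_up = 5`, `k_encoder = 3` and `c_m = 64` are the
canonical choices; the source does not state them, nor the normalizer
(softmax guarantees the convex-combination invariant), nor whether the
final 4× stage is CARAFE or bilinear — the default is CARAFE with
`σ = 4`, switchable to bilinear.

**Decoder.** The 8×-upsampled pyramid output concatenates with the
1×1-projected (width 48, the DeepLabv3+ convention) low-level map, passes
through one FasterNet refinement block and a 3×3 convolution back to 256
channels, is upsampled 4×, and a 1×1 classifier emits 4-class logits at
input resolution. Ties in the argmax resolve to the lower class index.

**Padding choices.** Convolutions are same-padded with zeros, except the
EMA 3×3 route and the CARAFE content encoder, which use replicate
(edge-clamp) padding: attention weights and predicted kernels should be
translation-invariant on spatially uniform inputs, and zero padding breaks
that exactly at image borders. With replicate padding a constant field
yields spatially uniform attention and, per sub-position offset, identical
reassembly kernels everywhere.

## Training

The engine is a small reverse-mode autodiff over channels-first feature
matrices with Rcpp kernels for im2col/col2im and CARAFE reassembly; its
gradients are validated against central finite differences through the
entire network. The loss is cross-entropy plus soft Dice with unit weights;
Dice uses smoothing ε = 1 and averages over the classes present in the
batch (the mean-IoU formula leaves the empty-class case undefined; absent
classes are excluded rather than scored 0 or 1). The published protocol is
the default `train_config()`: batch size 8, at most 500 epochs, early stop
after 20 epochs without validation-loss improvement, cosine learning-rate
decay from 0.005 to 0.0001. The optimizer description is internally
inconsistent in the source (SGD with momentum in the text, "Adam" in the
parameter table, and two different initial rates); the package defaults to
SGD with momentum 0.937 at the table's rates and offers Adam by
configuration. Weight decay defaults to 5e-4 (unstated in the source).
Augmentation is train-only and online: right-angle rotations, horizontal
flip (p = 0.5), log-uniform rescaling in [0.25, 2], random crop/shift with
grey padding (image 128, mask background), and HSV jitter on the image
only; the two augmentation lists given in the source overlap, so each
transform is individually switchable.

## Length measurement

`predict_mask()` output (or any 4-class mask) is measured in four steps.

1. **Instances.** Seedlings are the 8-connected components of the union of
   the non-background classes. The source never defines instance
   separation; its scenes are well-separated, and touching seedlings merge
   into one instance here.
2. **Skeletonization.** Per instance and class, Hilditch thinning: per
   pass, mark pixels with neighbour count in [2, 6], a single 0→1
   transition around the 8-neighbourhood, and passing the
   connectivity-preservation tests on the north and east neighbours; delete
   all marked pixels; repeat to a fixed point (capped at 500 passes). Two
   guards are added: pixels whose two foreground neighbours are mutually
   adjacent (terminal corners of 1-px staircase lines) are never deleted —
   without this, slanted line ends retract one pixel per pass — and a final
   cleanup peels removable pixels of any fully occupied 2×2 block left at
   junctions. Thinning preserves topology, so masks containing pin-holes
   keep rings around them; seedling masks are hole-free in practice.
3. **Length.** `skeleton_length()` is the classical edge sum — 1 per axial,
   √2 per diagonal 8-neighbour edge, counted once, with diagonal edges that
   merely shortcut two axial edges skipped. This is exact on axial and
   diagonal lines but overestimates digital curves at intermediate
   orientations by up to ~8% (raster staircase), so the measurement
   pipeline instead uses `skeleton_path_length()`: the skeleton is
   decomposed into simple chains, each chain's ordered pixels are resampled
   every 5 pixels, and chord lengths are summed. Resampling straightens the
   staircase: it stays exact on straight lines and tracks the analytic arc
   length of curved strokes to within a few percent. Branched skeletons
   report total length by default; `longest_path = TRUE` reports the
   longest geodesic path instead (the centerline-versus-main-root
   discrepancy is a known error source in this kind of pipeline, and the
   choice is left to the caller).
4. **Calibration.** The coin is found by Hough-gradient voting: Sobel
   gradients, edges above 0.25 of the peak magnitude, and votes cast along
   ± the gradient direction at every candidate radius in [10, 200] px.
   Votes are binned per radius and the 3×3-smoothed peak over all radii
   fixes centre and radius together; binning per radius (rather than
   collapsing all radii into one 2-D accumulator) keeps high-contrast
   seedling edges from hijacking the radius estimate in cluttered scenes.
   A least-squares (Kåsa) circle fit through the radially aligned edge
   points on the detected circle then refines the fit to sub-pixel
   accuracy. With a 25 mm coin, `mm_per_pixel = 25 / (2r)`, and
   `mm = px × mm_per_pixel` (the source calls this factor "pixel per
   metric"; dimensionally it is millimetres per pixel).

## The synthetic-data generator

`generate_scene()` renders the study conditions end to end with exact
ground truth: a dark field (intensity 22) with Gaussian noise (σ = 4),
seeds as filled ellipses (semi-axes 5–9 px), shoots and roots as strokes
stamped along quadratic Bézier curves leaving opposite ends of the seed
(arc lengths 60–140 px and 50–120 px; widths 4–6 px and 3–4 px, roots
thinner than shoots as in real morphology), and one bright disc of radius
25–40 px as the coin. Curvature is bounded (turning angle ≤ 45°) so strokes
cannot self-intersect and the centerline length is well defined; each
curve is rescaled about its start so its polyline-integrated arc length
(1500 segments) matches the sampled target exactly, and that value is the
recorded truth. Seeds are drawn after strokes so the junction belongs to
the seed class; objects keep a 6 px clearance, and the coin never touches a
seedling. On a 320×320 canvas these proportions mimic a downscaled
germination-board photograph.

What the generator does *not* emulate: specular highlights and embossing on
the coin, soft shadows, blur, fluff and secondary roots (which annotation
policy treats as background), touching or crossing seedlings, and
perspective distortion. Passing the recovery tests therefore shows the
geometry pipeline is correct and well calibrated, not that segmentation of
real photographs is solved; the network's accuracy on real boards still
depends on training data.

## Problem sizes used by the test suite

The suite exercises the published 512×512 stage shapes once with the
default architecture, checks operator oracles on inputs up to 3×8×8, runs
the length pipeline on 100 default scenes (coin centre/radius within 2 px;
mean absolute length error under 5%), and trains a width-reduced model
(widths 8–64, pyramid width 64) on 64 single-seedling 128×128 scenes for 18
epochs with Adam at 2e-3, which exceeds 0.8 validation mIoU on 16 held-out
scenes. These sizes were chosen so the full suite runs on one CPU core in
minutes while still covering every contract end to end.

## Known limitations

- Training is CPU-bound and single-threaded apart from BLAS; the package
  is built for method study and desk-scale experiments, not for training
  production models on large image sets.
- Skeleton-based lengths undercount by roughly half a stroke width at each
  end (thinning erodes end caps); for the default stroke widths this is
  the dominant component of the residual ~2% mean error.
- One coin per image is assumed; multiple circular objects in the radius
  range will compete in the accumulator and the strongest wins.
- Instances are defined by connectivity, so physically touching seedlings
  are measured as one (flagged only by their merged component).

## A worked example

```{r}
library(dfma)

sc <- generate_scene(scene_spec(seed = 42))
res <- measure_image(sc$sample$image, sc$sample$mask)
res[, c("instance_id", "shoot_mm", "root_mm")]
```
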