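---
title: "Methods: a two-stage RGB-D cascade for tomato sucker segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-stage RGB-D cascade for tomato sucker segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomseg)
```

## The problem

Tomato suckers (axillary shoots) grow at stem nodes, always in the axil
between the stem and a branch, and should be pruned while small. Finding
them in images is a four-class semantic-segmentation problem — every pixel
is other (0), stem (1), branch (2) or sucker (3) — complicated by two
things: the target structures are thin and elongated, so aggressive
down-sampling destroys them, and a *far* stem crossing behind a near
stem–branch junction looks exactly like a sucker in a flat 2-D image.
Depth resolves that second ambiguity: a sucker sits at its stem's distance,
while a crossing stem sits farther back.

## The model

The network is a two-stage cascade driven by prediction confidence.

**Stage 1** is a small depthwise-separable (DSConv) chain
3→32 (stride 2)→64 (stride 2)→96→32, a 1×1 convolution to 4 class
channels, a bilinear ×4 upsample and a softmax. Its job is not the final
answer: the per-pixel confidence `Premax(p) = max_c p_c` is compared with a
threshold `t1` (default 0.7). Pixels with confidence ≤ `t1` are **hard**
— in practice exactly the stem/branch/sucker pixels and ambiguous
boundaries — and only they carry information forward.

**Stage 2** receives three inputs through 3×3 convolutions concatenated at
a 12:16:4 channel ratio: the full RGB image, the RGB image with easy
pixels zeroed, and the mean-centered depth map with easy pixels zeroed.
Centering (`D = d − mean(d)`) removes the camera's absolute distance, so
prediction is bit-for-bit invariant to a constant depth offset; we then
scale by 1/1000 so the depth branch's dynamic range matches the
[0,1]-scaled RGB branches. The trunk descends to 1/8 resolution (tapping a
64-channel skip `C1` at 1/4), runs three inverted bottleneck residual
blocks (expansion 6, 5, 4), then three *feature blocks* that trade width
for diversity: each is three parallel grouped convolutions with kernels
3/5/7 and group counts `w`, `w/2`, `w/4`, summed and mixed by a 1×1
convolution (the dilated variant uses rates 1/2/3). A pyramid-pooling
module (bins 1, 2, 3, 6) adds global context at 96 channels, the result is
upsampled ×2 and fused with `C1`, and a classification head (two DSConv
layers, ×4 upsample, dropout 0.1, 1×1 convolution) emits the final
full-resolution four-class map. Keeping the minimum resolution at 1/8
rather than 1/16 is deliberate: suckers are small, and most of their
signal would not survive deeper down-sampling.

Two ablations are built by the same code: **Version 2** keeps both stages
but feeds the third input branch with masked RGB instead of depth;
**Version 1** is the stage-2 architecture alone on plain RGB with no
gating.

## Architecture ambiguities and the parameter-count arbitration

The block tables this architecture is specified by leave several details
open, and one entry is impossible as printed (a 7×7 branch with 26 groups
on 64 channels — 26 does not divide 64). Rather than guess, the package
enumerates every reading as `arch_variant_flags()` — bias placement,
normalization affinity, feature-branch style, the third-branch group
count, the bottleneck channel chain, and the skip-fusion form — and
`resolve_variant()` counts the trainable parameters of every combination,
comparing against the published totals (680,760 for the proposed network;
680,832 for Version 2). No combination matches exactly, which is expected
given the typo; the nearest combination differs by **+3 parameters on both
totals** (0.0004%), and every candidate reading reproduces the 72-parameter
difference between the two variants, which is pinned down by the depth
(1-channel) versus RGB (3-channel) third input convolution:
3·3·4·(3−1) = 72. That nearest combination is frozen as the package
default — biases off before normalization, non-affine normalization,
grouped-plus-pointwise feature branches, third-branch groups 16 (the
`w/4` pattern of the sibling tables), the bottleneck chain collapsed to
64 channels (matching the 64-channel input the first feature block
requires), concatenating skip fusion — and the per-block delta report is
archived at `inst/extdata/variant_report.txt`. `count_params()` counts
every trainable entry (kernels, enabled biases, affine pairs) and is
property-tested against a closed-form accounting.

## The layer engine

No deep-learning framework is involved: the package carries its own layer
engine (grouped/dilated/strided convolution via im2col in C++, bilinear
resampling as separable matrix products, adaptive average pooling,
dropout, softmax), each layer with an explicit backward pass verified
against numerical differentiation. Feature maps are `(H*W) × C` matrices.
Convolutions use "same" zero padding with output `ceil(in/stride)`; inputs
not divisible by 8 are zero-padded and the output cropped back, so no
shape ever fails. Upsampling is bilinear without corner alignment.
Rectification is plain ReLU except inside bottlenecks, which use the
clipped (ReLU6) variant of their mobile-architecture lineage.

Normalization is *instance* normalization: each channel is standardized
over the pixels of the sample being processed, identically in training and
evaluation. The engine processes samples one at a time (gradients are
accumulated across a batch before each SGD step), so per-sample statistics
are the only coherent choice; an early design that kept running averages
for evaluation mode trained well but evaluated poorly, because statistics
memorized from tiny training sets transfer badly. Instance statistics keep
inference deterministic — two forwards of the same input are identical —
which the tests rely on. Normalization layers are non-affine under the
frozen flags and therefore contribute no trainable parameters.

## Training protocol

Training runs twice. Phase one sets the stage-1 output as the final output
and optimizes stage-1 parameters alone. Phase two freezes stage 1 — its
weights are never touched again, a contract the tests check bit-for-bit —
and optimizes stage-2 parameters against the final output, recomputing the
hard-pixel masks per batch with the frozen stage 1 in evaluation mode.
The hyperparameters are batch size 12, 40 epochs, initial learning rate
0.025 multiplied by 0.997 at every optimizer step ("iteration" is read as
one optimizer step, the finer of the two possible readings). The optimizer
is SGD with momentum 0.9 and no weight decay, matching the real-time
segmentation lineage the blocks come from; the loss is unweighted
per-pixel cross-entropy over the four classes, with a per-class weight
hook left in the configuration. No pretrained weights are used.
Checkpoint selection uses validation mean IOU (the split is a seeded
uniform 80/10/10 shuffle).

Augmentation applies, each with probability 1/2: horizontal flip; scale-up
by a random rate in [1, 2] with a random crop back (nearest-neighbor for
label and depth so values stay exact, bilinear for RGB); Gaussian blur
(σ ∈ [0.5, 1.5]); additive channel noise (±10 of 255); brightness
(±20%). The photometric magnitudes are the package's own choices — only
the operation list and the scale range are prescribed. Spatial operations
are rigid or scaling, so the sucker-between-stem-and-branch adjacency
survives augmentation.

## Synthetic scenes

The farm dataset behind the published numbers is not deposited, so the
package generates synthetic RGB-D scenes that reproduce its *statistical*
structure rather than its appearance: thin near-vertical stems (8–14 px
wide) with diagonal branches (5–10 px) leaving at nodes, suckers (4–8 px
wide, 20–60 px long) along the stem–branch axil bisector so every sucker
component touches both a stem and a branch within 2 px; a second plant
drawn first and occluded, so far stems cross behind near junctions — the
depth-ambiguity case the cascade exists for; and three depth layers (near
plant 500 mm, the typical camera working distance; far plant 900 mm;
background 2000 mm) plus Gaussian noise (σ = 4 mm), so sucker depth tracks
stem depth within the noise. Rendering is flat class-dependent
greens/browns with additive noise; boundaries are hard so labels are
unambiguous. With the defaults, suckers occupy roughly 0.5–2% of pixels
depending on canvas size — the heavy class imbalance of real scenes.
What passing tests on these scenes shows is that the implementation
optimizes, gates and scores correctly; they say nothing about accuracy on
real greenhouse imagery, which also varies in illumination, texture and
depth-sensor artifacts that this generator deliberately does not model.

## Numerical choices and problem sizes

Tests and examples run at reduced scale as the package's own choice of
study size: scenes of 120×160 (or 48–80 px for unit tests) rather than
the camera's 480×640, and a five-scene capacity study that probes whether
the two-phase protocol can drive training mean IOU to at least 0.9 within
500 optimizer steps. That study uses batch size 1 and no augmentation —
a capacity probe wants the fastest faithful optimization of the fixed
training set, and with five scenes a step on one scene is the natural
iteration unit. Other conventions: confidence exactly equal to `t1`
counts as hard (borderline pixels can only gain from the extra
information); depth centering happens before easy-pixel zeroing, so the
scene mean does not depend on `t1`; a connected sucker region of area
exactly `t = 160` survives the noise filter (removal is strictly-below);
components are 8-connected by default (4-connected available); ground
truth components are never noise-filtered (annotations are trusted); and
mean IOU is reported both over all four classes and over the three
foreground classes, since the published aggregation does not say whether
background is included.

## Known limitations

The engine is CPU-bound R/C++ and runs at desk scale, not camera rate; the
published frame rates are hardware statements and are not reproduced.
Version 1's printed parameter total (690,596) exceeds Version 2's despite
lacking stage 1, which no reading of the ablation diagram reconciles, so
this package's Version 1 (667,588 parameters under the frozen flags) is
structurally faithful but not count-matched, and its total is not treated
as an anchor. Published accuracy figures (IOU 64.05, 80.2% sucker
detection) require the undeposited farm dataset; the package's tests
replace them with the property-based checks described above.
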