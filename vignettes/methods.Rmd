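---
title: "Structure- and pathology-aware virtual staining of coronary OCT: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure- and pathology-aware virtual staining of coronary OCT: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Optical coherence tomography (OCT) resolves the cross-sectional
microstructure of coronary arteries in vivo, but clinicians read pathology
from hematoxylin–eosin (H&E) histology, which requires excised, chemically
processed tissue. Virtual staining aims to translate an OCT cross-section
into an H&E-like image without any staining chemistry. Two obstacles shape
the design: OCT/H&E pairs are never pixel-aligned (the tissue deforms during
processing), so training must work on *unpaired* image collections; and a
translation trained only to look plausible tends to erase exactly the
features that matter clinically — the three-layer wall architecture
(intima, media, adventitia) and focal pathology (lipid pools,
calcifications).

`octstain` implements a cycle-consistent adversarial translator whose
generators carry two extra, supervised heads — a layer-segmentation head and
a normal/pathological classification head — that constrain the synthesis to
preserve structure and pathology.

## Model

Two generators map between the domains (`G_O→H`, `G_H→O`), each judged by a
patch discriminator (`D_H`, `D_O`) with a 70-pixel receptive field computed
analytically from its layer stack (4×4 kernels; strides 2, 2, 2, 1, 1).

Each generator is a U-Net style extractor: three stride-2 convolutions
produce a feature pyramid; three transposed convolutions with skip
concatenations restore resolution; a final sigmoid keeps outputs in [0, 1],
matching the input scaling. At the deepest scale two transformer components
operate:

* **Windowed-attention blocks.** Tokens are partitioned into non-overlapping
  `s × s` windows (`s` = 4 by default, so a window holds 16 tokens); each
  window runs multi-head self-attention
  `SoftMax(Q Kᵀ/√d + B) V` with projection matrices shared across windows
  and a learnable relative-position bias table of `(2s−1)²` entries per
  head. Layers alternate plain and cyclically shifted windows
  (shift `s/2`) with the standard region masking at the wrap-around
  borders; each layer is pre-norm residual with a two-level GELU MLP.
  A residual sub-block chains its layers and closes with a 3×3
  convolution; because every layer is residual, the chained output already
  carries the block input through to the closing convolution.

* **Structure/pathology head.** The pyramid levels are average-pooled onto
  the deepest grid, concatenated channel-wise, cut into patches (row-major),
  linearly embedded and summed with learnable position embeddings. A
  transformer encoder contextualizes the tokens; a decoder processes them
  jointly with three learnable class embeddings (intima, media,
  adventitia). Segmentation logits are the scalar products between patch
  embeddings `z_M` and the decoded class embeddings, nearest-upsampled to
  pixels and softmaxed. Classification applies a two-level MLP to pooled
  `z_M`. The same `z_M`, reshaped to the deepest grid, is concatenated with
  the attention-block output before up-sampling, so the head actively steers
  the synthesis.

Two head-design points deserve their rationale. First, the head tokenizes
the *fused multi-scale* pyramid rather than the deepest level alone: with an
untrained encoder the deepest features carry no linearly recoverable lesion
signal (a ridge probe stays at chance), while multi-scale tokens do; the
head is meant to see structure at every scale. Second, the classification
MLP receives the concatenation of mean- and max-pooled `z_M`: segmentation
training aligns tokens with the class embeddings, which makes the token
*mean* nearly identical across specimens (layer proportions are similar),
erasing focal-lesion evidence; the max-pooled profile keeps anomalous
tokens visible. Mean pooling alone left classification at chance even on
training data.

## Training objective

Five terms, combined as

    L = L_adv(H) + L_adv(O) + α·L_cycle + β·L_embedding + γ·L_SC + ι·L_PA

with defaults α = 1, β = 0.2, γ = 5, ι = 5. Adversarial terms use the
least-squares form (discriminator `E[(D(real)−1)²] + E[D(fake)²]`, generator
`E[(D(fake)−1)²]`). Cycle consistency is the mean L1 error of both
round-trips. The embedding term is the mean L1 distance between the
bottleneck (deepest encoder) embedding of an input and that of its cycle
reconstruction, both directions — a latent-space consistency that the
weights isolate behind β so alternatives are pluggable. `L_SC` is pixel-wise
three-class cross-entropy of each generator's segmentation of *its own
input* against that input's mask (in an unpaired setting the input's own
annotation is the only coherent supervision); background pixels are excluded
(the class set is the three wall layers). `L_PA` is binary cross-entropy of
the pathology probability against the image-level label. Masked samples are
the only contributors to `L_SC`; every sample contributes `L_PA`.

Optimization alternates a generator-side Adam step (β₁ = 0.5, β₂ = 0.999)
on the weighted total with a discriminator-side step on the least-squares
term with fakes detached. The learning rate starts at 1e-4 and decays
linearly to zero over the configured horizon in 2-epoch blocks. Batches are
drawn independently from each domain per epoch (epochs follow the larger
domain); left-right flips with probability 0.5 augment images and masks
together. An optional fake-image history pool for the discriminators exists
but is off by default, keeping runs bit-reproducible under a fixed seed.

The exact breakdown identity
`total = adv_H + adv_O + α·cycle + β·embedding + γ·sc + ι·pa`
is asserted on every step; a non-finite term aborts with the term named.

## The coronary phantom

The motivating clinical dataset is private, so the package ships a synthetic
phantom that reproduces the *statistical* structure the model needs:
unpaired two-domain images over a shared anatomy, a three-layer laminar
wall, focal pathology, image-level labels everywhere and pixel masks for a
subset. Geometry is planar (layer boundaries are gently undulating
horizontal bands) because training patches of a vessel wall are locally
laminar; no attempt is made at catheter/polar geometry, wave-optics speckle,
or stain chemistry.

* **OCT domain**: per-layer mean reflectivity (intima 0.78, media 0.36,
  adventitia 0.60 — bright/dark/intermediate, as in wall imaging) with
  exponential depth attenuation, multiplied by unit-mean gamma speckle with
  shape `1/speckle_contrast²` (default contrast 0.35), the first-order
  multiplicative speckle model.
* **H&E domain**: per-layer RGB palette (eosin-pink intima, purple-shifted
  media, collagen-pink adventitia, near-white lumen) plus Gaussian noise
  (sd 0.025).
* **Pathology**: elliptical inclusions. Lipid renders as a near-white hole
  in H&E and a smooth low-signal void in OCT; calcification as dark purple
  in H&E and a sharp low-signal core with a bright rim in OCT. The default
  semi-axis range is 6–16 px at the 64-px preset: lesion diameters
  comparable to the layer thicknesses, which is how real lipid pools and
  calcifications scale — cell-sized specks would be both unrealistic and
  invisible at the head's token resolution.
* **Labels**: the image-level label is 1 iff at least one inclusion was
  placed; the mask stores the four-class geometry (three layers +
  background) actually rasterized. Half the samples carry masks by default —
  the fraction of the original collection that was pixel-annotated is not
  public, and 0.5 is an arbitrary but documented choice.

Everything is drawn from a per-sample seed derived from the master seed, so
a dataset is byte-identical across runs. What passing phantom tests does
*not* show: robustness to real catheter artifacts, polar geometry, stain
variability between laboratories, or lesion morphologies beyond ellipses.

## Desk-scale study sizes

All shipped experiments run on one CPU core. The default generator preset is
64 × 64 patches with widths 6/9/12, transformer width 24 over three heads,
one residual attention sub-block of two layers, and a head of two encoder
plus two decoder layers; the discriminators start at 16 channels. A
368 × 368 preset with the full-scale widths (32 base, 96 transformer
channels, two sub-blocks) is provided for paper-scale work on capable
hardware. The documented study trains 2000 steps on 30 unpaired 64 × 64
phantoms (16 normal, 14 pathological, half masked), evaluates on 20 held-out
phantoms, and compares head-ablated models over 3 seeds at 32 × 32 with 250
steps. The study treats its 2000 steps as a *truncated prefix* of the
published 10,000-epoch schedule: the decay horizon is left at 10,000
epochs, so the learning rate stays effectively at 1e-4 — truncating a long
schedule preserves the effective learning rate the full run would have used
during those steps, whereas compressing the decay into the short run would
silently halve it. These sizes are the package's definition of "desk
scale": small enough to rerun routinely, large enough that the loss trace,
the held-out classification and the palette recovery are meaningfully
testable. Layer-palette recovery is measured on wall-layer tissue only
(lesion pixels, which are near-white or dark purple by construction, are
excluded from the per-layer color means).

## Metrics

**FID** between two image sets is the Fréchet distance
`|μ_A − μ_B|² + Tr(Σ_A + Σ_B − 2(Σ_A Σ_B)^{1/2})` between Gaussian fits to
per-image pooled deep features. The matrix square root uses
eigendecomposition of the symmetrized cross term with negative eigenvalues
clipped (tolerance 1e-6); near-singular covariances receive 1e-10 diagonal
loading, with a message. The printed form of this distance in some sources
omits the matrix square root and flips a sign; the standard Fréchet form is
implemented, and a test cross-checks it against an independent
Denman–Beavers square-root algorithm.

**PHV** compares, channel by channel, the set-mean globally average-pooled
activations of a chosen extractor level; it reports the percentage of
channels agreeing within a threshold T (default 0.02). The step direction is
chosen so that *higher means more similar* (identical sets score 100) —
the opposite direction would contradict the interpretation of higher scores
as better. Because the domains are unpaired, pooling is set-level: per-image
pooled features are averaged over each set before differencing.

Both metrics accept any extractor; the default is a seeded, fixed-weight
three-stage convolutional backbone (8/16/32 channels), deterministic and
dependency-free. A large pretrained residual network can be plugged in where
its weights are available; the desk-scale tests deliberately do not depend
on one.

**Reader-study statistics** treat "real" as the positive class:
accuracy, precision, sensitivity and specificity per reader, unweighted
averages, and — when per-image ratings are available — the intraclass
correlation ICC(2,1) (two-way random effects, absolute agreement, single
rater; the variant is stated because sources often leave it unspecified).
Zero-denominator statistics are reported as undefined (`NA`), never as 0.

## Numerical and engineering choices

The package trains its networks through a small reverse-mode autodiff core:
a dynamic tape of value/gradient nodes with hand-written backward closures
per operation, convolutions lowered to matrix products through C++
im2col/col2im kernels, and windowed attention implemented as a single
composite operation (one node per layer rather than per window/head) to keep
tape overhead low. Gradients of every operation are verified against central
finite differences in the development suite; the end-to-end test asserts
that every trainable parameter receives a nonzero gradient through a full
training objective, which guards dead branches such as the head-to-decoder
concatenation.

Other fixed choices: sigmoid output activation (to honor the [0, 1] range);
instance normalization in the convolutional trunk and discriminators (first
discriminator block unnormalized); LeakyReLU(0.2) activations; He/Glorot
style initialization from the model seed; softmax computed with row-max
subtraction; binary cross-entropy evaluated in softplus form from logits,
with the probability-space API clamped at 1e-7; cross-entropy under
nearest-neighbor upsampling computed exactly at token resolution via
per-token class pixel counts (mathematically identical to upsampling the
logits, at an eighth of the cost); checkpoints store all parameter arrays
keyed by hierarchical names plus the generator configuration under a
versioned header.

Tiled inference feathers overlapping tiles linearly and normalizes by the
accumulated weight; a tile covering the whole image bypasses blending and
reproduces the raw forward pass bit-exactly. 3D volumes are stained slice
by slice and written as multi-page TIFF; 8/16-bit quantization rounds half
away from zero.

## Known limitations

* The phantom is a statistical stand-in, not a physical simulation; results
  on it bound nothing about clinical OCT.
* Arbitrary-size single-pass inference is not supported: position embeddings
  fix the token grid, so other sizes go through tiling at the trained patch
  size.
* The embedding loss is one defensible reading of a latent-consistency
  term; it is isolated behind its own weight so alternatives can be swapped
  in.
* Lesion sub-typing (lipid vs calcium) is out of scope: the head is binary
  normal/pathological.
* At desk scale the adversarial game is run far short of convergence; the
  shipped study demonstrates learning dynamics and head supervision, not
  publication-grade image quality.
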