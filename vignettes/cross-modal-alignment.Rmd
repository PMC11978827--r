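---
title: "Cross-modal alignment of fMRI voxel signals and images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal alignment of fMRI voxel signals and images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofusion)
```

## The model

`neurofusion` aligns two views of the same visual event — an image and the
brain's voxel-level response to it — in one shared feature space.

**fMRI branch.** A brain volume is reduced to a voxel grid: integer lattice
coordinates, an integer ROI label per voxel, and a per-stimulus amplitude per
voxel. Voxels are serialized in ascending (z, y, x) order; that order is fixed
at grid construction and shared by every component that touches voxels. Three
steps produce the branch's features:

1. *Coordinate embedding.* Each voxel's (x, y, z) triple, rescaled to
   [0, 1] per axis, is mapped by one affine transform into the model
   dimension d. The embedding depends only on where a voxel sits, never on
   its signal.
2. *Tokenization.* The serialized amplitude sequence is chunked by a strided
   1D convolution (kernel 32, stride 16 by default) into tokens; each token
   receives, additively, the mean coordinate embedding over its receptive
   field. The two printed ingredients of this fusion live at different
   resolutions (the convolution downsamples, the concatenated embedding does
   not), so the residual addition is interpreted at token resolution —
   pooling the embeddings over each token's receptive field is the unique
   reading that keeps the sum well-typed while preserving both ingredients.
   Voxel counts not aligned to kernel/stride are right-zero-padded into one
   extra token whose true (unpadded) range is recorded; no signal is
   discarded.
3. *Sliced-window transformer.* Each of h = 2 layers slices its token
   sequence into windows of width w = 64 sliding with stride s = 32, runs a
   standard pre-norm transformer block (4 heads, GELU feed-forward of width
   4d — unstated upstream, standard choices, all configurable) inside each
   window with padded positions masked out of attention, and reassembles a
   full-length sequence by averaging overlapping window outputs
   position-wise. Averaging is used because the upstream description only
   says slices are collected for the next layer: position-wise averaging is
   deterministic, order-independent, and length-preserving. The global
   feature is the token mean of the final sequence (the pooling is likewise
   unstated upstream); per-ROI features are receptive-field-weighted means
   of the final tokens, projected by a linear head.

"Multi-scale" behaviour comes from stacking layers over the fixed (w, s);
no per-layer scale schedule is claimed anywhere, so none is invented —
per-layer (w, s) vectors are accepted but default to constant.

**Visual branch.** A small self-contained backbone (`tiny_conv`: four
3×3-conv + mean-pool stages, a 224×224 input becomes a 7×7 feature grid)
replaces the large pretrained backbones of the original setting, which need
external weights and GPU-scale training. One fully connected head projects
the flattened grid to the global feature; one head per brain ROI projects
the same flattened grid to that ROI's local feature. How image regions
should correspond to brain ROIs is not specified anywhere upstream — here
the per-ROI heads are free projections and the ROI-guided loss is what
creates the correspondence.

A deliberate design revision: an earlier draft of this package projected the
*grid mean* to the global feature. Mean pooling is translation-invariant,
so the global feature was blind to *where* content appears — but the brain
responses the feature must align with are driven by spatially localized,
category-selective content. Measured on the synthetic world below, the
grid-mean feature linearly decodes the generative latents with R² ≈ 0.11
(retrieval ceiling near chance), the flattened grid with R² ≈ 0.74
(near-perfect oracle retrieval). The global head therefore reads the
flattened grid.

**Losses.** With visual globals `p_i` and fMRI globals `q_i` (rows
unit-normalized by default):

* contrastive: symmetric temperature-scaled cross-entropy,
  `L_con = -(1/N) Σ_i log softmax_j(p_i·q_j/σ)[i] + (q→p direction)`;
* ROI-guided: `L_bfg = -(1/N_r) Σ_i Σ_k log[exp(p̄_ik·q̄_ik) /
  Σ_g exp(p̄_ik·q̄_ig)]` — note the printed normalization divides by the ROI
  count only, so this term grows linearly with the batch; a
  `bfg_batch_norm` flag adds the 1/N division for users who want the two
  terms on comparable scales;
* total: `L = λ_con L_con + λ_bfg L_bfg`.

Both losses are computed with log-sum-exp; the contract is exactness of the
printed formula, not a particular evaluation order. Feature normalization
before the dot products is unstated upstream; it defaults to on because raw
dot products at σ ≈ 0.07 overflow. σ, λ_con, λ_bfg have no stated values
anywhere; the defaults (0.07, 1, 1) are the field's conventions and are
flagged as such.

**Fusion and encoding head.** Global and local features of both modalities
form a (2 + 2·N_r)-token sequence with learned modality-type embeddings, one
transformer block mixes them, and the mean-pooled output feeds a linear
encoding head predicting voxel responses. Where the fused representation is
consumed is unstated upstream; here the losses act on pre-fusion features —
matching their printed definitions, which use p and q directly — and the
fused feature feeds only the evaluation head behind the voxel-wise Pearson
correlation (PCC) metric. That head is declared plumbing: the original work
reports PCC without defining the prediction pathway.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| conv kernel / stride | 32 / 16 | voxels | stated tokenizer geometry |
| w / s / h | 64 / 32 / 2 | tokens / tokens / layers | stated windowing |
| d | 32 | — | desk-scale model width |
| σ | 0.07 | — | convention; unstated upstream |
| λ_con, λ_bfg | 1, 1 | — | convention; unstated upstream |
| lr | 1e-4 | — | stated full-scale rate (100 epochs, large data) |
| epochs | 30 | — | desk-scale default |
| batch size | 32 | samples | unstated upstream; convention |
| images | 224×224 | px | stated input size |
| N_r | 6 | ROIs | stated parcellation |

Desk-scale training (a few hundred samples, ~240 optimizer steps) cannot
move Adam at 1e-4; acceptance-scale runs use lr = 0.01. The stated 1e-4
belongs to the full-scale regime with orders of magnitude more steps.

## What training optimizes (and what stays frozen)

The environment has no automatic differentiation, so the package trains what
linear algebra can train exactly: the visual global head, the per-ROI local
heads, the fMRI ROI head, a shared-space projection of the fMRI global
feature, and the encoding head, with hand-derived analytic gradients
(verified against central finite differences in the test suite) under Adam.
The convolutional backbone and the transformer bodies stay at their random
initialization — the random-features regime, standard when studying whether
an *objective* aligns two modalities. The optimized objective is exactly the
weighted total loss above; the auxiliary mean-squared term (weight 0.1)
backpropagates to the encoding head only. The shared-space projection on the
fMRI global is needed because with a frozen transformer body the fMRI side
of the contrastive loss would otherwise have no trainable capacity.

Cached features are z-scored per dimension before the heads see them (frozen
random features have raw row norms around 1e-2, which ill-conditions the
head problem); the standardization is a deterministic function of the
dataset and changes nothing about what is representable.

## The synthetic world

`generate_pairs()` emulates the structure of a natural-scenes fMRI
experiment: `n_vox` voxels on an integer lattice, partitioned into
`n_roi = 6` spatially contiguous ROIs by k-means on coordinates; one latent
code of dimension 4 per (sample, ROI); images rendered procedurally — each
ROI owns a fixed image sector and draws one glyph (discs for even ROIs,
squares for odd) whose RGB colour and radius are the logistic-squashed code,
mimicking category-selective regions; responses
`alignment_strength × (loading · code) + noise_sd × ε` with unit-norm
loadings fixed per grid so the coupling is learnable across samples.
`d_latent = 4` makes the image fully determine each ROI's code (3 colour
channels + radius). Whether inputs should be per-trial responses or raw
time series is ambiguous upstream (features are indexed by time step, the
data described are stimulus-evoked); the generator defaults to per-stimulus
response vectors and offers a T-step repetition with AR(1) noise as a
toggle.

The generator does **not** emulate: haemodynamic response dynamics, scanner
noise physics, cortical geometry, inter-subject variability, or natural
image statistics. A green alignment-recovery test therefore establishes that
the objective and architecture can recover a *planted* smooth
image-to-response coupling at desk scale — not that the method works on real
7T data.

## Numerical choices

* Softmaxes via max-subtraction / log-sum-exp; rows of all-(-Inf) attention
  logits get exactly zero mass.
* Layer norm uses ε = 1e-5; feature normalization clamps norms at 1e-12.
* Retrieval ties break toward the lower candidate index (deterministic).
* Zero-variance voxels are excluded from PCC and counted in an attribute;
  an all-excluded input is an error, not an NaN.
* IoU of two empty masks is defined as 0, with a message.
* Right-zero padding everywhere records true (unpadded) ranges; coverage is
  exact for every (L, w ≥ s) under `pad_last` (exhaustively tested).
* Weight and model archives store tensors as 17-significant-digit decimal
  strings (bit-exact IEEE round trip) behind a SHA-256 checksum line.
* NIfTI-1 I/O is implemented in-package (no R NIfTI reader is available in
  the target environment) and cross-validated against nibabel; volumes are
  used in stored index order with no reorientation (documented limitation).

## Known limitations

* Frozen-body training measures the objective, not end-to-end
  representation learning; full backpropagation through the backbone and
  transformer stack is out of scope here.
* The printed ROI-guided loss has no temperature and batch-linear scale;
  λ_bfg interacts with batch size unless `bfg_batch_norm` is enabled.
* The per-ROI image heads share one input (the flattened grid); nothing
  constrains them to *spatial* sectors except the loss.
* Retrieval metrics at desk scale (64 held-out samples) have ±0.016 SE at
  chance; single-seed numbers are noisy, which is why recovery tests
  aggregate five seeds.
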