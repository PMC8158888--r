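---
title: "Coarse-to-fine 2.5D attention segmentation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine 2.5D attention segmentation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Small abdominal organs such as the pancreas are hard to segment from CT:
the organ occupies well under 2% of the volume, its intensity barely
differs from surrounding soft tissue, its boundary is blurred, and its
shape and pose vary strongly between subjects. A segmenter applied to the
whole volume spends almost all of its capacity on background and is easily
distracted by structures of similar intensity. `pancseg` implements the
two ideas this package is organized around:

1. **A 2.5D U-like network with dense blocks and hybrid attention.** Each
   training sample is a single 2D slice plus its two neighbours stacked as
   three channels, giving a 2D network limited through-plane context at a
   fraction of the cost of a full 3D model. The first encoder levels treat
   those three channels as a depth-3 volume and run 3x3x3 convolutions;
   deeper levels are 2D. Convolutions are organized in dense blocks, and
   every skip connection is gated by a hybrid spatial + channel attention
   module.
2. **A coarse-to-fine multi-view cascade.** Three per-view models
   (sagittal, coronal, axial) are fused per voxel by majority vote. The
   fused coarse mask localizes the organ; a safety frame is added and the
   image is cropped; three fine-stage models segment the crop at higher
   effective resolution, are fused again, and the result is stitched back.

## Model definition

For a slice stack $S_1,\dots,S_n$ along one view, the network input for
slice $i$ is

$$I_i = \begin{cases}(S_i, S_i, S_i) & i = 1 \text{ or } i = n\\
(S_{i-1}, S_i, S_{i+1}) & \text{otherwise,}\end{cases}$$

i.e. end slices are replicated rather than zero-padded
(`make_input25d()`). The model maps the $(H, W, 3)$ input to a centre-slice
foreground probability map through:

* **Encoder** — `n_blocks` dense blocks with 2x2 max pooling between
  levels; level $k$ has width `base_channels * 2^(k-1)`. The first
  `n3d_blocks` levels run 3x3x3 convolutions with depth-preserving padding
  on the depth-3 tensor; after the last 3D level, depth is folded into
  channels and processing continues in 2D.
* **Dense block** — `dense_layers` (default 6) 3x3 convolutions where
  layer $j$ sees the concatenation of the block input and all previous
  layer outputs, each adding `growth` channels, followed by a 1x1
  transition to the block width. Six stacked 3x3 kernels give a 13x13
  receptive field, which matters once the fine stage makes the organ large
  relative to its crop.
* **Hybrid attention on skips** — at level $k$ the gate takes
  $X \in \mathbb{R}^{w\times h\times c}$ (level-$k$ features) and
  $Y \in \mathbb{R}^{w/2\times h/2\times 2c}$ (level-$k{+}1$ features).
  The *spatial* branch upsamples $Y$ 2x, channel-matches it with a 1x1
  convolution, adds it to $X$, applies two 1x1 convolutions
  ($c \to c/2 \to 1$) and a sigmoid, and multiplies the resulting
  single-channel weight map into $X$. The *channel* branch concatenates
  $X$ with upsampled $Y$ (3c channels), reduces it by global average *and*
  global max pooling, passes both descriptors through one shared linear
  map ($3c \to c$), sums them, applies a sigmoid and scales $X$
  per channel. The two branches are summed. With all attention weights at
  zero each branch outputs exactly $0.5X$ and their sum returns $X$ — a
  property the test suite checks analytically.
* **Decoder** — `n_blocks` dense blocks with bilinear 2x upsampling; level
  $k$ concatenates the upsampled deeper features with the gated skip. A
  1x1 convolution plus sigmoid yields the probability map.

Training minimizes the soft Dice loss
$L = 1 - (2\sum_i y_i\hat y_i + \varepsilon)/(\sum_i y_i + \sum_i \hat y_i
+ \varepsilon)$ with Adam. Evaluation uses the Dice similarity coefficient
$\mathrm{DSC} = 2|A\cap B|/(|A|+|B|)$ on the reconstructed full-resolution
3D masks.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_lo`, `window_hi` | -100, 240 HU | CT soft-tissue clipping window |
| `out_lo`, `out_hi` | 0, 255 | rescaled intensity range (kept floating point) |
| `target_size` / `in_size` | 224 x 224 px | network-resolution slice size |
| `n_blocks` | 4 | dense blocks per path |
| `n3d_blocks` | 2 | leading 3D encoder levels |
| `base_channels`, `growth` | 32, 32 | level-1 width; channels added per dense layer |
| `epochs`, `learning_rate`, `batch_size` | 30, 1e-5, 1 | reference training regime |
| `val_fraction` | 0.10 | fraction of training slices held out |
| `min_pancreas_pixels` | 100 | strict slice filter for coarse training |
| `margin` | 20 voxels | safety frame around the coarse mask |
| `vote_threshold` | 0.5 | fraction of views required (2 of 3) |

## Design choices where the design was open

* **Slice filter scope.** The >100-pixel foreground filter applies to
  coarse-stage training only; the fine stage trains on every cropped slice
  containing any foreground. Fine-stage crops derive from ground-truth
  boxes plus margin at training time (coarse predictions are not available
  yet), which is standard cascade practice.
* **Normalization.** Each convolution is followed by instance
  normalization rather than batch normalization: with batch size 1, batch
  statistics are degenerate. `norm = "none"` is available.
* **Binarization and voting.** Per-view probability maps are binarized at
  0.5 before fusion, since fusion averages *masks*; a voxel is foreground
  when at least 2 of 3 views agree (`vote_threshold = 0.5`).
* **Localization by largest component.** The bounding box of the coarse
  mask is taken over its largest 6-connected component. A handful of
  isolated false-positive voxels would otherwise inflate the crop to most
  of the volume and starve the fine stage of its resolution advantage;
  component selection affects localization only, never the reported coarse
  DSC. `localize = "full_mask"` restores the plain behaviour.
* **One fused crop.** A single fused coarse mask defines one crop used by
  all three fine views, rather than per-view crops.
* **Upsampling.** Bilinear interpolation everywhere (decoder and attention
  branches): deterministic, artifact-free, and with an exact adjoint for
  the backward pass. Transposed convolutions are not used.
* **Resampling semantics.** Images are resized bilinearly, masks by
  nearest neighbour (they stay binary); per-slice predictions are resized
  back to native in-plane resolution before reassembly because DSC is
  defined on the full-resolution volume. Boxes are 0-based half-open;
  slice indices are 1-based.
* **Empty-mask conventions.** DSC of two empty masks is 1; an empty coarse
  mask triggers a whole-volume fine stage with a warning. The Dice loss
  carries additive smoothing `eps = 1e-6` in numerator and denominator.
* **Standard deviation** of per-case summaries divides by $n$
  (population); `sd_type = "sample"` is available.
* **Fold assignment** shuffles case indices under the configured seed and
  deals round-robin, so fold sizes differ by at most one and the
  assignment is reproducible.
* **Model selection** keeps final-epoch weights; no learning-rate
  schedule, early stopping or augmentation are applied by default.
* Deep supervision is not implemented; the deepest encoder block serves as
  the bottleneck; decoder blocks are dense blocks like the encoder's.

## The compute engine

No deep-learning runtime is assumed: the package ships its own
define-by-run reverse-mode autodifferentiation tape in R over
Rcpp/Armadillo kernels (im2col convolutions in 2D and 3D, max pooling,
bilinear resampling with exact adjoints). The forward pass records nodes
in topological order; the backward pass walks them in reverse. Gradient
correctness is tested against central finite differences through the full
assembled model, with the caveat that ReLU and max-pool kinks can spoil
individual finite-difference probes — the tests therefore assert on the
bulk of sampled parameters.

## The phantom generator

`generate_phantom()` emulates the statistical structure the method
assumes, on the post-preprocessing 0..255 intensity scale: a smooth random
background; a sinusoidally deformed ellipsoid organ (irregular shape,
volume capped at 2% of the voxels, centre drawn near the volume centre —
a location prior analogous to an organ's anatomical position); peripheral
distractor blobs whose intensities overlap the organ's and whose total
volume exceeds the organ's, so that no global threshold can solve the
task; Gaussian blur over the clean image (vague boundaries); and additive
Gaussian noise. Ground truth is the pre-blur organ. Everything is
deterministic given the seed, and case $i$ of a dataset uses seed
`base_seed + i - 1`.

What the phantoms deliberately do **not** model: anatomically realistic
anatomy and organ neighbourhoods, CT physics (beam hardening, streaks,
dose noise models), anisotropic voxel spacing, and inter-scanner
variation. Passing the phantom study shows the pipeline's machinery —
slicing, learning, fusion, cropping, stitching, evaluation — works end to
end and that the cascade's resolution advantage materializes; it does not
certify clinical-grade accuracy on real CT.

## Problem sizes used by the shipped studies

The reference regime (224 x 224 slices, 4+4 blocks, 30 epochs) is the
configuration a practitioner would train on GPU-scale data. The package's
own studies run a scaled-down configuration chosen for desk-scale CPU
work: 64 x 64 x 48 phantoms, 12 training and 4 test cases per seed,
coarse models at `in_size` 32 (3 blocks, width 8, 2 dense layers, one 3D
level) for 6 epochs and fine models at `in_size` 24 for 3 epochs, learning
rate 1e-3, crop margin 6. Under these conditions the fused coarse stage
typically reaches a mean DSC near 0.8 and the cascade raises it to about
0.9, reproducing the direction and rough magnitude of the coarse-to-fine
improvement the method is designed for; the acceptance script
(`scripts/acceptance.R`) recomputes these quantities from scratch for any
seed.

## Known limitations

* CPU-only; a full-scale run (hundreds of 512-resolution slices, 30
  epochs, six models) is out of desk-scale reach.
* The cascade iterates once; no test-time augmentation or ensembling.
* Surface-distance metrics (Hausdorff, ASSD) are not implemented; DSC is
  the only headline metric.
* The attention-gate and dual-attention baseline blocks used in published
  ablations are not reimplemented; the ablation hook that *is* provided is
  `attention = "none"`.
* No DICOM series assembly and no resampling to isotropic spacing; NIfTI
  volumes are consumed at native spacing.
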