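# pancseg

Coarse-to-fine, multi-view segmentation of small low-contrast organs
(pancreas-like targets) from 3D grayscale volumes, built around a 2.5D
U-like encoder-decoder with dense convolution blocks and a hybrid
spatial/channel attention module on the skip connections.

**Who this is for:** researchers and engineers who need a fully tested,
self-contained reference implementation of the 2.5D attention U-net +
coarse-to-fine cascade pattern — runnable end to end on CPU with seeded
synthetic phantom volumes, no external dataset or GPU required.

## The method

Segmentation quality for small organs is measured by the Dice similarity
coefficient between voxel sets *A* (prediction) and *B* (ground truth):

    DSC = 2 |A ∩ B| / (|A| + |B|)

and models are trained with the soft Dice loss
`L = 1 − (2 Σ y ŷ + ε) / (Σ y + Σ ŷ + ε)`.

The pipeline:

1. **Preprocess** — CT intensities clipped to `[−100, 240]` HU, rescaled
   to `[0, 255]`, slices resized to the network input size.
2. **2.5D inputs** — the volume is cut into slices along the sagittal,
   coronal and axial views; slice *i* is stacked with its neighbours as a
   3-channel input `(S_{i−1}, S_i, S_{i+1})` (end slices replicated).
3. **Network** — a U-like encoder-decoder of dense blocks (each 3×3 layer
   sees all previous outputs; 1×1 transition) whose first encoder levels
   are 3D over the slice triple; every skip is gated by hybrid attention:
   a spatial branch `X · σ(conv(f(X, Y)))` and a channel branch driven by
   global average + max pooling through a shared projection, summed.
4. **Multi-view fusion** — per-view masks vote per voxel; foreground needs
   ≥ 2 of 3 views.
5. **Coarse-to-fine** — the fused coarse mask (largest connected
   component) is framed by a safety margin and cropped; three fine models
   segment the crop at higher effective resolution; results are fused and
   stitched back.

See `vignettes/pancseg-methods.Rmd` for assumptions, parameters, and the
design decisions behind every convention.

## Worked example

Generate a phantom (a deformed low-contrast organ under 2% of the volume,
with distractor blobs and noise), check that thresholding cannot solve it,
and run the cascade plumbing with ground-truth oracle models:

```r
library(pancseg)

ph <- generate_phantom(phantom_spec(seed = 1))
ph$fraction                                  # organ volume fraction
#> [1] 0.01869202
threshold_baseline_dsc(ph$image, ph$mask)    # best global threshold
#> [1] 0.5145078

om <- oracle_model(ph$mask)                  # emits ground truth
views <- list(sagittal = om, coronal = om, axial = om)
out <- run_pipeline(ph$image, views, views, margin = 6)
dsc(out, ph$mask)                            # cascade plumbing is exact
#> [1] 1
print(out$box)
#> <bounding_box> lo (12,17,13) hi (51,50,40), margin 6

summarize_scores(c(0.91, 0.88, 0.95, 0.86))
#> DSC over 4 cases: mean 0.9000 +/- 0.0339 (min 0.8600, max 0.9500)
dsc_histogram(c(0.45, 0.55, 0.88, 0.92, 0.97))
#> DSC [0, 0.5]    20.00%
#> DSC (0.5, 0.6]  20.00%
#> DSC (0.6, 0.7]   0.00%
#> DSC (0.7, 0.8]   0.00%
#> DSC (0.8, 0.9]  20.00%
#> DSC (0.9, 1]    40.00%
```

The numbers mean: the organ occupies ~1.9% of the volume; the best
possible global intensity threshold only reaches DSC ≈ 0.51 (the
distractors share the organ's intensities), so spatial context is
required; and the crop/fuse/stitch machinery reproduces a perfect
segmenter exactly, localized to a 39×33×27 block instead of the full
64×64×48 volume.

Training a real model set works the same way at any scale:

```r
cases <- generate_dataset(16, phantom_spec(seed = 1000))
mcfg  <- model_config(in_size = 32, n_blocks = 3, base_channels = 8,
                      dense_layers = 2, growth = 8, n3d_blocks = 1)
tcfg  <- train_config(epochs = 6, learning_rate = 1e-3, seed = 1)
tc    <- train_cascade(cases[1:12], tcfg, mcfg, margin = 6)
mean(evaluate_fused(tc$coarse, cases[13:16]))        # coarse stage
mean(evaluate_pipeline(tc$coarse, tc$fine, cases[13:16], margin = 6))
```

A shell interface covers the same workflow
(`exec/pancseg generate | train | predict | pipeline | evaluate`).

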