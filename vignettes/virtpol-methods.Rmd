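---
title: "virtpol: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{virtpol: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Congo red is the gold-standard stain for amyloid: congophilic deposits
appear pink-salmon under brightfield microscopy and show the diagnostic
apple-green birefringence under crossed polarizers. Both the chemical stain
and the manual polarization imaging are slow, variable, and unsupported by
clinical slide scanners. `virtpol` implements a label-free alternative: a
single conditional GAN that maps four-channel autofluorescence images
(DAPI, FITC, TxRed, Cy5 filter bands) of unstained tissue to (i) virtual
brightfield Congo red, (ii) virtual cross-polarized birefringence, and
(iii) a virtual small-angle-rotated birefringence rendering, selected at
inference time by a *digital staining matrix* (DSM): one extra constant
input channel with value $+1$, $-1$ or $2$.

## Model

Three networks are trained jointly:

* **Generator** $G(I, \tilde c)$ — attention U-Net, four down/up levels.
  Down blocks are three-convolution residual blocks (3×3 kernels, 1×1
  convolutional residual path) with leaky ReLU (slope 0.1) and 2×2
  stride-2 max pooling, doubling channels each level. Up blocks gate the
  skip features with an additive attention gate (both inputs projected to
  half the skip width, summed, ReLU, 1-channel conv, sigmoid), concatenate
  with the bilinearly 2× upsampled decoder state, and reduce channels 4×
  through a residual block; a residual head plus a single conv produces the
  3-channel RGB output (linear activation, clipped to $[0,1]$ only at
  export).
* **Discriminator** $D$ — a conv to `base_width` channels, five
  two-convolution residual blocks (second conv stride 2, channels
  doubling), global average pooling and two dense layers to a sigmoid
  probability. The DSM is concatenated to its input by default (the
  conditional-GAN reading; configurable), resolving the printed
  inconsistency between the generator's and discriminator's adversarial
  terms.
* **Registration module** $R$ — a seven-level U-Net over the 6-channel
  (generated, target) pair whose 1×1 output head regresses the per-pixel
  displacement field $(d_x, d_y)$. The head is zero-initialized so training
  starts from the identity warp. Channel doubling is capped at
  8×`base_width`: the spec fixes seven levels but not the channel schedule,
  and uncapped doubling is intractable on one CPU while adding nothing at
  1–2 px spatial extent.

The losses are

$$L_G = \alpha\, L_1^{s}\!\big(I_t,\; G \circ R\big) + \beta\,
\mathrm{BCE}(D(G, \tilde c), 1) + \gamma\, \mathrm{TV}(G), \qquad
(\alpha, \beta, \gamma) = (10, 1, 10^{-4})$$

$$L_D = \mathrm{BCE}(D(G, \tilde c), 0) + \mathrm{BCE}(D(I_t, \tilde c), 1)$$

$$L_R = \lambda\, L_1^{s}\!\big(I_t,\; G \circ R\big) + \mu\,
\mathrm{SMTH}(R), \qquad (\lambda, \mu) = (20, 10)$$

with the smooth-L1 ($\varphi = 1$), the un-normalized anisotropic TV, and
the mean squared forward-difference field smoothness, all implemented as
printed (index ranges stop at the last valid pixel; no padding or
wraparound; multi-channel images average over channels as well as pixels).
$\circ$ is bilinear resampling of the generated image through the predicted
field. The update schedule is the repeating 6-tick cycle G,G,G,G,D,R
(4:1:1), each module with its own Adam optimizer (betas 0.9/0.999), default
learning rates 2e-5 / 2e-6 / 2e-6, batch 32 of random 256² crops with the
modality drawn uniformly and the DSM always matching the target's modality.

### Why a hand-built autodiff engine

No deep-learning framework exists in the supported R stack, and the
co-trained registration mechanism *is* the contribution under test, so the
package ships a small reverse-mode engine (R tape over Rcpp/Armadillo
kernels: im2col+GEMM convolution, max-pool, bilinear resize, grid sampling
with gradients w.r.t. both image and field). Every operation is validated
against central finite differences in the test suite; the full generator
gradient is additionally smoke-checked for finiteness.

## Data preparation (registration pipeline)

Training pairs are built in two steps. First, a global projective
registration: corner features (Harris response, non-max suppression,
normalized 15×15 patch descriptors, ratio-test matching) on downsampled
luminance images feed an MSAC-style truncated-cost RANSAC homography
(normalized DLT, refit on the consensus set). A scale/rotation-invariant
detector brand is deliberately not mandated — the contract is recovery
accuracy (identity within 0.5 px, a 10 px translation within 1 px).
Second, after tiling, a correlation-based pyramid elastic registration:
coarse-to-fine (4 levels), per-block normalized cross-correlation peaks
(blocks halving from 64 px, 50 % overlap, ±3 px search, parabolic
sub-pixel refinement), zero-variance blocks excluded, displacements
interpolated to a dense field and smoothed. A guard returns the zero field
whenever warping would *increase* the luminance MAE by more than 1 %. The
optional outer loop trains a style-transfer model (the generator without
its registration submodule) so cross-modality tiles are compared in a
common style, repeating until the mean residual displacement is below
0.5 px or 4 rounds — the concrete reading of "repeat until precise
pixel-level registration".

Conventions (used everywhere): 0-based (row, col), origin top-left; a
field stores (dx = col, dy = row) offsets and `warp(img, f)(p) = img(p +
f(p))` with border replication (avoids dark seams that would bias the
losses). For a synthetically *applied* deformation $d$ the recovering
field is therefore the inverse, $\approx -d$.

## The phantom world

Real data are IRB-restricted, so the generator of record is a seeded
phantom: amyloid deposits are thresholded smoothed Gaussian fields
(irregular outlines, graded density — not disks — so morphology and
segmentation are exercised realistically), nuclei are Poisson-disk-placed
disks (unambiguous ground-truth counts), and tissue background is a
smooth random texture. The stack shows correlated amyloid elevation
across all four channels (gains 0.35/0.85/0.65/0.75 — free parameters;
no quantitative autofluorescence signature is published) with nuclei
visible in the DAPI channel. Brightfield targets render amyloid
pink-salmon (RGB 0.90/0.52/0.50) and nuclei dark red-purple on a pale
background; cross-polarized targets render apple-green amyloid
(constant hue 114.7°) on a near-black (0.02) background; the angle-shifted
target applies the package's own hue emulator (deposit hue ×0.6,
background hue ×1.1). Defaults: 256² px, area fraction 0.15, 25 nuclei of
radius 5 px, noise σ = 0.01, deformation amplitude 4 px. Sub-seeds per
sub-process (placement, texture, noise) keep samples bit-reproducible.

What a green test does *not* establish: the phantom map from
autofluorescence to stain is nearly pointwise and noise-light, so passing
desk-scale criteria demonstrates the mechanisms (DSM multiplexing,
co-trained registration, transfer learning), not clinical image quality.

## Evaluation suite

* MAE and PSNR exactly as defined (PSNR's peak is the observed max of the
  ground-truth image, not a fixed dynamic range; identical images return an
  `Inf` sentinel with a warning).
* MS-SSIM with six dyadic scales (11 px Gaussian window, σ 1.5,
  K = 0.01/0.03): contrast–structure at scales 1–5, full SSIM at scale 6,
  weights (0.05, 0.05, 0.1, 0.15, 0.2, 0.45) for brightfield and the
  reversed vector for polarization. RGB pairs are compared on BT.601
  luminance; negative contrast–structure means are clamped at 0 before
  exponentiation. The single-scale core reproduces scikit-image's
  `structural_similarity` to 7 decimals on a frozen fixture. Inputs must
  be ≥ 352 px (11·2⁵) per side.
* FID with a pluggable extractor; offline default is a fixed-seed random
  convolutional extractor (64 features) — FID is well defined for any fixed
  extractor, but values are not comparable with Inception-based numbers.
  Polarization sets are first brightness-adjusted (YCbCr, Y×1.5, clip).
* Apple-green segmentation: HSV band hue ∈ [70°, 170°], s ≥ 0.25,
  v ≥ 0.15, then opening and closing with a 2 px disk. The clinical
  thresholds were pathologist-tuned and unpublished; these defaults are
  calibrated on phantoms and fully configurable.
* D-IoU: 32× block-average down-sampling (the averaging reading of
  "bilinear"; the τ = 1/32² "any coverage counts" threshold presupposes
  it), binarize, intersection over union; empty-vs-empty defined as 1.
* YCbCr histograms (full-range BT.601) as normalized densities plus a
  kernel-smoothed curve, whole-FOV or masked.
* Nuclei: optical density, deconvolution against a 3-stain basis
  (Ruifrok-Johnston hematoxylin vector; a Congo-red vector derived from a
  representative congophilic absorbance; orthogonal residual), Otsu
  threshold, dilation+erosion, 8-connected components with a 6 px minimum
  area.

## Numerical choices and degenerate inputs

BCE predictions are clamped to [1e-7, 1-1e-7]. The covariance square root
in FID uses a symmetric eigendecomposition with negative eigenvalues
clamped at zero. Hue arithmetic is multiplicative on the [0,1) hue
coordinate exactly as described (not a circular rotation); values ≥ 1 are
clipped; zero-saturation (black) pixels are untouched. Tiles not divisible
by 16 are reflect-padded and cropped back. WSI stitching uses linear
feathering over a 64 px default overlap (the stitching method is not
described in the source; feathering suppresses tile-edge artifacts and is
traversal-order independent). Generator inputs are z-scored per channel
with training-set statistics frozen into the checkpoint.

## Desk-scale instantiations

The acceptance criteria run on one CPU with `base_width = 8`, 64–128 px
crops and a few hundred update ticks. The full-scale learning rates
(2e-5/2e-6/2e-6) are kept as `train_config` defaults, but the toy runs use
2e-3 (G) / 5e-4 (D) / 1e-3 (R): at 1/64 of the paper's batch-pixel
throughput the full-scale rates cannot move a freshly initialized network
measurably within the CPU budget. The discriminator rate matters
qualitatively at this scale: with a too-weak discriminator the generator
averages the two birefringence modalities (their targets differ only
inside deposits), and with a too-strong one the brightfield hue drifts —
5e-4 is the balance at which the conditional-adversarial term does its
stated job of separating the DSM channels. The shared three-modality model
behind the DSM-multiplexing, angle-shift and noise-transfer criteria
trains for 600 ticks on six 256² phantoms; the noise-transfer fine-tune
runs 400 ticks on σ = 0.1 stacks. The standalone registration-module probe
trains on four 128² pairs with each step's batch covering the whole set
(sampling without replacement): with batches sampled with replacement, the
300-step budget is too short for the module to stop confusing the
per-pair fields.

Two scales in the phantom world deserve justification. The synthetic
deformation's correlation length is an absolute 32 px, not a fraction of
the image: staining-induced tissue distortion has a physical scale, and a
relative scale would make small test crops disproportionately rough —
rough enough that the field-smoothness penalty (weighted as printed)
would forbid full recovery, misrepresenting the full-scale system. And
the registration probe's image contrast sets the balance between the
data and smoothness terms; the phantom's stained-image contrast is
realistic for the modality, so the printed (λ, μ) = (20, 10) are used
unchanged.

## Known limitations

* The phantom forward model is nearly pointwise; it cannot probe the
  network's use of spatial context or hallucination behaviour on
  out-of-distribution tissue.
* No physical fluorophore or polarization optics simulation (explicit
  non-goal).
* FID values are extractor-specific; only relative comparisons under the
  same extractor are meaningful.
* The CPU engine is double-precision and single-threaded by design (for
  bit-reproducibility); it is a mechanism testbed, not a performance
  implementation.
* Image I/O is 16-bit NetPBM + JSON manifests; slide-scanner formats and
  TIFF are out of scope in this environment.
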