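---
title: "Growing-truss segmentation by depth-colormap translation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing-truss segmentation by depth-colormap translation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The growing truss of a greenhouse tomato plant — the actively growing stem
tip with its young leaves — is the part of the canopy that reacts first to
environmental stress, so locating it in imagery is the entry point for
automated growth monitoring. In RGB alone the task is nearly hopeless: the
truss is green foliage in front of a wall of green foliage. What makes it
separable is geometry, not colour: on a monitoring platform driving along
the row, the growing truss is the structure *nearest the camera*. A depth
camera encodes exactly that — rendered through a colour table, near objects
appear red and the far canopy blue — and a fixed HSV gate on the red band
then isolates the truss.

Depth cameras, however, lose focus at close range and drop out in harsh
greenhouse lighting. The idea implemented here is to learn the mapping from
RGB to the *depth-colormap rendering* with a CycleGAN, so that a plain RGB
stream can be converted to pseudo-depth images and fed to the same
deterministic segmentation chain. Because the translation is learned from
unpaired image sets, no manual annotation is needed.

`trussseg` implements the full pipeline: a synthetic paired-scene generator
(so everything is testable without greenhouse data), the CycleGAN and its
training loop, the HSV/Otsu/morphology segmentation chain, pixel-level
evaluation metrics, and an end-to-end experiment driver comparing the
depth-camera path against the translation path.

## The translation model

Two generators are trained jointly with two discriminators on unpaired
domains $X$ (RGB) and $Y$ (depth colormaps): $G : X \to Y$ and
$F : Y \to X$, with patch discriminators $D_Y$ and $D_X$ judging each
domain. The objective combines least-squares adversarial terms with L1
cycle-consistency terms

$$\mathcal{L} = \mathbb{E}\,(D_Y(G(x)) - 1)^2 + \mathbb{E}\,(D_X(F(y)) - 1)^2
  + \lambda\,\big(\lVert F(G(x)) - x \rVert_1 + \lVert G(F(y)) - y \rVert_1\big),$$

with the discriminators trained on the usual real/fake least-squares
targets. The cycle terms are what make unpaired training work: any mapping
that discards the truss structure cannot reconstruct its input.

Each generator is an encoder / transformer / decoder stack: a 7×7
convolution and two stride-2 3×3 convolutions that double channels while
halving spatial size, a series of residual blocks (8 by default) at the
bottleneck, then two 3×3 transpose convolutions and a 7×7 output
convolution restoring the input resolution. Every layer is followed by
instance normalisation and ReLU.

Design choices made where the design was genuinely open:

* **Output activation.** A strict per-layer ReLU cannot emit negative
  values, so the generator's final layer uses tanh instead, with images
  normalised to $[-1, 1]$. This is the only departure from
  ReLU-everywhere, and is forced by the value range of colour images.
* **Discriminator.** A 70×70-receptive-field patch discriminator
  (three stride-2 4×4 convolutions, then two stride-1 4×4 layers; leaky
  ReLU 0.2, instance-normalised except the first layer). Patch
  discriminators judge local texture rather than whole images, which both
  regularises and keeps parameter counts small.
* **Losses and optimiser.** Least-squares adversarial loss (stable at
  small scale), cycle weight $\lambda = 10$, Adam with learning rate
  2×10⁻⁴ and $\beta_1 = 0.5$. An identity loss
  ($\lVert G(y) - y\rVert_1$, useful against hue drift) is available via
  `identity_weight` but off by default.
* **Batching.** Training draws one independent batch from each domain per
  iteration (batch size 5 by default), so domains of different sizes and
  with no pairing are handled naturally. No image-history buffer is kept
  for the discriminator updates: at the scales this package targets it was
  not needed for stability.
* **Padding.** Convolutions use zero padding rather than reflection
  padding; at the trained scales no border artefacts attributable to this
  were observed in the converted images.
* **Resizing.** Inputs of other sizes (e.g. 1600×900 camera frames) are
  resized to the generator's native square size by plain bilinear
  interpolation, accepting the aspect distortion of a direct resize.

The engine behind these networks — strided convolution, transpose
convolution, instance normalisation and Adam, with analytic
backpropagation — is implemented in the package itself (im2col/col2im plus
BLAS matrix products via RcppArmadillo). Every gradient path is verified
against central finite differences in the test suite, and training is
bit-reproducible under a fixed seed in single-threaded use.

## The segmentation chain

`segment_truss()` composes four deterministic steps:

1. **HSV gate.** Pixels are kept iff their (H, S, V) triple lies inside
   closed intervals, using the 0–179 hue convention (degrees halved) and
   0–255 saturation/value scales — the published gating ranges only make
   sense on that hue scale. Three development-stage presets ship verbatim
   as `a` (H 0–65, S 150–255, V 150–255), `b` (H 0–30, S 180–245,
   V 250–255) and `c` (H 0–30, S 248–255, V 240–255); `c`, the narrow
   saturated red band, is the default. Preset `b`'s odd value range is
   reproduced uncorrected.
2. **Otsu binarisation** of the luma (0.299 R + 0.587 G + 0.114 B) of the
   gated image, with gated-out pixels set to 0. The threshold maximises
   between-class variance over the 256-level histogram; among tied
   maximisers the lowest level is taken, and a constant image maps
   entirely to background. Luma-of-gated-image is the package's choice of
   the binarised channel; the chain's published description fixes only
   the order (gate, then binarise).
3. **Morphological cleanup**: closing with a 5×5 disc (larger than the
   erosion kernel, so fragments are net-filled), hole-filling of each
   component's external contour, then one erosion with a 3×3 box kernel
   to strip small noise objects. The 3×3/one-iteration erosion is fixed
   by the protocol; the closing kernel and the 25 px minimum component
   area are package defaults, both configurable.

The same chain is applied to true depth colormaps and to CycleGAN-converted
images, which is what makes the two-path comparison meaningful.

For ROC analysis the continuous score is the quantity the chain actually
thresholds — the luma of the HSV-gated image (`segmentation_scores()`) — so
the curve sweeps the pipeline's own decision axis.

## The synthetic scene generator

`generate_scene()` emulates the imaging regime the pipeline exploits, not
greenhouse photography. Each scene is a deterministic function of
(seed, index) and consists of:

* a **truss**: a quadratic-Bézier stem rising from the lower edge into an
  overlapping elliptical leaf canopy with occasional fruit, drawn in plant
  greens with per-pixel texture noise, at depths inside the near band;
* a **background**: a receding canopy wall plus elliptical clutter blobs
  (leaves, stems, pipes) in greens/browns at far-band depths;
* a **depth map** with per-pixel noise, and optionally a **defocus
  failure**: with probability `defocus_prob`, a contiguous blob of the
  depth map is invalidated and overwritten with far-range noise — the RGB
  image is unaffected, mimicking how close-range defocus corrupts only
  the depth stream.

Key parameters (all in `scene_config()`):

| parameter | default | meaning |
|---|---|---|
| `image_size` | 512 px | raster size; the network's native input size |
| `n_trusses` | 1 | near-camera structures per scene |
| `near_depth_range` | 0.4–0.9 m | camera-to-truss distance band |
| `far_depth_range` | 1.5–4.0 m | background distance band |
| `clutter_density` | 0.3 | background clutter coverage |
| `defocus_prob` | 0 | probability of a depth-dropout frame |

The depth bands reflect a platform imaging the truss at arm's length with
the far canopy a few meters behind; the clean separation between bands is
what a working depth camera delivers and what the red/blue gate assumes.
`render_depth_colormap()` maps depth through an explicit 256-entry
jet-like table (red at `near`, blue at `far`, invalid pixels black), as a
*fixed-range* colorizer: the mapping from meters to colour is constant
across frames, which is the assumption under which a fixed HSV gate is
meaningful. A dynamic-range colorizer would make the gate
distance-dependent.

What the generator deliberately does **not** model: photorealistic plant
texture, sunlight spectra, specular highlights, camera intrinsics, motion
blur, or occlusion of the truss by foreground objects. Tests passing on
these scenes therefore demonstrate that the pipeline's operators are
mutually consistent with the data regime they assume — near ⇒ red,
connected foreground, cluttered background — not that the trained model
transfers to real greenhouse imagery.

## Evaluation metrics

For one (prediction, truth) mask pair with confusion counts (tp, fp, fn):

* residual-ratio FN $= 100\,\mathrm{fn}/(\mathrm{tp}+\mathrm{fn})$ — the
  share of the actual ROI remaining after removing the predicted pixels;
* residual-ratio FP $= 100\,\mathrm{fp}/(\mathrm{tp}+\mathrm{fp})$ — the
  share of the prediction remaining after removing the actual ROI;
* mIoU $= 100\,\mathrm{tp}/(\mathrm{tp}+\mathrm{fp}+\mathrm{fn})$.

The two residual ratios use different denominators (actual ROI for FN,
predicted ROI for FP): each removal happens inside a different image, and
the ratio is taken relative to the image being removed from. Aggregates
are reported as mean ± sample (n−1) standard deviation; per-image values
that are undefined (empty truth for FN, empty prediction for FP, both
masks empty for mIoU) are excluded from aggregates rather than imputed,
and a single-image aggregate reports SD 0 with a degeneracy flag. AUC is
computed by trapezoidal integration of the tie-grouped ROC and equals the
Mann–Whitney pairwise statistic with ties counted half.

## Numerical choices and degenerate inputs

* Instance normalisation uses $\varepsilon = 10^{-5}$ inside the square
  root; weights initialise from $\mathcal{N}(0, 0.02^2)$.
* Training aborts with the iteration index if any loss component becomes
  non-finite; zero-iteration training is a no-op returning the
  initialised state.
* Converted images are de-normalised from tanh range and quantised to
  8-bit levels, so conversion is exactly reproducible through a PNG
  round-trip.
* All stochastic steps (scene synthesis, weight init, batch sampling) are
  driven by explicit seeds and leave the caller's RNG state untouched;
  scene `(seed, index)` pairs map to independent substreams.
* An all-background gate (e.g. an all-blue image) propagates through Otsu
  as a constant image and yields an empty mask rather than an error.

## Problem sizes

Full-scale operation uses 512×512 rasters, 64 base channels, 8 residual
blocks and training on the order of 10⁴ iterations. The test suite and the
acceptance script exercise the identical code paths at reduced scale —
64×64 rasters, 12 base channels, 3 residual blocks, batch 5, 400
iterations on 20 scenes, evaluated on 10 held-out scenes — chosen so that
a complete training run demonstrates both convergence of the cycle losses
and a translation good enough that the gate finds red truss pixels in
converted RGB, which untranslated RGB never contains. At this scale the
translated truss is coarse, so held-out mIoU is modest; the comparison
against the raw-RGB baseline, not the absolute value, is the meaningful
output.

## Known limitations

* The fixed HSV gate presumes a fixed camera-to-crop distance and a
  fixed-range colorizer; the method does not transfer to scenes where the
  target's distance varies freely.
* Sequential frames are converted and segmented independently
  (`scan_sequence()`); registration or stitching of overlapping frames is
  out of scope.
* The depth-to-RGB direction ($F$) exists to close the cycle; its outputs
  are not assessed beyond the cycle loss.
* The square generator input means oblong camera frames are
  aspect-distorted on resize.
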