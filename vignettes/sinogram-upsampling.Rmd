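---
title: "Angular upsampling of CT sinograms with a lightweight convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angular upsampling of CT sinograms with a lightweight convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinoup)
```

## The problem

Time-resolved (4D) X-ray micro-tomography captures each tomogram of a
series quickly, with few projections — typically 91 over a 180° sweep —
so that fast events (corrosion, bubble formation, material failure) are not
blurred. Reconstructions from so few angles are heavily undersampled:
noisy, streaked by ray artefacts, and hard to segment. A single *fully
sampled* tomogram (e.g. 3601 projections) is routinely collected at the
start or end of the series, when speed no longer matters.

`sinoup` uses that one fully sampled tomogram to learn how intermediate
projections look for this particular sample, and then predicts the
projections skipped in every undersampled tomogram of the series. Work
happens in *sinogram space*: for each sample height, the detector rows of
all projections are stacked into a θ × x image, and the θ axis (angle) is
upscaled 2× or 4×.

## The network

The mapping from an 11-row input patch `I` (rows spaced g apart in the
fully sampled sinogram) to the aggregated intermediate rows `O` is a
three-layer convolutional network with two rectified linear units:

* layer 1 — feature extraction: `n1` kernels of size 10 × 17, zero padding
  (4, 8), so each feature map already has the output's size
  (input height − 1, width preserved);
* layer 2 — non-linear mixing: `n2` kernels of 7 × 13, padding (3, 6);
* layer 3 — linear synthesis of the `N_out` output channels with 7 × 13
  kernels, padding (3, 6) and no rectifier.

`N_out` is the upscaling factor minus one: one output channel doubles the
projection count, three channels quadruple it, each channel predicting one
of the evenly spaced intermediate rows per gap. Named variants scale the
feature counts (64/32 base; 128/64; 32/16) or the kernel sizes (12 × 19,
9 × 15, 9 × 15 and 8 × 15, 5 × 11, 5 × 11); their paddings are solved from
the same shape contract. All layers are cross-correlations over
zero-padded inputs; since the kernels are learned, the orientation
convention is immaterial. `feature_scale` produces reduced analogues of
any variant for CPU-scale work.

Because the network is fully convolutional, width shifts of the sinogram
(e.g. rotation-axis drift between tomograms of a series) shift the output
correspondingly — translation equivariance up to a border band — and
arbitrary input heights ≥ the patch height are accepted at inference.

## Patch geometry

Training pairs are drawn from fully sampled sinograms as overlapping
windows of `g·(m−1)+1` rows (defaults g = 40, m = 11: 401 rows). The m
input rows sit at offsets 0, g, …, g·(m−1); target channel c holds the
m − 1 rows at offsets `g·j + c·g/(N_out+1)`. The stride-1 window starts
run over rows 1 … T − window (so a 3601-row sinogram yields exactly 3200
patches and the duplicated 180° row never starts a window). The spacing g
matches the angular gap of the undersampled acquisition — 91 of 3601 rows
is a 40:1 downsampling — so training and inference see the same geometry.

At inference an L-row undersampled sinogram is tiled into L − 10
overlapping 11-row windows; window predictions for the same inter-row gap
are averaged positionally (edge gaps average over fewer windows), and the
merged intermediate rows are interlaced with the input rows, giving
`(N_out+1)·(L−1)+1` rows — 91 → 181 (2×) → 361 (4×).

Each input window is min–max normalized to [0, 1] before the network and
the prediction is mapped back with the same affine parameters; targets are
transformed with the *input's* parameters during training so the learning
problem is expressed in the normalized frame. A constant window is flagged
degenerate and maps to zeros; its inverse restores the constant exactly.
Per-patch normalization is the default; it makes the learned mapping
invariant to the local intensity scale of real data.

## Training

The loss is the mean squared error over the predicted intermediate rows.
Optimization is Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8) with two learning
rate groups: layers 1–2 and layer 3, whose output every pixel is a linear
combination of feature vectors and which is therefore the most
error-sensitive. The schedule defaults to the classical starting rates
0.01 and 0.001 for the two groups. At the reduced, CPU-scale problem sizes
used throughout this package (detector widths of 32–256 pixels and
feature counts of 4–16 rather than 64–128), those rates are too aggressive:
the normalized-step optimizer drives the rectifier pre-activations
negative faster than the loss surface can recover them, the hidden layers
die, and training stalls at the bias-only solution. Desk-scale runs in the
tests and scripts therefore start both groups at 0.001; the 10:1 ratio of
the defaults is kept for full-scale geometry.

One training *iteration* draws one random patch from every training
sinogram, in freshly shuffled sinogram order, so no sinogram is revisited
before all others have been seen; patches are consumed in minibatches of
ten. After every 16 iterations the model is scored on a frozen validation
set (ten random patches per validation sinogram, drawn once with a
dedicated seed), a parameter snapshot is recorded, and a plateau rule
adjusts the rates: when the validation loss has not improved by at least
`min_improvement` (default 1 % relative) for `patience` (default 3)
consecutive validations, both rates are divided by ten. The 1 % threshold
operationalizes "the error trend has flattened": without it, microscopic
improvements postpone the decay indefinitely. Training stops after
`max_decays` decays or `max_iterations` iterations and returns the
best-validation snapshot. Sinograms of a tomogram are split alternately
(odd heights train, even heights validate) so both halves span the whole
sample.

## Synthetic data

The phantom simulator emulates a pin-corrosion experiment: a vertical
aluminium pin (cylinder, density 1), a half-ellipsoid droplet of salt
water resting on top (density 0.35), 3 gas bubbles (spheres of density
−0.25 *added inside* the droplet, i.e. less dense than their host; 3 in
training scenes, conventionally 4 in test scenes) and 40 small dense
ellipsoidal deposits inside the pin (density +0.4). Placements and radii
are uniform within their admissible regions; densities and radius ranges
are configurable defaults chosen to give line integrals of order 0.1–1
(they are not measurements). The projector is analytic: every
ray–primitive chord is solved in closed form, so projections are exact and
linear in the scene, and serve as their own oracle in tests.

Counting noise follows the transmission physics: expected counts
`I0·exp(−p)` with a Poisson draw, inverted by `−log(max(c,1)/I0)`; the
default incident flux is I0 = 10⁴ photons per pixel, a mid-range
synchrotron value giving ~1–2 % noise on the line integrals. Zero counts
are clamped to one before the logarithm.

The default desk-scale geometry is 64 heights × 721 angles × 256 detector
pixels. 721 angles downsample by 8 to exactly 91 rows — the same
undersampled row count as the full-scale experiment at a reduced ratio —
and upscale back to 181 (2×) and 361 (4×). Heights span the whole object
(the `height_range` of the geometry is decoupled from the detector pixel
size) so sinograms vary along the sample, as they do in real data.

What the simulator does *not* model: detector point spread, flat-field and
ring artefacts, continuous-rotation (fly-scan) blur, sample drift, and the
step changes that live events imprint on real sinograms. Passing the
package's tests therefore demonstrates the pipeline's correctness and the
expected method ordering on clean physics, not performance on any real
beamline dataset.

## Evaluation

Restoration quality is measured by PSNR (`10·log10(peak²/MSE)`, peak
defaulting to the ground-truth data range, since sinogram values are not
bounded by a bit depth) and by SSIM with the standard Gaussian-weighted
11 × 11 window (σ = 1.5, k₁ = 0.01, k₂ = 0.03, population covariance).
Scoring uses the *predicted intermediate rows only* — the copied input
rows are exact by construction and would inflate both metrics.

Reconstruction-space comparisons use a plain parallel-beam filtered back
projection: spatial-domain Ram–Lak filter applied in the frequency domain
with power-of-two padding, linear-interpolation backprojection, trapezoid
weighting of the duplicated 0°/180° pair, and an `NA` sentinel outside the
inscribed circular field of view. Both metrics exclude sentinel pixels
(PSNR pairwise, SSIM by dropping windows that touch one). This
reconstructor is deliberately simple; absolute reconstruction scores are
not comparable with GPU production toolchains, so only orderings and
trends across methods and projection counts are meaningful.

The cubic baseline interpolates each detector column independently along
θ (natural cubic spline by default; Forsythe–Malcolm–Moler and Catmull–Rom
flavours are available), evaluating factor − 1 equispaced positions per
gap and keeping the original rows bit-exactly. 1-D interpolation along θ
is chosen because only the θ axis is upscaled.

## Numerical choices

* All computation is in double precision (R's native numeric); HDF5
  tomograms and checkpoints are stored as 64-bit floats so write/read
  round trips are bit-exact, and TIFF previews are 32-bit float.
* Weights initialize from N(0, 0.001²) with zero biases — the convention
  of the super-resolution CNN lineage this architecture belongs to — under
  a fixed seed; biases share their layer's learning-rate group.
* Convolution is im2col + GEMM in C++ (batched across a minibatch);
  gradients are exact (verified against numerical differentiation) and
  wide inputs are processed in bounded-memory column chunks.
* A training iteration block is assembled per validation interval and cut
  into minibatches of ten, the final partial batch kept.
* Degenerate inputs: constant patches normalize to zeros with a flag;
  zero-count pixels clamp to one count; a zero-MSE PSNR reports `Inf`
  rather than an arbitrary cap.

## Problem sizes used in the bundled checks

The test-suite and the acceptance script run, by design, at desk scale:
the 64 × 721 × 256 phantom above; an 8/4-feature analogue of the 128/64
variant trained for ~1500 minibatch steps for the method-ordering
benchmark; a midpoint-recovery task (per-column affine ramps, for which
the exact interpolator lies inside the architecture) at width 32 trained
to validation MSE below 1e−4; and FBP trend comparisons at 91/181/361
projections. Full-scale dimensions (2160 × 3601 × 2560, 3.45 M training
patches) appear only in the counting identities, which are exact at any
scale.

## Known limitations

* The plateau rule is a deterministic stand-in for what is, in practice, a
  human decision about "the trend of the error"; its `min_improvement`
  and `patience` interact with the validation cadence.
* 4× upscaling trains a separate three-channel model; the package does not
  chain 2× models.
* The FBP reconstructor and the analytic projector assume ideal parallel
  beams and a centered rotation axis.
* Real-data effects listed under *Synthetic data* are out of the
  simulator's scope; on real tomograms the network's advantage over cubic
  interpolation must be re-established per experiment by retraining on
  that experiment's fully sampled tomogram.
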