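---
title: "Accelerated PAINT reconstruction: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated PAINT reconstruction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Single-molecule localization microscopy (SMLM) trades time for space: a
super-resolved image is accumulated from tens of thousands of camera frames,
each showing only a handful of spatially isolated emitters. PAINT imaging
with exchangeable protein labels (weak-affinity ligands binding a protein
tag such as HaloTag7) removes the photobleaching limit — unbound ligand in
solution constantly replenishes the signal — but the acquisition-time
problem remains. `hdpaint` implements the computational side of the
high-density acceleration strategy: record frames with *overlapping* PSFs
at roughly ten-fold higher emitter density, and recover emitter positions
with a convolutional encoder-decoder trained on semi-synthetic data built
from a low-density acquisition of the same label chemistry. Per structure,
a ~25-fold reduction in acquisition time is the operating point at which
the approach is intended to work (1,000 high-density frames replacing a
25,000-frame low-density acquisition).

Every stage of the chain is in the package, together with a PAINT
simulator that stands in for microscope data, so that the whole pipeline
can be exercised and tested end to end on a desktop CPU.

# The simulator (`generate_structure`, `sample_binding_events`, `render_frames`)

The simulator emulates the essential statistics of an exchangeable-label
PAINT acquisition:

* **Structures.** Filament bundles (smooth random curves), tubule-like
  curves with transverse spread, or node-edge networks, decorated with
  binding sites at a fixed arc-length spacing (default 10 nm). These
  caricature intermediate filaments, ER tubules and organelle networks;
  they are not morphological models of any specific protein.
* **Binding kinetics.** Event starts form a Poisson process whose rate is
  `density * area / mean_on_frames`; on-times are geometric with mean
  `mean_on_frames` (memoryless binding, the standard PAINT assumption; the
  label chemistry's true dwell times are not published, so the default of
  3 frames is a placeholder, not a fit). Sites can be re-bound arbitrarily
  often — exchangeable labels do not bleach — so the expected active
  density is constant over the whole acquisition. A warm-up period before
  frame 0 guarantees stationarity from the first frame.
* **Camera.** Photons deposit as pixel-integrated 2-D Gaussians
  (`psf_sigma_px`, default 1.3 px at 157 nm pixels). The EMCCD chain is
  the standard Poisson–gamma–Gaussian cascade: Poisson photoelectrons
  (quantum efficiency 0.9), gamma-distributed electron multiplication
  (shape = electrons, scale = EM gain 50), additive Gaussian read noise
  (60 e⁻ RMS at a 5 MHz readout), division by the sensitivity
  (12.5 e⁻/ADU), baseline offset 100 ADU, and 16-bit quantization. Only
  the gain settings are published operating values; QE, read noise and
  sensitivity are typical back-illuminated EMCCD data-sheet numbers.
* **Densities.** 0.109 emitters/µm² per frame is the low-density
  (ground-truth) regime; ~1.3 emitters/µm² the high-density regime. The
  mapping from ligand concentration (nM) to density is deliberately not
  modeled — it is chemistry-dependent — so densities are specified
  directly.

What the simulator does *not* model: 3-D PSFs and astigmatism, sCMOS
pixel-dependent noise, triplet states or any photophysics beyond binary
on/off binding, structured background, and optical aberrations. Tests that
pass on simulated data therefore demonstrate the correctness and internal
consistency of the algorithms, not microscope-grade performance on real
cells.

# Ground-truth localization (`localize_stack` and friends)

The low-density chain mirrors the conventional SMLM reconstruction
pipeline:

* **Detection** by the net-gradient criterion: a candidate is a strict
  local maximum whose summed inward gradient projection over a `box_px`
  box (default 7) exceeds a threshold (default 400 photon-units; a config
  value, as in practice it is tuned per dataset).
* **Fitting** by maximum likelihood for a pixel-integrated Gaussian under
  Poisson noise, with Fisher-scoring coordinate updates on
  (x, y, photons, background, sx, sy). Fits are retained when finite and
  inside the box; the convergence flag records whether the increments fell
  below tolerance. Localization precision (`lpx`, `lpy`) uses the
  Mortensen MLE formula with the EMCCD excess-noise factor 2 whenever the
  camera's EM gain exceeds 1. A Monte-Carlo test verifies that the fitter
  reaches within 20% of the bound at 5,000 photons.
* **Filtering** on closed intervals of sx, sy (default 0.6–2.0 px) and
  lpx, lpy (default ≤ 0.3 px). The exact cutoffs used in practice are
  dataset-dependent, so they are configuration, not constants.
* **NeNA** estimates the experimental localization precision from
  nearest-neighbor distances between consecutive-frame localizations,
  fitting the 2-D distance density `d/(2s²)·exp(−d²/(4s²))` (variance
  2 s² for two independent observations of precision s) plus a linear
  background term for unrelated neighbors.
* **Linking** merges transitive chains of localizations within a radius
  (conventionally 4× NeNA) and a maximum dark time of 5 consecutive
  frames, merging by photon-weighted mean position with summed photons.
  The merge statistic is a package choice; precision-weighted merging
  would be equally defensible.
* **RCC drift correction** renders temporal segments (default 200 frames),
  estimates all pairwise shifts by cross-correlation, solves the
  over-determined system by least squares and interpolates per frame.
  Sub-pixel shifts use local matrix-DFT upsampling of the correlation
  peak (step 0.02 px); 3-point parabolic interpolation was rejected
  because its peak-locking bias (~0.1 px) exceeded the accuracy target.
* **Raw-frame drift correction** estimates each frame's shift against the
  blurred stack mean. On transient-binding data single-frame estimates
  carry constellation noise (different emitters are on in each frame), so
  an optional temporal smoothing window is provided for slow drift.

Coordinates follow the Picasso convention everywhere: continuous, origin
at the corner of pixel (0, 0), x along columns, y along rows; tables carry
`frame, x, y, photons, bg, sx, sy, lpx, lpy`.

# Training data by patch summing (`extract_patches`, `sum_patches`)

High-density training data with exactly known emitter positions is
obtained by summing random low-density patches: `k_per_sum` 17 × 17 px
patches (drawn with replacement, at uniformly random frame and position)
are added pixel-wise and their localization lists concatenated. Emitter
counts and photons are conserved exactly, so the output density is
`k_per_sum` times the input density; the default `k_per_sum = 12` turns
0.109 emitters/µm² into ~1.3 emitters/µm². Labels are by default the
MLE-fitted positions — carrying their localization errors, exactly as when
the source data are experimental — with simulator truth available for
oracle tests. A global additive offset matches the patch background median
to a reference high-density acquisition (`background_stats`), so the
network sees prediction-like backgrounds at training time; a more refined
scheme (noise rescaling) was considered and left out because the additive
offset suffices to align the standardized input distributions. Patches are
center-cropped to 16 px at training time.

# The network (`build_model`, `train_model`, `predict_maps`)

A fully convolutional encoder-decoder predicts an upsampled
localization-density map from each frame:

* input bilinearly resized to the upsampled grid (factor 8 for live-cell,
  16 for fixed-cell work, giving 20 nm and 10 nm map pixels at 157 nm
  camera pixels);
* three encoder blocks (3×3 convolution, batch normalization, ReLU,
  2× max-pooling) with channel widths 4/8/16, mirrored by three
  nearest-upsample + convolution blocks, and a final 1×1 convolution with
  ReLU to one nonnegative channel. The widths are a desk-scale choice:
  they keep single-CPU training in minutes while retaining enough capacity
  for the spike-regression task (the overfit probe in the test suite
  drives the training loss down by more than an order of magnitude on a
  tiny patch set). The layer count and resize-first design follow the
  established density-map-regression architecture for this problem.
* Loss: MSE between Gaussian-blurred prediction and Gaussian-blurred label
  spike map (σ = 1 upsampled px) plus an L1 sparsity penalty
  (weight 0.01); labels carry amplitude 100 per emitter so gradients are
  well-scaled. Optimizer: Adam. Inputs are standardized by the training-set
  mean/σ, stored in the model and re-applied at prediction time.
* The fidelity configuration is `train_config()`: 30,000 patches,
  batch 256, 100 epochs, 15% validation split, initial learning rate 1e-5.
  The desk preset (`desk_preset()`: 2,000 patches, 20 epochs, batch 64)
  raises the learning rate to 5e-4 — chosen once, as roughly inverse to
  the ~20-fold schedule reduction — so the short schedule still reaches a
  useful optimum.
* Training and inference are implemented natively (C++/Armadillo) with
  exact backpropagation through the blurred-MSE loss, batch-norm and
  pooling; the 3×3 convolution layer is verified against a direct R
  implementation in the tests.

# Threshold calibration and extraction

Prediction maps are reduced to localizations by finding local maxima at or
above a threshold and taking the intensity-weighted centroid of a 3×3
neighborhood (local averaging), with the window mass as photon surrogate.
The threshold is not a free parameter: it is calibrated by monotone
bisection so that the total number of extracted localizations matches a
reference count derived from the ground-truth acquisition. In
`run_experiment` the reference is
`GT rows × (pred_frames × hd_density) / (gt_frames × gt_density)` — the
expected number of emitter instances in the predicted window estimated
from the GT table alone, which reduces to a plain frame-count ratio
whenever the two acquisitions share a density. The calibration tolerance
(2%) is the bisection stopping rule, not an accuracy claim about the
network.

# Image quality assessment (`imqual`)

For similarity metrics both images receive a 2-px Gaussian blur, min-max
scaling and 8-bit quantization (`preprocess_pair`); metrics are PCC, SSIM
(11×11 Gaussian window, σ 1.5, standard constants, dynamic range 255),
MS-SSIM (canonical 5-scale weights), MAE and PSNR. An optional structure
mask (Otsu threshold on the blurred ground truth, 3×3 closing) restricts
PCC/MAE to the labeled structure; masking is per-structure optional since
it matters most when large background areas would otherwise dominate the
statistics. The perceptual-similarity metric that requires pretrained
network weights is deliberately excluded.

Resolution uses decorrelation analysis: the correlation d(r) between an
image's Fourier transform and its phase-normalized, low-pass-masked
version, over 50 mask radii and 10 Gaussian high-pass pre-filters, with
`resolution = 2 × pixel / cutoff`. Two details matter in practice and are
deliberate choices here. First, the decorrelation input is the *raw*
rendered image, not the 8-bit preprocessed one — quantization noise is
spectrally white and would drag the cutoff to Nyquist. Second, peak
selection rejects maxima at the last radius (they arise from interpolation
replicas and noise floors) *unless* the curve rises monotonically through
its final quarter, the genuine signature of a flat spectrum; a white-noise
image therefore correctly reports information out to Nyquist, while a
noisy widefield image reports its structural cutoff. The cutoff is the
highest per-curve peak frequency across the filter family.

# Live-cell movies (`livemovie`)

Super-resolution videos are built from overlapping temporal windows
(default 400 frames, step 20; at 50 ms integration the step corresponds to
a 1 s temporal spacing). Each window's localizations are rendered on the
upsampled grid, clipped at the per-frame 99th intensity percentile,
normalized to [0, 1], mean-filtered (3×3; kernel size is a package
default, chosen as the smallest neighborhood that suppresses isolated
single-localization pixels) and smoothed with a 1.5-px Gaussian. The step
(not the overlap) is 20 frames: only that reading reproduces the 1 s
spacing at 50 ms integration, so it is adopted despite the ambiguity
between the two published phrasings. Frames are written as a PNG sequence
with a JSON sidecar of timestamps (`start × integration time`); an MP4 is
encoded when an encoder is available on the PATH.

# Desk-scale experiment sizes

`run_experiment()` defaults define the end-to-end rehearsal used by the
tests and the acceptance script: a 7.5 µm filament field (48 px at
157 nm), a 5,000-frame GT acquisition at 0.109 emitters/µm², a 1,000-frame
HD acquisition at 1.3 emitters/µm², 2,000 summed training patches, 20
epochs at upsampling 8, and prediction of 400 HD frames. These sizes were
chosen once as the smallest configuration at which the pipeline's
qualitative claims (prediction beats the widefield image in correlation to
the GT render and in decorrelation resolution) are comfortably
reproducible on a single CPU; the full-scale settings remain available
through `train_config()`.

# Numerical and degenerate-input conventions

* All randomness flows through explicit integer seeds; each pipeline stage
  derives a fixed offset from the experiment's master seed, so any stage
  can be reproduced in isolation.
* Empty structures, empty windows, all-zero frames and empty tables pass
  through as empty results (or a warning) rather than errors wherever a
  downstream consumer has a sensible interpretation; violated geometry
  (labels outside a patch, trajectory length mismatches, unknown
  configuration keys) errors immediately.
* Ties in local-maximum detection are broken toward the first pixel in
  column-major order, making extraction deterministic.
* PSNR of identical images is reported as `Inf` rather than an arbitrary
  cap.

# Known limitations

* The network is a compact CPU-trainable variant; with GPU-scale widths
  and the 30,000-patch/100-epoch schedule the reconstruction quality would
  improve, and nothing in the code limits those settings.
* Single-emitter MLE deliberately does not handle overlapping PSFs; at
  0.109 emitters/µm² on filaments, a minority of localizations come from
  multi-emitter clusters and carry elevated widths (they are largely
  removed by the sx/sy filter). Overlap is the network's job.
* Raw-frame drift estimation on transient-binding data is noisy per frame
  (~0.2 px on the simulated conditions); it is adequate for the slow,
  smooth drifts it is meant to remove.
* The decorrelation implementation follows the published algorithm's
  structure (radius family, high-pass family, peak logic) but is not a
  line-by-line port of any reference code; absolute resolution numbers on
  real data may differ slightly from other implementations.
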