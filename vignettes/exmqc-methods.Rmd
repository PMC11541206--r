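---
title: "Methods and design of the exmqc validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the exmqc validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`exmqc` quantifies how well an expansion-microscopy (ExM) experiment
performed: how much the gel expanded, what effective resolution the
expanded images carry, how much the expansion distorted distances, and
whether canonical nanoscale structures (microtubule sidewalls, nuclear
pore rings, synaptic nanocolumns) come out with the right geometry. This
vignette records the models behind each stage, the parameters that
matter, and the design decisions taken where the methods literature
leaves choices open.

## Units and the image model

All quantities are reported in **biological units**: physical distance at
the detector divided by the linear expansion factor. An `image_stack`
carries per-axis physical pixel sizes and the expansion factor; every
estimator converts through `bio_pixel_size()` so a stack recorded at
104 nm pixels under 20× expansion is analyzed on a 5.2 nm grid. A
property test verifies that multiplying the pixel size and the expansion
factor by a common constant leaves every nm-valued estimate unchanged.

Voxel `(i, j, k)` (1-based) has its center at `(i-1) * pixel_size`; all
subpixel sampling is bilinear on that grid.

## The phantom generator

Each analysis is validated by parameter recovery on synthetic phantoms
with exact ground truth. The generator emulates:

* **Microtubules** — pairs of parallel line sources (the immunolabeled
  sidewalls) at a chosen separation, rendered analytically as transverse
  Gaussians with erf-smoothed end caps.
* **NPC rings** — eight point emitters equally spaced on a circle, each
  present with a per-slot labeling probability, with a random ring phase.
* **Synapse pairs** — two-channel 3D volumes: disc-like cluster envelopes
  separated by a cleft along a random axis, containing Gaussian hotspots
  ("nanodomains") of chosen FWHM; measured-channel hotspots are offset
  laterally by a controllable trans-synaptic offset. The envelope is
  `"soft"` (Gaussian falloff, realistic for segmentation tests) or
  `"uniform"` (sharp ellipsoid rendered without PSF blur, the exact
  degenerate case whose autocorrelation baseline is 1).
* **Warp pairs** — a texture-rich random-emitter image resampled through
  a smooth random displacement field (Gaussian-filtered white noise
  rescaled to an exact RMS amplitude), with the field stored as truth.
* **FRC pairs** — two realizations sharing one clean signal and
  differing only in noise.

Design choices, fixed once:

* The PSF is an **isotropic Gaussian**, the standard confocal
  approximation; default σ = 15 nm in biological units (≈ a 300 nm
  optical σ divided by a 20× expansion factor).
* Emitters are rendered by **analytic evaluation** of the blurred model
  on the grid, not by binning point masses and convolving, which would
  alias at 2–5 nm pixels. Total intensity therefore equals emitter count
  × PSF integral to 1e-6, which a conservation test asserts.
* Noise is either additive Gaussian with a **peak-signal-to-noise ratio**
  (`sd = peak/snr`) or Poisson with a chosen peak count. Defaults used in
  recovery tests: SNR 10 (Gaussian) or 200 peak counts (Poisson) —
  bright-confocal conditions.
* One integer seed fully determines a phantom; per-structure RNG streams
  are split deterministically, so outputs are bit-reproducible.

What the phantoms do **not** emulate: vectorial/depth-dependent PSFs,
antibody linkage error, label stochasticity beyond per-corner Bernoulli
dropout, gel polymer mechanics, and spatially varying backgrounds. A
green recovery suite therefore demonstrates correctness of the
*estimators*, not robustness to every real-data pathology.

## Expansion factor and preprocessing

`expansion_factor_from_landmarks()` forms all pairwise distances within a
matched landmark set and reports the mean ± s.d. of post/pre ratios; the
estimate is invariant to rigid motion of either set, which is tested.

`preprocess()` chains rolling-ball background subtraction → optional
Gaussian smoothing → optional maximum z-projection (the conventional
order). Rolling-ball is implemented as grayscale **opening with a flat
disc** of the stated radius (default 50 px): EBImage morphology operates
on [0, 1], and opening commutes with affine intensity maps, so the image
is normalized, opened, and mapped back — exact, not approximate. A
brute-force min/max-loop oracle in the test suite pins the behavior;
bit-parity with any particular GUI implementation is not promised.
Output is clamped at 0.

## Microtubule sidewall profiles

A `profile_box` centers a sampling rectangle on the structure with its
long axis transverse to it; intensities are bilinearly sampled, averaged
across the 185 nm box width (the conventional averaging window,
configurable), and normalized to peak 1. Sample grids are constructed
symmetric about the box center regardless of step size, so a symmetric
structure yields a symmetric profile.

`fit_double_gaussian()` fits `a₁G(μ₁,σ₁) + a₂G(μ₂,σ₂) + b` by
Levenberg–Marquardt (minpack.lm). Initialization: the two highest local
maxima of the lightly smoothed profile; σ starts at 10 nm (PSF scale);
σ is bounded in [2 nm, box length/2]. Failures — optimizer errors or
peak collapse below one sample spacing — set `converged = FALSE` rather
than raising, so population runs never abort. Peak-to-peak distance is
invariant to affine intensity changes (tested), and a Monte-Carlo test
shows the mean recovered separation is unbiased within 1 nm at 5%
profile noise.

## FRC resolution

`frc_curve()` computes the ring-normalized Fourier cross-correlation on
Hann-apodized inputs; apodization is required because image blocks are
not periodic, and an exact-invariance test (common circular whole-pixel
shift, unwindowed) separates the windowing from the statistic itself.
Rings are one frequency pixel wide. `frc_resolution()` takes the first
downward crossing of the fixed **1/7 threshold** (the standard
convention; configurable), locates it by linear interpolation, optionally
after a 3-ring moving average (the raw curve is always retained), and
floors the result at the 2-pixel Nyquist limit. `blockwise_frc()` tiles
the pair (default 128 px blocks, 50% overlap), marks blocks whose curve
never crosses as invalid, and reports the mean and the median of valid
blocks — both, since either may be quoted as "global". Identical inputs
produce an all-invalid map pinned at Nyquist with a warning, not an
error. The resolution estimate is validated against an analytic spectral
oracle (expected FRC assembled from the noiseless signal spectrum plus
the known noise power) within 20%.

## Distortion analysis

`rigid_register()` replaces the interactive rigid-body step of the
classical workflow: the post image is resampled into the pre frame using
the expansion factors, phase correlation initializes the translation, and
Nelder–Mead maximizes normalized cross-correlation over translation,
rotation, and residual isotropic scale (the recovered scale is itself an
expansion-factor estimate). Correlation below a floor raises an explicit
registration error.

`nonrigid_register()` estimates the residual smooth displacement field by
**multiresolution block matching**: after Gaussian presmoothing (σ = 4 px
by default, the conventional preprocessing), control nodes on a 32 → 16 →
8 px coarse-to-fine grid are matched by windowed NCC with subpixel
quadratic refinement; node displacements are interpolated bilinearly and
Gaussian-regularized (σ = spacing/3). This was chosen over a B-spline
free-form-deformation optimizer as a deliberate design decision: block
matching with smoothing recovers the phantom warp fields to the same
accuracy (RMS within 25% of truth, pointwise correlation > 0.8, identity
residual < 0.1 px — all asserted in tests) at a small, predictable
computational cost in pure R, and has no inner optimization that can
silently diverge. The field maps post-aligned coordinates to pre
coordinates, matching the phantom truth convention.

`rms_error_curve()` samples, per measurement length L (default
log-spaced 100 nm–10 µm), point pairs at exactly distance L uniformly
inside the valid region (rejection sampling, seeded), and aggregates
`|q+u(q) − p−u(p)| − L`. It is gauge invariant (a constant field shifts
nothing), exactly zero for identity warps, and matches the closed-form
small-L limit `L·a·k·sqrt(3/16)` on a sinusoidal test field within 10%.

## Synaptic nanocolumn statistics

`segment_synapses()` thresholds at `k_sigma` (default 7) × the background
s.d. and labels 26-connected 3D components (via the foreground adjacency
graph). Background statistics come from a user mask when given; the
automatic fallback samples every 10th z-slice and uses the **MAD** rather
than the raw s.d., since the sampled slices inevitably contain some
structure and a truncated-tail s.d. underestimates the noise (which
inflates false components at 7σ).

`autocorrelation_ga()` computes the shell-binned pair correlation of the
masked intensities, divided by the same computation on a same-shape
uniform object — algebraically, shell-averaged `E[I_i I_j]` divided by
`mean(I)²` — so support geometry cancels and a uniform cluster sits at
exactly 1. The implementation is FFT-based with explicit pair-count
normalization on a zero-padded bounding box; an exhaustive double-loop
oracle pins it to 1e-6 on small ROIs, including anisotropic voxel sizes
(distances are always in nm). Shell width defaults to 5 nm; shells with
no voxel pairs are `NA`, never silently zero. The per-cluster intensity
peak is the argmax after a 3-voxel median filter, suppressing single-voxel
noise spikes.

`nanodomain_size()` reads the hotspot size off the radius where the decay
of g_a(r) stops. "Flat" is judged with a slope threshold **normalized to
the curve's excess above baseline** (default 0.01 per nm per unit
excess), evaluated beyond the steepest-descent point of the 3-bin-smoothed
curve. The normalization is the key design choice: an absolute slope
tolerance makes the flattening radius grow with hotspot brightness (the
slope of a Gaussian-hotspot curve scales with its amplitude), whereas the
normalized criterion lands at the hotspot's PSF-broadened FWHM regardless
of contrast — verified on analytic curves with a 4× contrast difference.
Uniform clusters (excess < 0.05) and curves that never flatten in range
return `defined = FALSE`. Note a structural limitation, visible on
phantoms: when probed radii are comparable to the cluster size, the
pair-support geometry itself adds a slowly varying trend to g_a(r)
(centrally placed hotspots keep contributing while the pair count
shrinks), and the flattening radius can then be undefined within range.
This is intrinsic to the statistic, not to the implementation.

`cross_enrichment()` averages the measured cluster's intensity in shells
around the reference cluster's peak and divides by the uniform-surrogate
baseline (the cluster mean). Both g_a and enrichment are invariant to
affine intensity rescaling of their channel, and both directions (A→B
peak, B→A peak) are supported. `snr()` divides mean ROI intensity by the
background standard deviation. Cross-channel cluster pairing is
automated as mutual-nearest centroids within 500 nm, standing in for
manual identification of juxtaposed pairs; a manual pair list can always
be substituted.

## NPC quantification

`radial_profile_radius()` refines the center by three rounds of
intensity-weighted centroid-of-annulus iteration, azimuthally averages
intensity into annuli one pixel wide, and returns the
parabolic-interpolated profile peak. A monotone profile (e.g. a point
source) raises a no-ring error.

One bias deserves emphasis: the azimuthal *mean* of a ring of radius R
blurred by an isotropic Gaussian is `f(r) ∝ exp(-(r²+R²)/2σ²)·I₀(rR/σ²)`,
whose peak sits **below** R by roughly `σ²`-order terms — for R = 53.5 nm
and σ = 15 nm the analytic peak is ≈ 51.3 nm, and the pipeline measures
exactly that on phantoms (51.2 ± noise), while at σ = 5 nm the bias
shrinks to ≈ 0.2 nm. The estimator is kept as the field uses it (the
peak, uncorrected): correcting would require assuming a PSF width that is
unknown on real data, and the bias is part of the method's reported
behavior, not an implementation artifact.

`count_corners()` integrates the annulus from `α·R` to `R/α`
(α = 0.93) and divides it into eight sectors. The sector phase is set
from the **8th circular harmonic** of the annulus' azimuthal intensity
profile, so sector centers land on the eightfold corner lattice. This
replaces a scan over phase offsets maximizing the above-threshold sector
count, which is subtly wrong: such a scan prefers phases that split a
bright corner across a boundary so that *two* sectors clear the
threshold, and partially labeled phantom rings were counted as fully
labeled. The harmonic alignment is deterministic, rotation invariant (16
rotations tested), and never double-counts. A sector is a corner when its
peak intensity, normalized to the annulus maximum, exceeds 0.6; the count
is monotone non-increasing in that threshold.

`corner_distances()` draws a line profile through each adjacent pair of
detected corners — the corner directions refined from the azimuthal
profile, emulating a line selection through the visible corners — and
measures the two-peak distance with the same double-Gaussian fit as the
microtubule analysis. `npc_population_report()` applies the standard
top-view selection rule (≥ 4 visible corners) to radius statistics while
keeping every ring in the corner-count histogram.

## Problem sizes and reproducibility

The recovery benchmarks run at the scale the statistics need and no
larger: 50 noise seeds for the NPC radius (single rings at 2 nm pixels),
100 fully labeled NPCs (≈ 790 adjacent-corner fits) for the corner
spacing, and 100 microtubule segments for the sidewall mean; property
tests use ≤ 12³-voxel ROIs where exhaustive pair enumeration is exact.
`scripts/acceptance.R --seed N` derives every phantom seed from N, so
outputs are exactly reproducible. Registration tests run on 192–256 px
images — large enough for three pyramid levels, small enough to keep the
suite fast.

## Known limitations

* I/O is plain TIFF with a JSON calibration sidecar; OME-XML metadata is
  read nowhere and written nowhere, and proprietary microscope formats
  are out of scope.
* Nonrigid registration is 2D (z-stacks are handled by orthogonal
  projection before registration, per the standard workflow); fully
  volumetric registration is out of scope.
* The radial-profile radius estimator carries the convolution bias
  described above; users comparing against structural references should
  budget for it when the PSF is a substantial fraction of the ring
  radius.
* The randomized-shift null model sometimes used alongside enrichment
  analysis is not implemented; curves are normalized by the
  uniform-surrogate baseline only.
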