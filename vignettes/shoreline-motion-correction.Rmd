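---
title: "Leave-one-out q-space prediction for dMRI head-motion correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leave-one-out q-space prediction for dMRI head-motion correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A diffusion-weighted MRI (dMRI) session acquires tens to hundreds of 3-D
volumes, each sensitized to water diffusion along a different direction and
strength (the b-value, s/mm^2). Head motion between volumes misaligns the
series, and the usual fMRI remedy — register everything to one reference
volume — fails because diffusion weighting changes the image contrast
drastically from volume to volume: a b = 0 volume looks nothing like a
b = 3000 volume, and two high-b volumes with different gradient directions
highlight different structures.

The correction strategy implemented here (the SHORELine scheme) sidesteps the
contrast problem by *synthesizing* a registration target for every volume.
The diffusion signal is a smooth function of the q-space encoding vector
`q = sqrt(b) u`, so a basis fit over all *other* volumes can predict what the
left-out volume should look like if it were aligned — and the observed volume
is then rigidly registered to its own prediction. Because the 3dSHORE basis
is defined on all of R^3 rather than on spherical shells, the approach covers
multi-shell, Cartesian-grid (DSI) and sparse random Cartesian (CS-DSI)
sampling schemes alike; the only structural requirement is at least two
distinct nonzero b-values.

## The signal model

The 3dSHORE basis expands the normalized signal `E(q) = S(q) / S(0)` in
radial generalized-Laguerre-Gaussian functions times real spherical
harmonics of even order:

    phi_nlm(q) = kappa(zeta, n, l) * (q^2/zeta)^(l/2) * exp(-q^2 / (2 zeta))
                 * L_{n-l}^{l+1/2}(q^2/zeta) * Y_lm(u)

with even `l <= N` and `l <= n <= (N + l)/2` for radial order `N` — 50 basis
functions at the default `N = 6`. Per voxel the coefficients solve a ridge
problem, `argmin |Phi c - s|^2 + lambda' |Gamma c|^2`, in closed form through
one Cholesky factorization shared across voxels.

Parameters that matter:

* **`zeta`** (b-value units under the package's `q = sqrt(b) u` convention)
  sets the radial decay scale. It is estimated per series by fitting a
  mono-exponential to the per-volume mean attenuations and applying
  `zeta = 1/(2 MD)`; with a typical mean diffusivity of 0.7-1.0e-3 mm^2/s
  this lands near the conventional value of ~700.
* **`lambda`** (relative to the mean diagonal of `Phi'Phi`, default 5e-2 in
  the correction loop, 1e-8 in the standalone fit). Leave-one-out targets are
  predictions at an *unsampled* q-point from as few as 54 noisy samples, and
  need visibly more shrinkage than an interpolating fit.
* **`angular_weight`** (default 0.01 in the correction loop) rescales the
  diagonal penalty by `1 + angular_weight * (l(l+1))^2`, a Laplace-Beltrami
  style weighting: high angular orders are damped most, which stabilizes the
  near-square fits on sparse schemes without giving up order-6 angular
  resolution where the data supports it. With an unweighted identity penalty
  a 55-direction fit must drop to radial order 4, and the resulting angular
  over-smoothing makes predicted high-b volumes systematically rotatable —
  registration then "improves" on truth by a few degrees.
* The fit is anchored at `q = 0` by including the mean b = 0 image as a
  design row. Without the anchor, schemes with sparse low-b coverage (the
  Cartesian grids sample few points with `|q-index| <= 1`) let the Laguerre
  radial polynomials extrapolate freely toward the origin, which can invert
  the predicted contrast of low-b volumes.

## Registration

Each volume is aligned with a rigid (optionally affine) transform maximizing
normalized cross-correlation over the brain mask, by regular-step gradient
descent on a 3-level Gaussian pyramid followed by a restarted Nelder-Mead
refinement at full resolution (fixed-step descent stalls in the shallow,
curved NCC valley near the optimum). Parameters are `(tx, ty, tz)` mm and
`(rx, ry, rz)` degrees, extrinsic X-Y-Z Euler angles about the volume center
— the same convention the motion simulator uses, so estimated and true
parameters compare directly, pivot and all.

Numerical choices worth knowing about:

* **Sample-lattice jitter.** The metric is evaluated at mask voxel centers
  perturbed by a fixed, seeded sub-voxel offset, and *both* images are read
  through trilinear interpolation. Sampling the moving image on the integer
  grid would make grid-aligned poses interpolation-blur-free and every other
  pose slightly blurred, a bias that pushes unmoved volumes off their correct
  identity transform.
* **Metric smoothing** (`metric_sigma`): both images are smoothed identically
  before the metric. The default is 1.0 voxel; the correction loop uses 0.5
  for the b > 0 target registrations, where heavier smoothing lets residual
  basis-misfit structure in the sharp high-b volumes dominate the matched
  fine detail.
* **Overlap guard and search bound.** Candidate poses that throw most of the
  mask out of the field return the worst metric value, and a soft quadratic
  penalty beyond `bound` (default 10 mm/degrees) keeps estimates local for
  volumes that carry little registration information; head motion inside a
  scanner coil cannot be arbitrarily large. The optimizer also never returns
  a pose whose finest-level metric is worse than its initialization.
* Masks are Otsu thresholds on the mean b = 0 plus one morphological
  closing, dilated by one voxel when the fixed image is a real acquisition
  (the object boundary is a strong rigid-body cue) but not when it is a
  synthetic prediction, which is undefined outside the mask.

## The correction loop

```{r}
library(dwimotion)
scheme <- make_scheme("HASC55")
truth  <- sample_motion(length(scheme), prevalence = 0.30, seed = 1)
series <- simulate_series(phantom_spec(), scheme, truth, snr = 20, seed = 1)
corr   <- shoreline_correct(series, model = "rigid", iterations = 2)
motion_error(corr$motion, truth)
```

Step by step: (1) all b = 0 volumes are registered to the first b = 0 volume
and re-anchored to the *consensus* frame — the componentwise median transform
of the largest cluster of mutually-agreeing b = 0 transforms. The first
volume is an arbitrary choice of reference and may itself have moved; the
consensus cluster is the unmoved majority, and anchoring there makes
estimated per-volume transforms directly comparable to simulated truth. A
second registration pass against the resulting mean b = 0 tightens the
reference. (2) Every b > 0 volume is registered to its leave-one-out 3dSHORE
prediction, built from all other volumes resampled with their current
transforms and normalized by a lightly smoothed (0.75 voxel) b = 0 reference
— smoothing matters because the reference's noise otherwise imprints a
common pattern on every target. (3) One optional second pass rebuilds the
targets from the round-1 alignments and refits; this is the point of
iterating, rather than reusing stale targets. (4) Each original volume is
resampled exactly once with its final transform.

## The phantom

`phantom_spec()` defines an analytic object — an ellipsoidal head with a
free-water rim, five cylindrical fiber bundles with spread orientations and
offsets, axially-symmetric compartment tensors (axial diffusivity 1.4e-3,
radial 0.3e-3 mm^2/s; the voxel-scale anisotropy of coherent but dispersed
white matter, not of a single axon), and a deterministic low-frequency
multiplicative texture on the b = 0 intensity. Motion is injected by
transforming this *continuous* object before each volume is sampled onto the
fixed 32^3 grid of 2 mm voxels: rendered volumes carry no interpolation
signature a correction algorithm could exploit, and volumes with identity
parameters are bit-identical between a motion-corrupted and a clean
simulation under the same seed. Rician noise is applied per volume
(`sigma = S0_tissue / snr`).

Design choices, and what they emulate:

* The **texture** stands in for anatomical contrast: registration in real
  brains is driven by intensity gradients everywhere, and a piecewise-
  constant phantom degenerates NCC to a thin boundary-shell comparison. The
  texture mixes incommensurate wavelengths (~12-26 mm) across axes so no
  rigid rotation maps it onto itself.
* **Five bundles** rather than one or two: a lone cylinder is symmetric about
  its own axis, so any volume in which only one bundle is visible would leave
  one rotation axis unconstrained — a phantom pathology, not a property of
  brains.
* The default grid (32^3) and the simulation scale used by the tests and the
  acceptance script (about ten corrected series per check) keep a full
  correction of a 55-direction series under a minute; they are the package's
  deliberate desk-scale working point.

What the phantom does *not* emulate: k-space artifacts (ghosting, eddy-
current warps, susceptibility distortion), intra-volume (slice-wise) motion,
slice dropout, spatially varying coil sensitivity, and real anatomical
complexity. Passing tests on this phantom demonstrate the estimator's
geometric correctness and noise behavior, not robustness to artifacts.

## Quality metrics

* `motion_error()` decomposes the residual `T_est o T_true^-1` per volume
  into the six parameters and pools signed per-axis errors over axes and
  volumes: the mean signed error measures bias, the RMSE its magnitude,
  translation and rotation separately. Pooling per axis (rather than taking
  displacement norms) is a documented convention; both per-axis tables and
  pooled scalars are returned.
* `ndc()` is the neighboring-DWI correlation: the mean in-mask Pearson
  correlation between each b > 0 volume and the volume sampling the closest
  q-space point under antipodal identification (the magnitude signal is
  antipodally symmetric, so opposite-hemisphere duplicates are true
  neighbors). Noise and misalignment both lower it.
* `estimate_fwhm()` is the classic Gaussian-random-field smoothness
  estimator from in-mask first differences. On pure white noise the
  difference variance can reach twice the value variance and the estimator
  is then undefined — reported as `Inf` with a warning, meaning "no
  detectable smoothness", not an error in the data.

## MP-PCA denoising

`denoise_mppca()` implements patchwise Marchenko-Pastur PCA: for every
sliding 5^3 patch the volume-centered Casorati matrix is eigen-decomposed,
the largest set of trailing eigenvalues whose spread fits the MP bulk edge
for the matrix aspect ratio is classified as noise (their mean gives the
local sigma^2), and only supra-cutoff components are kept. Overlapping patch
reconstructions are averaged uniformly — a deliberate simplification of the
reference implementation's nonlocal weighting.

## Known limitations

* Gradient directions are not rotated after alignment ("bvec rotation"); at
  the simulated motion range (<= 5 degrees) the induced signal error is well
  below the noise floor, but the corrected gradient table would need this
  step for downstream model fitting on strongly rotated data.
* On sparse schemes a handful of extreme-attenuation volumes have genuinely
  low-information targets; their estimates are kept local by the search
  bound rather than made accurate. This is why a motion-free, noiseless
  series yields median estimated parameters near zero but worst-case
  rotations of a degree or two — the leave-one-out prediction is a model,
  not an oracle.
* Eddy-current and susceptibility distortion correction, slice-to-volume
  alignment, and slice-dropout imputation are out of scope.
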