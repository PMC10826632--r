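# dwimotion

Head-motion correction for diffusion-weighted MRI (dMRI) on arbitrary
q-space sampling schemes, with a ground-truth motion simulator and the
quality metrics needed to benchmark correction accuracy.

## Why

A dMRI series is a stack of 3-D volumes whose contrast changes with the
diffusion encoding (b-value in s/mm², gradient direction **u**), so head
motion between volumes cannot be corrected by registering everything to a
single reference image — a b = 3000 volume simply does not look like a
b = 0 volume. The method implemented here (the SHORELine scheme) builds a
*synthetic* registration target for every diffusion-weighted volume: the
3dSHORE basis — radial Laguerre–Gaussian functions times even-order real
spherical harmonics over q-space, `q = √b·u` — is fit with L2
regularization to all *other* volumes, per voxel,

  c = argmin ‖Φc − s‖² + λ‖Γc‖²,

and the predicted signal at the left-out q-point becomes the fixed image for
a rigid (6-DOF) or affine (12-DOF) registration of the observed volume. The
loop runs up to twice, rebuilding targets from the first round's alignments,
and resamples each volume exactly once. Because the basis lives on all of
R³, shelled, Cartesian-grid (DSI) and sparse random Cartesian (CS-DSI)
schemes are all supported; only two distinct nonzero b-values are required.

The package also provides:

* `make_scheme()` — the four benchmark sampling schemes (ABCD- and HCP-style
  multi-shell, DSIQ5 Cartesian half-sphere grid, HASC55 sparse random
  Cartesian), plus FSL bval/bvec I/O;
* `phantom_spec()` / `simulate_series()` — an analytic multi-tensor head
  phantom whose *continuous* geometry is rigidly transformed before each
  volume is rendered (object moves, grid fixed), with per-volume ground-truth
  transforms and Rician noise;
* `denoise_mppca()` — Marchenko–Pastur PCA denoising;
* `motion_error()`, `ndc()`, `estimate_fwhm()` — motion-parameter error
  summaries, the neighboring-DWI correlation, and Gaussian-field smoothness;
* `build_full_plan()` / `run_benchmark()` — the full factorial benchmark
  design (4 schemes × algorithms × denoising × 3 motion-prevalence levels ×
  30 replicates) and a desk-scale executor for its SHORELine rows.

## Worked example

Simulate a 55-direction CS-DSI series (32³ voxels, 2 mm) in which 30% of the
volumes carry a random rigid movement of up to ±5 mm / ±5°, correct it, and
score the estimate against the simulated truth:

```r
library(dwimotion)
scheme <- make_scheme("HASC55")
truth  <- sample_motion(length(scheme), prevalence = 0.30, seed = 1)
series <- simulate_series(phantom_spec(), scheme, truth, snr = 20, seed = 1)
corr   <- shoreline_correct(series, model = "rigid", iterations = 2)
motion_error(corr$motion, truth)
#> translation: mean error -0.0586 mm, RMSE 0.5020 mm
#> rotation:    mean error +0.1836 deg, RMSE 1.8928 deg
ndc(series, corr$mask)       # 0.422  raw, motion-corrupted
ndc(corr$series, corr$mask)  # 0.639  after correction
```

The mean errors measure estimator bias (here a few hundredths of a
millimeter / a fraction of a degree — the estimator is essentially
unbiased), the RMSEs its typical magnitude (here a quarter of a voxel and
under two degrees at a per-volume SNR that is deliberately low). The
neighboring-DWI correlation rises after correction because adjacent q-space
samples become spatially consistent again.

A thin command-line wrapper over the same functions ships at
`inst/cli/dwimotion` (`simulate`, `denoise`, `correct`, `metrics`,
`benchmark` subcommands).

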