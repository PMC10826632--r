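#' Define a parametric multi-tensor phantom
#'
#' The phantom is an analytic object model: an ellipsoidal "head" with a free-
#' water (CSF-like) rim, containing straight cylindrical fiber bundles whose
#' compartments are axially symmetric diffusion tensors. Because the geometry
#' is continuous, simulated head motion transforms the object itself before
#' any voxel grid is sampled, so rendered volumes carry no interpolation
#' signature.
#'
#' @param dim Grid shape in voxels (length 3).
#' @param voxel_size Isotropic voxel edge length (mm).
#' @param head_radii Ellipsoid semi-axes of the head (mm).
#' @param head_center Center of the head in world coordinates (mm); the voxel
#'   grid is centered on the world origin.
#' @param rim Thickness of the free-water rim (mm).
#' @param bundles List of bundles, each `list(axis =, radius =, fraction =)`
#'   with an optional `offset` (mm): a cylinder along the unit vector `axis`
#'   through `head_center + offset`, with the given radius (mm) and
#'   intra-voxel volume fraction.
#' @param ad,rd Axial / radial diffusivity of the fiber compartment (mm^2/s).
#' @param d_tissue Isotropic diffusivity of non-fiber tissue (mm^2/s).
#' @param d_csf Free-water diffusivity in the rim (mm^2/s).
#' @param S0_tissue,S0_bundle,S0_csf Unweighted (b=0) intensities.
#' @param texture Amplitude of the deterministic low-frequency multiplicative
#'   S0 texture (0 disables it). The texture belongs to the continuous object
#'   model — it rotates and translates with the head — and gives rendered
#'   volumes the pervasive intensity gradients that drive image registration
#'   in real anatomy.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(32L, 32L, 32L),
                         voxel_size = 2,
                         head_radii = c(22, 19, 16),
                         head_center = c(0, 0, 0),
                         rim = 3,
                         bundles = default_bundles(),
                         ad = 1.4e-3, rd = 0.3e-3,
                         d_tissue = 0.8e-3, d_csf = 3.0e-3,
                         S0_tissue = 800, S0_bundle = 900, S0_csf = 1000,
                         texture = 0.08) {
  stopifnot(length(dim) == 3, all(dim >= 4), voxel_size > 0,
            all(head_radii > 0), rim >= 0,
            ad > 0, rd > 0, ad >= rd, d_tissue > 0, d_csf > 0)
  for (b in bundles) {
    stopifnot(length(b$axis) == 3, b$radius > 0,
              b$fraction > 0, b$fraction <= 1)
  }
  bundles <- lapply(bundles, function(b) {
    b$axis <- b$axis / sqrt(sum(b$axis^2))
    b
  })
  structure(list(dim = as.integer(dim), voxel_size = voxel_size,
                 head_radii = head_radii, head_center = head_center,
                 rim = rim, bundles = bundles, ad = ad, rd = rd,
                 d_tissue = d_tissue, d_csf = d_csf,
                 S0_tissue = S0_tissue, S0_bundle = S0_bundle,
                 S0_csf = S0_csf, texture = texture),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_bundles <- function() {
  # five bundles with spread orientations and offsets (two crossing at 60
  # degrees, three out-of-plane). Several bundles stay visible from any
  # diffusion-encoding direction, so every volume constrains all three
  # rotation axes (a lone cylinder is symmetric about its own axis), and no
  # single orientation dominates the angular signal.
  nrm <- function(v) v / sqrt(sum(v^2))
  list(list(axis = c(1, 0, 0), radius = 6, fraction = 0.8,
            offset = c(0, 5, 5)),
       list(axis = c(cos(pi / 3), sin(pi / 3), 0), radius = 6, fraction = 0.8,
            offset = c(0, -4, -5)),
       list(axis = c(0, 0.5, sqrt(0.75)), radius = 5.5, fraction = 0.8,
            offset = c(7, -5, 0)),
       list(axis = nrm(c(0.7, -0.3, 0.65)), radius = 5.5, fraction = 0.8,
            offset = c(-7, 4, 0)),
       list(axis = nrm(c(-0.25, 1, 0.2)), radius = 5, fraction = 0.8,
            offset = c(5, 3, -5)))
}

#' Voxel-to-world affine of a phantom grid
#'
#' RAS affine with the grid center at the world origin; voxel indices are
#' 0-based.
#' @param spec A [phantom_spec] (or any list with `dim` and `voxel_size`).
#' @return 4x4 matrix.
#' @export
grid_affine <- function(spec) {
  v <- spec$voxel_size
  off <- -(spec$dim - 1) / 2 * v
  rbind(cbind(diag(v, 3), off), c(0, 0, 0, 1))
}

# Cubic smoothstep of a signed distance (mm) over a transition width (mm):
# 0 well outside, 1 well inside.
smoothstep <- function(d, width) {
  t <- pmin(pmax(d / width + 0.5, 0), 1)
  t * t * (3 - 2 * t)
}

# Tissue composition of the phantom at continuous object-frame points
# (n x 3, mm). All boundaries taper smoothly (partial-volume-like) and the
# b=0 intensity carries a deterministic low-frequency texture so rendered
# volumes have gradient information everywhere, as real anatomy does. The
# texture is part of the continuous object and moves with it.
phantom_composition <- function(spec, pts) {
  n <- nrow(pts)
  rel <- sweep(pts, 2, spec$head_center)
  rbar <- exp(mean(log(spec$head_radii)))
  r_out <- sqrt(rowSums(sweep(rel, 2, spec$head_radii, "/")^2))
  w_head <- smoothstep((1 - r_out) * rbar, 2)
  inner_radii <- pmax(spec$head_radii - spec$rim, 1e-6)
  rbar_in <- exp(mean(log(inner_radii)))
  r_in <- sqrt(rowSums(sweep(rel, 2, inner_radii, "/")^2))
  w_core <- smoothstep((1 - r_in) * rbar_in, 2)
  w_core <- pmin(w_core, w_head)

  k <- length(spec$bundles)
  fb <- matrix(0, n, max(k, 1L))
  if (k > 0) {
    for (b in seq_len(k)) {
      bd <- spec$bundles[[b]]
      ax <- bd$axis
      rb <- if (is.null(bd$offset)) rel else sweep(rel, 2, bd$offset)
      proj <- drop(rb %*% ax)
      perp <- sqrt(pmax(rowSums(rb^2) - proj^2, 0))
      fb[, b] <- bd$fraction * w_core * smoothstep(bd$radius - perp, 1.5)
    }
    tot <- rowSums(fb)
    over <- tot > 0.9   # cap total fiber fraction, rescaling proportionally
    if (any(over)) fb[over, ] <- fb[over, , drop = FALSE] * (0.9 / tot[over])
  }
  tot <- rowSums(fb)
  f_csf <- pmax(w_head - w_core, 0)
  f_tis <- pmax(w_core - tot, 0)
  # incommensurate wavelengths (~12-26 mm), mixing axes so that no rigid
  # rotation maps the texture onto itself
  texture <- 1 + spec$texture *
    (sin(pts[, 1] / 4.1) + sin(pts[, 2] / 5.3) + sin(pts[, 3] / 6.7) +
       sin((pts[, 1] + pts[, 2]) / 2.3) + sin((pts[, 2] - pts[, 3]) / 2.0) +
       sin((pts[, 1] - pts[, 3]) / 2.6) + sin((pts[, 1] + pts[, 2] + pts[, 3]) / 3.1))
  S0 <- texture * (tot * spec$S0_bundle + f_csf * spec$S0_csf +
                     f_tis * spec$S0_tissue)
  list(S0 = S0, f_bundle = fb, f_csf = f_csf, f_tis = f_tis,
       texture = texture, in_head = w_head > 0.5)
}

# Noiseless signal at arbitrary points for one (b, u) with the object rotated
# by Rm (3x3): fiber axes appear rotated in scanner frame, equivalently the
# gradient direction is rotated into the object frame.
phantom_signal_points <- function(spec, comp, b, u, Rm = diag(3)) {
  if (b == 0) return(comp$S0)
  u_obj <- drop(crossprod(Rm, u))   # R^T u
  S <- comp$f_csf * spec$S0_csf * exp(-b * spec$d_csf) +
    comp$f_tis * spec$S0_tissue * exp(-b * spec$d_tissue)
  for (k in seq_along(spec$bundles)) {
    ax <- spec$bundles[[k]]$axis
    c2 <- sum(u_obj * ax)^2
    e_k <- exp(-b * (spec$rd + (spec$ad - spec$rd) * c2))
    S <- S + comp$f_bundle[, k] * spec$S0_bundle * e_k
  }
  comp$texture * S
}

#' Noiseless signal attenuation of one voxel
#'
#' Evaluates the multi-tensor model
#' `E = sum_k f_k exp(-b u' D_k u) + f_iso exp(-b d_iso)` at a voxel center
#' (no motion, no noise), where the weights `f` are *signal* fractions —
#' volume fractions scaled by the compartment b=0 intensities and normalized
#' to sum to one. Returns 1 for b = 0 by construction.
#'
#' @param spec A [phantom_spec].
#' @param voxel Integer voxel index (1-based, length 3).
#' @param b b-value (s/mm^2).
#' @param u Unit gradient direction (required when b > 0).
#' @return Attenuation in `[0, 1]` (0 outside the head).
#' @export
voxel_signal <- function(spec, voxel, b, u = c(0, 0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"), length(voxel) == 3, b >= 0)
  if (b > 0 && abs(sqrt(sum(u^2)) - 1) > 1e-6)
    stop("u must be a unit vector for b > 0")
  A <- grid_affine(spec)
  pt <- drop(A %*% c(voxel - 1, 1))[1:3]
  comp <- phantom_composition(spec, matrix(pt, 1, 3))
  if (comp$S0[1] <= 0) return(0)
  s <- phantom_signal_points(spec, comp, b, u)
  unname(s / comp$S0[1])
}

#' Sample a ground-truth motion trace
#'
#' Flags `round(prevalence * n)` volumes (round-half-up) as moved, chosen
#' uniformly at random, and draws their six rigid parameters i.i.d. uniform on
#' `[-max_trans, max_trans]` mm and `[-max_rot, max_rot]` degrees per axis.
#' All other volumes are exactly identity.
#'
#' @param n_volumes Number of volumes in the series.
#' @param prevalence Fraction of volumes carrying motion, in `[0, 1]`.
#' @param max_trans Maximum absolute translation per axis (mm).
#' @param max_rot Maximum absolute rotation per axis (degrees).
#' @param seed Integer seed.
#' @return A `motion_trace` data.frame with columns `volume`, `tx`, `ty`,
#'   `tz` (mm), `rx`, `ry`, `rz` (degrees; extrinsic X-Y-Z Euler about the
#'   volume center) and `moved`.
#' @export
sample_motion <- function(n_volumes, prevalence, max_trans = 5, max_rot = 5,
                          seed = 0) {
  stopifnot(n_volumes >= 1)
  if (prevalence < 0 || prevalence > 1)
    stop("prevalence must be in [0, 1]")
  if (max_trans < 0 || max_rot < 0)
    stop("motion bounds must be non-negative")
  n_moved <- floor(prevalence * n_volumes + 0.5)  # round-half-up
  tr <- data.frame(volume = seq_len(n_volumes),
                   tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0,
                   moved = FALSE)
  if (n_moved > 0) {
    with_seed(seed, {
      idx <- sort(sample.int(n_volumes, n_moved))
      tr[idx, c("tx", "ty", "tz")] <-
        matrix(runif(3 * n_moved, -max_trans, max_trans), ncol = 3)
      tr[idx, c("rx", "ry", "rz")] <-
        matrix(runif(3 * n_moved, -max_rot, max_rot), ncol = 3)
      tr$moved[idx] <- TRUE
    })
  }
  class(tr) <- c("motion_trace", "data.frame")
  tr
}

#' An all-identity motion trace
#' @param n_volumes Number of volumes.
#' @export
identity_motion <- function(n_volumes) sample_motion(n_volumes, 0)

motion_params <- function(trace, i) {
  unlist(trace[i, c("tx", "ty", "tz", "rx", "ry", "rz")], use.names = FALSE)
}

#' Construct a DWI series object
#'
#' @param data 4-D array (x, y, z, volume), non-negative intensities.
#' @param affine 4x4 voxel(0-based)-to-world matrix (RAS, mm).
#' @param scheme The [sampling_scheme]; its length must match `dim(data)[4]`.
#' @param motion Optional ground-truth `motion_trace`.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(data, affine, scheme, motion = NULL) {
  stopifnot(length(dim(data)) == 4, inherits(scheme, "sampling_scheme"))
  if (dim(data)[4] != length(scheme$bvals))
    stop("volume count must equal scheme length")
  if (any(data < 0)) stop("intensities must be non-negative")
  if (!is.null(motion) && nrow(motion) != dim(data)[4])
    stop("motion trace length must equal volume count")
  structure(list(data = data, affine = affine, scheme = scheme,
                 voxel_size = unname(sqrt(colSums(affine[1:3, 1:3]^2))),
                 motion = motion),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_series> %dx%dx%d voxels, %d volumes, scheme '%s'\n",
              d[1], d[2], d[3], d[4], x$scheme$name))
  invisible(x)
}

#' Simulate a motion-corrupted DWI series
#'
#' For every volume the phantom's continuous geometry is rigidly transformed
#' by that volume's motion parameters before the signal is sampled onto the
#' fixed voxel grid (the object moves, the grid stays; no rendered image is
#' ever resampled). Rician noise is then applied at the stated SNR. Noise is
#' drawn from a per-volume seeded stream, so a volume with identity parameters
#' is bit-identical to its counterpart in a no-motion simulation under the
#' same seed.
#'
#' @param spec A [phantom_spec].
#' @param scheme A [sampling_scheme].
#' @param motion A `motion_trace` of the same length (default: no motion).
#' @param snr Signal-to-noise ratio of the tissue b=0 intensity
#'   (sigma = S0_tissue / snr); `Inf` for noiseless data.
#' @param seed Integer seed for the noise stream.
#' @return A [dwi_series] with the ground-truth trace attached.
#' @export
simulate_series <- function(spec, scheme, motion = NULL, snr = Inf, seed = 0) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scheme, "sampling_scheme"))
  n <- length(scheme$bvals)
  if (is.null(motion)) motion <- identity_motion(n)
  if (nrow(motion) != n)
    stop("motion trace length must equal scheme length")
  A <- grid_affine(spec)
  d <- spec$dim
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  X <- cbind(sweep(ijk, 2, (d - 1) / 2, "-") * spec$voxel_size, 1)
  comp0 <- phantom_composition(spec, X[, 1:3])
  sigma <- spec$S0_tissue / snr
  out <- array(0, c(d, n))
  for (v in seq_len(n)) {
    p <- motion_params(motion, v)
    if (all(p == 0)) {
      comp <- comp0
      Rm <- diag(3)
    } else {
      M <- rigid_matrix(p)
      Minv <- solve(M)
      pts <- t(Minv[1:3, ] %*% t(cbind(X[, 1:3], 1)))
      comp <- phantom_composition(spec, pts)
      Rm <- M[1:3, 1:3]
    }
    s <- phantom_signal_points(spec, comp, scheme$bvals[v],
                               scheme$bvecs[v, ], Rm)
    if (is.finite(snr)) {
      s <- with_seed(seed + 7919L * v, {
        n1 <- rnorm(length(s), 0, sigma)
        n2 <- rnorm(length(s), 0, sigma)
        sqrt((s + n1)^2 + n2^2)
      })
    }
    out[, , , v] <- s
  }
  dwi_series(out, A, scheme, motion)
}
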