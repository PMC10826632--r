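#' Rigid transform parameters to a 4x4 world matrix
#'
#' Parameters are `(tx, ty, tz)` in mm and `(rx, ry, rz)` in degrees,
#' extrinsic X-Y-Z Euler rotations (`R = Rz Ry Rx`) about the pivot `center`
#' (world mm; default the origin, which is the grid center for phantom
#' grids). The matrix maps a world point `p` to `R (p - center) + center + t`.
#' The same convention describes simulated motion, so estimated and true
#' parameters are directly comparable.
#'
#' @param params Numeric vector of length 6.
#' @param center Pivot in world coordinates.
#' @return 4x4 matrix.
#' @export
rigid_matrix <- function(params, center = c(0, 0, 0)) {
  stopifnot(length(params) == 6)
  t <- params[1:3]
  a <- params[4:6] * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  off <- t + center - drop(R %*% center)
  rbind(cbind(R, off), c(0, 0, 0, 1))
}

#' Decompose a rigid 4x4 matrix into the 6 parameters
#'
#' Inverse of [rigid_matrix] under the same Euler/pivot convention.
#' @param M 4x4 rigid matrix.
#' @param center Pivot in world coordinates.
#' @return Numeric vector `(tx, ty, tz, rx, ry, rz)`.
#' @export
matrix_to_params <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock: fold rz into rx
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  t <- M[1:3, 4] - center + drop(R %*% center)
  c(t, c(rx, ry, rz) * 180 / pi)
}

# 12-parameter affine: rigid 6 + log-scales 3 + shears 3 (xy, xz, yz),
# A = T R Shear Scale about the pivot.
affine_matrix <- function(params, center = c(0, 0, 0)) {
  stopifnot(length(params) == 12)
  Rg <- rigid_matrix(params[1:6], center = c(0, 0, 0))[1:3, 1:3]
  Sc <- diag(exp(params[7:9]))
  Sh <- diag(3)
  Sh[1, 2] <- params[10]; Sh[1, 3] <- params[11]; Sh[2, 3] <- params[12]
  L <- Rg %*% Sh %*% Sc
  off <- params[1:3] + center - drop(L %*% center)
  rbind(cbind(L, off), c(0, 0, 0, 1))
}

transform_matrix <- function(params, center = c(0, 0, 0)) {
  if (length(params) == 6) rigid_matrix(params, center)
  else affine_matrix(params, center)
}

#' Resample a volume under a world-space transform
#'
#' Applies a single interpolation: `out(x) = in(T x)` in world coordinates,
#' i.e. `T` maps output (fixed) space into input (moving) space — the
#' convention returned by [register()]. Out-of-field voxels are set to 0. The
#' identity transform with linear interpolation is an exact pass-through.
#'
#' @param volume 3-D array.
#' @param transform 4x4 world matrix, or a 6/12-parameter vector.
#' @param affine Voxel(0-based)-to-world 4x4 matrix of the grid.
#' @param interpolation `"linear"` (default) or `"spline"` (interpolating
#'   cubic).
#' @return 3-D array on the same grid.
#' @export
resample <- function(volume, transform, affine, interpolation = c("linear", "spline")) {
  interpolation <- match.arg(interpolation)
  if (is.numeric(transform) && is.null(dim(transform)))
    transform <- transform_matrix(transform)
  d <- dim(volume)
  Mvox <- solve(affine) %*% transform %*% affine
  out <- .resample_affine_cpp(as.numeric(volume), as.integer(d), Mvox,
                              if (interpolation == "linear") 0L else 1L)
  array(out, d)
}

# Build the multi-resolution pyramid for one volume: list of
# list(vol, affine) from coarse to fine. Smoothing sigmas (in voxels of the
# original grid) precede each downsampling step.
build_pyramid <- function(vol, affine, levels = 3L, sigmas = c(2, 1, 0)) {
  n <- length(vol)
  out <- vector("list", levels)
  out[[levels]] <- list(vol = vol, affine = affine)
  cur <- vol
  cur_aff <- affine
  for (l in seq(levels - 1L, 1L)) {
    s <- sigmas[levels - l]
    sm <- gauss_smooth3(cur, s)
    cur <- downsample2(sm)
    # level voxel i maps to parent voxel 2i + 0.5
    S <- rbind(cbind(diag(2, 3), rep(0.5, 3)), c(0, 0, 0, 1))
    cur_aff <- cur_aff %*% S
    out[[l]] <- list(vol = cur, affine = cur_aff)
  }
  out
}

# Regular-step gradient descent on a scalar objective.
regular_step_gd <- function(f, p0, step0, min_step, maxit, delta) {
  p <- p0
  fp <- f(p)
  step <- step0
  np <- length(p)
  for (it in seq_len(maxit)) {
    g <- numeric(np)
    for (k in seq_len(np)) {
      e <- numeric(np); e[k] <- delta[k]
      g[k] <- (f(p + e) - f(p - e)) / (2 * delta[k])
    }
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) break
    cand <- p - step * g / gn
    fc <- f(cand)
    if (fc < fp) {
      p <- cand
      fp <- fc
    } else {
      step <- step / 2
    }
    if (step < min_step) break
  }
  list(par = p, value = fp)
}

# Normalized mutual information (Studholme) between fixed values and moving
# samples; returned negated for minimization.
neg_nmi <- function(a, b, nbins = 32L) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ia <- pmin(pmax(floor((a - ra[1]) / diff(ra) * nbins) + 1L, 1L), nbins)
  ib <- pmin(pmax(floor((b - rb[1]) / diff(rb) * nbins) + 1L, 1L), nbins)
  h2 <- table(factor(ia, 1:nbins), factor(ib, 1:nbins)) / length(a)
  pa <- rowSums(h2); pb <- colSums(h2)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  hab <- -sum(h2[h2 > 0] * log(h2[h2 > 0]))
  -(ha + hb) / hab
}

#' Register a volume to a fixed target
#'
#' Multi-resolution (3-level Gaussian pyramid) estimation of a rigid (6-DOF)
#' or affine (12-DOF) transform maximizing normalized cross-correlation
#' (default) or normalized mutual information over the fixed-image mask:
#' regular-step gradient descent with a halving step schedule at each level,
#' then a restarted Nelder-Mead refinement at full resolution. The result is
#' never worse (in the finest-level metric) than the initialization. The
#' returned transform maps fixed-space points into moving space, so
#' `resample(moving, transform, affine)` aligns the moving volume to the
#' fixed one.
#'
#' @param moving,fixed 3-D arrays on the same grid.
#' @param affine Shared voxel-to-world matrix.
#' @param model `"rigid"` or `"affine"`.
#' @param init Initial parameter vector (length 6 or 12; default identity).
#' @param mask Logical array (fixed-image mask); required non-empty.
#' @param metric `"ncc"` (default) or `"nmi"`.
#' @param center Rotation pivot in world coordinates.
#' @param bound Soft search bound on the rigid parameters (mm / degrees): a
#'   quadratic penalty activates beyond `|p| > bound`, keeping the estimate
#'   local when a volume carries little registration information (head motion
#'   inside a scanner coil is physically bounded). Default `Inf` (off).
#' @param dilate_mask Dilate the mask by one voxel to include the object
#'   boundary (default `TRUE`; set `FALSE` when the fixed image is a model
#'   prediction that is undefined outside the mask).
#' @param metric_sigma Gaussian smoothing (voxels) applied identically to
#'   both images at each pyramid level before the metric is evaluated.
#' @return List with `params`, `matrix`, `metric` (achieved value, NCC or NMI
#'   scale) and `model`.
#' @export
register <- function(moving, fixed, affine, model = c("rigid", "affine"),
                     init = NULL, mask = NULL, metric = c("ncc", "nmi"),
                     center = c(0, 0, 0), bound = Inf, dilate_mask = TRUE,
                     metric_sigma = 1.0) {
  model <- match.arg(model)
  metric <- match.arg(metric)
  if (!identical(dim(moving), dim(fixed)))
    stop("moving and fixed must share one grid")
  if (any(!is.finite(moving)) || any(!is.finite(fixed)))
    stop("non-finite intensities")
  if (is.null(mask)) mask <- make_brain_mask(fixed)
  if (!any(mask)) stop("empty registration mask")
  # include the object boundary — a strong rigid-body cue — but only when the
  # fixed image is a real acquisition: synthetic targets are zero outside the
  # mask and would present an artificial cliff in the dilated ring
  if (dilate_mask) mask <- morph3(mask * 1, pmax) > 0.5
  npar <- if (model == "rigid") 6L else 12L
  if (is.null(init)) init <- numeric(npar)
  if (length(init) != npar) stop("init has wrong length for model")

  lv <- min(3L, floor(log2(min(dim(fixed)) / 8)) + 1L)
  lv <- max(lv, 1L)
  pyr_m <- build_pyramid(moving, affine, lv)
  pyr_f <- build_pyramid(fixed, affine, lv)
  # mask pyramid: block-mean occupancy, slightly dilated by the > 0.3 cut
  masks <- vector("list", lv)
  masks[[lv]] <- mask
  mcur <- array(as.numeric(mask), dim(mask))
  for (l in rev(seq_len(lv - 1L))) {
    mcur <- downsample2(mcur)
    masks[[l]] <- mcur > 0.3
  }

  p <- init
  scales <- if (model == "rigid") rep(1, 6) else c(rep(1, 6), rep(0.02, 6))
  steps0 <- c(2, 1, 0.5)[seq(4 - lv, 3)]
  min_steps <- c(0.02, 0.01, 0.005)[seq(4 - lv, 3)]
  for (l in seq_len(lv)) {
    fl <- pyr_f[[l]]
    ml <- pyr_m[[l]]
    mvol <- gauss_smooth3(ml$vol, metric_sigma)
    fvol <- gauss_smooth3(fl$vol, metric_sigma)
    ml_mask <- masks[[l]]
    if (!any(ml_mask)) ml_mask <- array(TRUE, dim(fvol))
    cl <- which(ml_mask, arr.ind = TRUE) - 1  # integer level-grid coords
    storage.mode(cl) <- "double"
    if (nrow(cl) > 20000)
      cl <- cl[round(seq(1, nrow(cl), length.out = 20000)), , drop = FALSE]
    # sub-voxel jitter of the sample lattice: both images then pass through
    # trilinear interpolation symmetrically at every candidate transform
    # (grid-aligned transforms would otherwise sample the moving image
    # blur-free and bias the metric toward off-grid poses)
    dl <- dim(fvol)
    cl <- cl + with_seed(8191L, matrix(runif(length(cl), -0.5, 0.5), ncol = 3))
    for (ax in 1:3) cl[, ax] <- pmin(pmax(cl[, ax], 0), dl[ax] - 1)
    fvals <- .sample_points_cpp(as.numeric(fvol), as.integer(dl), cl)
    Ainv <- solve(ml$affine)
    mvec <- as.numeric(mvol)
    mdim <- as.integer(dim(mvol))
    AL <- fl$affine
    objective <- function(z) {
      pp <- z * scales
      M <- Ainv %*% transform_matrix(pp, center) %*% AL
      val <- if (metric == "ncc") {
        .ncc_points_cpp(mvec, mdim, cl, fvals, M)
      } else {
        mv <- .sample_points_mat(mvol, cl, M)
        neg_nmi(mv, fvals)
      }
      if (is.finite(bound))
        val <- val + 0.05 * sum(pmax(abs(pp[1:6]) - bound, 0)^2)
      val
    }
    res <- regular_step_gd(objective, p / scales,
                           step0 = steps0[l], min_step = min_steps[l],
                           maxit = 60L,
                           delta = rep(if (l < lv) 0.5 else 0.25, npar))
    p <- res$par * scales
    if (l == lv) {
      # derivative-free simplex refinement at full resolution: the NCC
      # valley is shallow and curved near the optimum, where fixed-step
      # descent stalls
      # restarted simplex: a fresh simplex at the previous optimum recovers
      # from premature collapse far more cheaply than one long run
      for (restart in 1:3) {
        nm <- optim(res$par, objective, method = "Nelder-Mead",
                    control = list(maxit = 300L, reltol = 1e-10))
        improved <- nm$value < res$value - 1e-7
        if (nm$value < res$value) {
          res <- nm
          p <- nm$par * scales
        }
        if (!improved) break
      }
      # the chain must never end worse than where it started: if the coarse
      # levels wandered (featureless or degenerate volumes), keep the init
      f_init <- objective(init / scales)
      if (f_init <= res$value) {
        p <- init
        res$value <- f_init
      }
    }
  }
  list(params = p, matrix = transform_matrix(p, center),
       metric = -res$value, model = model)
}

# Sample a volume at transformed 0-based voxel coordinates (n x 3), trilinear.
.sample_points_mat <- function(vol, coords, M) {
  d <- dim(vol)
  vapply(seq_len(nrow(coords)), function(t) {
    p <- M %*% c(coords[t, ], 1)
    .interp_one(vol, d, p[1], p[2], p[3])
  }, numeric(1))
}

.interp_one <- function(vol, d, x, y, z) {
  if (x < 0 || y < 0 || z < 0 || x > d[1] - 1 || y > d[2] - 1 || z > d[3] - 1)
    return(0)
  x0 <- min(floor(x), d[1] - 2); y0 <- min(floor(y), d[2] - 2)
  z0 <- min(floor(z), d[3] - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  v <- vol[(x0 + 1):(x0 + 2), (y0 + 1):(y0 + 2), (z0 + 1):(z0 + 2)]
  c00 <- v[1, 1, 1] * (1 - fx) + v[2, 1, 1] * fx
  c10 <- v[1, 2, 1] * (1 - fx) + v[2, 2, 1] * fx
  c01 <- v[1, 1, 2] * (1 - fx) + v[2, 1, 2] * fx
  c11 <- v[1, 2, 2] * (1 - fx) + v[2, 2, 2] * fx
  (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
}
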