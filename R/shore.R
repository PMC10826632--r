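#' Define a 3dSHORE basis
#'
#' The simple-harmonic-oscillator reconstruction and estimation (3dSHORE)
#' basis expresses the q-space signal as radial generalized-Laguerre-Gaussian
#' functions times real spherical harmonics of even order, defined over all of
#' R^3 — hence applicable to shelled, Cartesian-grid and sparse random
#' sampling alike. Basis functions are indexed by `(n, l, m)` with even
#' `l <= radial_order`, `l <= n <= (radial_order + l)/2`, `|m| <= l`; the
#' count is `(N/2+1)(N/2+2)(2N+3)/6` for radial order `N` (50 at the default
#' order 6).
#'
#' q-vectors follow the package convention `q = sqrt(b) * u`, so the scale
#' parameter `zeta` is expressed in b-value units (s/mm^2): the radial
#' Gaussian factor is `exp(-q^2 / (2 zeta))`. This matches the usual
#' `zeta = 1 / (8 pi^2 tau MD)` rule with `tau = 1/(4 pi^2)` folded in.
#'
#' @param radial_order Even non-negative integer (default 6).
#' @param zeta Positive scale parameter in b-value units.
#' @return An object of class `shore_basis` with the `(n, l, m)` index table.
#' @export
shore_basis <- function(radial_order = 6L, zeta = 700) {
  if (radial_order < 0 || radial_order %% 2 != 0)
    stop("radial_order must be a non-negative even integer")
  if (zeta <= 0) stop("zeta must be positive")
  idx <- do.call(rbind, lapply(seq(0, radial_order, 2), function(l) {
    do.call(rbind, lapply(seq(l, (radial_order + l) / 2), function(n) {
      data.frame(n = n, l = l, m = seq(-l, l))
    }))
  }))
  structure(list(radial_order = as.integer(radial_order), zeta = zeta,
                 index = idx),
            class = "shore_basis")
}

#' @export
print.shore_basis <- function(x, ...) {
  cat(sprintf("<shore_basis> radial order %d, %d functions, zeta = %.4g\n",
              x$radial_order, nrow(x$index), x$zeta))
  invisible(x)
}

# Associated Legendre P_l^m(x) for m >= 0 (with Condon-Shortley phase).
assoc_legendre <- function(l, m, x) {
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(1 - x^2, 0))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in seq(m + 2, l)) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pmmp1
}

# Real spherical harmonic Y_{lm}(theta, phi), orthonormal on the sphere.
real_sph_harm <- function(l, m, theta, phi) {
  am <- abs(m)
  K <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  P <- assoc_legendre(l, am, cos(theta))
  if (m == 0) K * P
  else if (m > 0) sqrt(2) * K * P * cos(am * phi)
  else sqrt(2) * K * P * sin(am * phi)
}

# Generalized Laguerre polynomial L_k^alpha(x) by recurrence.
gen_laguerre <- function(k, alpha, x) {
  if (k == 0) return(rep(1, length(x)))
  lm1 <- rep(1, length(x))
  l <- 1 + alpha - x
  if (k == 1) return(l)
  for (i in seq(2, k)) {
    lnew <- ((2 * i - 1 + alpha - x) * l - (i - 1 + alpha) * lm1) / i
    lm1 <- l
    l <- lnew
  }
  l
}

#' Evaluate the 3dSHORE design matrix
#'
#' Entry `(i, j)` is basis function `j` at q-point `i`. At the origin only the
#' zero-angular-order (`l = 0`) functions are nonzero, which anchors the b=0
#' prediction.
#'
#' @param basis A [shore_basis].
#' @param qpoints Matrix (n x 3) of q-vectors (`sqrt(b) * u` convention).
#' @return Numeric matrix (n points x n basis functions).
#' @export
shore_design_matrix <- function(basis, qpoints) {
  stopifnot(inherits(basis, "shore_basis"))
  qpoints <- as.matrix(qpoints)
  if (nrow(qpoints) == 0) stop("qpoints must be nonempty")
  r2 <- rowSums(qpoints^2)
  r <- sqrt(r2)
  theta <- ifelse(r > 0, acos(pmin(pmax(qpoints[, 3] / pmax(r, 1e-300), -1), 1)), 0)
  phi <- atan2(qpoints[, 2], qpoints[, 1])
  x <- r2 / basis$zeta
  gauss <- exp(-x / 2)
  idx <- basis$index
  M <- matrix(0, nrow(qpoints), nrow(idx))
  for (j in seq_len(nrow(idx))) {
    n <- idx$n[j]; l <- idx$l[j]; m <- idx$m[j]
    kappa <- sqrt(2 * exp(lgamma(n - l + 1) - lgamma(n + 1.5)) /
                    basis$zeta^1.5)
    radial <- gen_laguerre(n - l, l + 0.5, x) * gauss * kappa *
      (if (l == 0) 1 else x^(l / 2))
    M[, j] <- real_sph_harm(l, m, theta, phi) * radial
  }
  M
}

#' L2-regularized 3dSHORE fit
#'
#' Per-voxel ridge solution `c = argmin |Phi c - s|^2 + lambda' |c|^2` via the
#' regularized normal equations, one Cholesky factorization shared across all
#' voxels. The penalty is isotropic (identity Tikhonov matrix) and `lambda` is
#' expressed relative to the mean diagonal of `Phi' Phi`, so the shrinkage
#' strength is invariant to the basis normalization.
#'
#' @param signals Matrix (n q-points x n voxels) of attenuations normalized by
#'   the mean b=0 signal (values mostly in `[0, ~1.5]`).
#' @param basis A [shore_basis].
#' @param qpoints The design q-points (n x 3), matching `signals` rows.
#' @param lambda Relative ridge weight, `>= 0` (default 1e-8).
#' @param angular_weight Optional Laplace-Beltrami-style weighting of the
#'   penalty: the diagonal Tikhonov entry for a basis function of angular
#'   order `l` becomes `1 + angular_weight * (l (l + 1))^2`, damping
#'   high-angular-order terms more strongly (0 = plain identity penalty).
#' @param design Optional precomputed design matrix for these q-points.
#' @return An object of class `shore_fit` with per-voxel `coefficients`
#'   (n basis x n voxels).
#' @export
shore_fit_l2 <- function(signals, basis, qpoints, lambda = 1e-8,
                         angular_weight = 0, design = NULL) {
  if (lambda < 0) stop("lambda must be non-negative")
  signals <- as.matrix(signals)
  if (is.null(design)) design <- shore_design_matrix(basis, qpoints)
  if (nrow(design) != nrow(signals))
    stop("design rows must correspond to signal entries")
  AtA <- crossprod(design)
  lam_abs <- lambda * mean(diag(AtA))
  pen <- penalty_diag(basis, angular_weight)
  A <- AtA + diag(lam_abs * pen, ncol(design))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    if (lambda == 0)
      stop("design is rank-deficient; refit with lambda > 0")
    stop("normal equations could not be factorized")
  }
  if (lambda == 0 && rcond(AtA) < 1e-12)
    stop("design is rank-deficient; refit with lambda > 0")
  coefs <- backsolve(ch, forwardsolve(t(ch), crossprod(design, signals)))
  structure(list(coefficients = coefs, basis = basis, lambda = lambda,
                 lambda_abs = lam_abs, qpoints = as.matrix(qpoints),
                 design = design),
            class = "shore_fit")
}

#' Predict the signal at an arbitrary q-space point
#'
#' Evaluates `Phi(q) c` per voxel and clips negative predictions to zero.
#' Predictions stay on the normalized-attenuation scale of the fitted
#' signals; multiply by the b=0 reference to recover intensities.
#'
#' @param fit A [shore_fit_l2] result.
#' @param qpoint q-vector (length 3).
#' @return Numeric vector, one predicted attenuation per voxel.
#' @export
predict_at <- function(fit, qpoint) {
  stopifnot(inherits(fit, "shore_fit"))
  phi <- shore_design_matrix(fit$basis, matrix(qpoint, 1, 3))
  pmax(drop(phi %*% fit$coefficients), 0)
}

#' Data-driven scale parameter for the 3dSHORE basis
#'
#' Fits a mono-exponential decay to the per-shell mean attenuations and sets
#' `zeta = 1/(2 MD)` in b-value units (the `1/(8 pi^2 tau MD)` rule with
#' `tau = 1/(4 pi^2)` under the `q = sqrt(b) u` convention).
#'
#' @param bvals b-values of the fitted volumes.
#' @param mean_att Mean in-mask attenuation per volume.
#' @return Positive scalar `zeta`.
#' @export
estimate_zeta <- function(bvals, mean_att) {
  ok <- mean_att > 0 & bvals > 0
  if (sum(ok) < 2) return(700)
  md <- -coef(lm(log(mean_att[ok]) ~ bvals[ok]))[[2]]
  md <- min(max(md, 1e-4), 4e-3)  # clamp to physical diffusivities (mm^2/s)
  1 / (2 * md)
}

penalty_diag <- function(basis, angular_weight) {
  if (angular_weight <= 0) return(rep(1, nrow(basis$index)))
  l <- basis$index$l
  1 + angular_weight * (l * (l + 1))^2
}

# Leave-one-out SHORE predictions for every b>0 volume at once, via rank-one
# downdates of the shared normal equations. signals: (n rows x n voxels)
# attenuations; rows listed in loo_rows are predicted with themselves left
# out, while the remaining rows (e.g. a q = 0 anchor built from the b=0
# mean) stay in every fit. Returns predictions for loo_rows in order.
shore_loo_matrix <- function(signals, basis, qpoints, lambda,
                             angular_weight = 0,
                             loo_rows = seq_len(nrow(signals))) {
  Phi <- shore_design_matrix(basis, qpoints)
  AtA <- crossprod(Phi)
  lam_abs <- lambda * mean(diag(AtA))
  pen <- diag(lam_abs * penalty_diag(basis, angular_weight), ncol(Phi))
  B <- crossprod(Phi, signals)
  out <- matrix(0, length(loo_rows), ncol(signals))
  for (t in seq_along(loo_rows)) {
    i <- loo_rows[t]
    phi <- Phi[i, ]
    Ai <- AtA - tcrossprod(phi) + pen
    bi <- B - phi %*% t(signals[i, ])
    ch <- chol(Ai)
    ci <- backsolve(ch, forwardsolve(t(ch), bi))
    out[t, ] <- pmax(drop(phi %*% ci), 0)
  }
  out
}

#' Leave-one-out 3dSHORE prediction of one volume
#'
#' Fits the basis to all b>0 volumes except `leave_out` (signals normalized by
#' the mean b=0 volume) and returns the predicted 3-D volume at the left-out
#' q-space point, rescaled to intensity units. This prediction is the
#' registration target used by [shoreline_correct()].
#'
#' @param series A [dwi_series].
#' @param leave_out Index of a b>0 volume.
#' @param basis Optional [shore_basis]; by default radial order 6 with a
#'   data-driven `zeta` from [estimate_zeta()].
#' @param lambda Relative ridge weight.
#' @param mask Optional logical array; defaults to a mask of the mean b=0.
#' @return 3-D array (prediction inside the mask, 0 outside).
#' @export
loo_predict <- function(series, leave_out, basis = NULL, lambda = 1e-8,
                        mask = NULL) {
  stopifnot(inherits(series, "dwi_series"))
  sch <- series$scheme
  if (sch$bvals[leave_out] == 0)
    stop("leave_out must index a b>0 volume")
  sh <- detect_shells(sch)
  if (length(sh$shell_b) < 3)  # shell 0 plus at least two nonzero b clusters
    stop("sampling scheme must contain at least two unique non-zero b-values")
  b0 <- which(sch$bvals == 0)
  if (length(b0) == 0) stop("series has no b=0 volume for normalization")
  b0_ref <- apply(series$data[, , , b0, drop = FALSE], 1:3, mean)
  if (is.null(mask)) mask <- make_brain_mask(b0_ref)
  dwi <- setdiff(which(sch$bvals > 0), leave_out)
  q <- qvectors(sch)
  ref <- b0_ref[mask]
  ref[ref <= 0] <- 1
  sig <- t(vapply(dwi, function(v) series$data[, , , v][mask] / ref,
                  numeric(sum(mask))))
  if (is.null(basis)) {
    zeta <- estimate_zeta(sch$bvals[dwi], rowMeans(sig))
    basis <- shore_basis(6L, zeta)
  }
  fit <- shore_fit_l2(sig, basis, q[dwi, , drop = FALSE], lambda)
  pred <- predict_at(fit, q[leave_out, ])
  out <- array(0, dim(series$data)[1:3])
  out[mask] <- pred * ref
  out
}
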