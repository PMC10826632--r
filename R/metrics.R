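#' Motion-parameter error summary
#'
#' For each volume the residual transform `Delta = T_est o T_true^{-1}` is
#' decomposed into the six rigid parameters under the shared Euler/pivot
#' convention. Signed per-axis errors are pooled over the three axes and all
#' volumes: the mean signed error measures estimator bias, and
#' `RMSE = sqrt(mean(error^2))` its magnitude — translation (mm) and rotation
#' (degrees) separately. A per-axis breakdown is included.
#'
#' @param estimated,truth `motion_trace` data.frames of equal length.
#' @param center Rotation pivot (world mm) shared by both traces.
#' @return An object of class `motion_error_summary`: lists `translation` and
#'   `rotation`, each with `mean_error`, `rmse` and `per_axis`; plus the
#'   per-volume residual parameter matrix `residuals`.
#' @export
motion_error <- function(estimated, truth, center = c(0, 0, 0)) {
  if (nrow(estimated) != nrow(truth))
    stop("estimated and truth traces must have equal length")
  n <- nrow(estimated)
  res <- matrix(0, n, 6, dimnames = list(NULL, c("tx", "ty", "tz",
                                                 "rx", "ry", "rz")))
  for (i in seq_len(n)) {
    Te <- rigid_matrix(motion_params(estimated, i), center)
    Tt <- rigid_matrix(motion_params(truth, i), center)
    res[i, ] <- matrix_to_params(Te %*% solve(Tt), center)
  }
  tr <- as.vector(res[, 1:3])
  ro <- as.vector(res[, 4:6])
  per_axis <- data.frame(axis = c("x", "y", "z"),
                         mean_error_trans = colMeans(res[, 1:3, drop = FALSE]),
                         rmse_trans = sqrt(colMeans(res[, 1:3, drop = FALSE]^2)),
                         mean_error_rot = colMeans(res[, 4:6, drop = FALSE]),
                         rmse_rot = sqrt(colMeans(res[, 4:6, drop = FALSE]^2)),
                         row.names = NULL)
  structure(list(
    translation = list(mean_error = mean(tr), rmse = sqrt(mean(tr^2))),
    rotation = list(mean_error = mean(ro), rmse = sqrt(mean(ro^2))),
    per_axis = per_axis,
    residuals = res), class = "motion_error_summary")
}

#' @export
print.motion_error_summary <- function(x, ...) {
  cat(sprintf("translation: mean error %+.4f mm, RMSE %.4f mm\n",
              x$translation$mean_error, x$translation$rmse))
  cat(sprintf("rotation:    mean error %+.4f deg, RMSE %.4f deg\n",
              x$rotation$mean_error, x$rotation$rmse))
  invisible(x)
}

#' Neighboring DWI correlation (NDC)
#'
#' Mean in-mask Pearson correlation between each b>0 volume and the b>0
#' volume sampling the closest q-space point (antipodally identified; see
#' [nearest_qspace_neighbors()]). Misalignment between volumes and noise both
#' lower NDC, making it a concise quality score for a series.
#'
#' @param series A [dwi_series].
#' @param mask Optional logical array; defaults to a mask of the mean b=0
#'   (or of the mean volume if no b=0 exists).
#' @return Scalar in `[-1, 1]`.
#' @export
ndc <- function(series, mask = NULL) {
  stopifnot(inherits(series, "dwi_series"))
  nb <- nearest_qspace_neighbors(series$scheme)
  if (is.null(mask)) {
    b0 <- which(series$scheme$bvals == 0)
    ref <- if (length(b0) > 0)
      apply(series$data[, , , b0, drop = FALSE], 1:3, mean)
    else apply(series$data, 1:3, mean)
    mask <- make_brain_mask(ref)
  }
  if (!any(mask)) stop("empty mask")
  cors <- vapply(seq_len(nrow(nb)), function(t) {
    a <- series$data[, , , nb$i[t]][mask]
    b <- series$data[, , , nb$j[t]][mask]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  if (anyNA(cors))
    warning("skipped ", sum(is.na(cors)), " pair(s) with zero variance in-mask")
  mean(cors, na.rm = TRUE)
}

#' FWHM smoothness of a volume
#'
#' Classic Gaussian-random-field estimator: per axis,
#' `FWHM = voxel * sqrt(-2 log(2) / log(1 - var(diff) / (2 var(values))))`
#' from in-mask first differences along that axis; the geometric mean across
#' axes summarizes overall smoothness. Where the first-difference variance
#' reaches twice the value variance the estimator is undefined and `Inf` is
#' reported with a warning.
#'
#' @param volume 3-D array.
#' @param mask Logical array with at least 100 voxels.
#' @param voxel_size Voxel edge lengths (mm), length 1 or 3.
#' @return List with `per_axis` (named, mm) and `fwhm` (geometric mean, mm).
#' @export
estimate_fwhm <- function(volume, mask = NULL, voxel_size = 1) {
  d <- dim(volume)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (sum(mask) < 100) stop("mask must contain at least 100 voxels")
  voxel_size <- rep(voxel_size, length.out = 3)
  v_all <- var(volume[mask])
  per_axis <- numeric(3)
  for (ax in 1:3) {
    idx_hi <- lapply(1:3, function(k) if (k == ax) 2:d[k] else seq_len(d[k]))
    idx_lo <- lapply(1:3, function(k) if (k == ax) seq_len(d[k] - 1) else seq_len(d[k]))
    hi <- do.call(`[`, c(list(volume), idx_hi, list(drop = FALSE)))
    lo <- do.call(`[`, c(list(volume), idx_lo, list(drop = FALSE)))
    mhi <- do.call(`[`, c(list(mask), idx_hi, list(drop = FALSE)))
    mlo <- do.call(`[`, c(list(mask), idx_lo, list(drop = FALSE)))
    dif <- (hi - lo)[mhi & mlo]
    vd <- var(dif)
    ratio <- 1 - vd / (2 * v_all)
    if (!is.finite(ratio) || ratio <= 0) {
      warning("FWHM undefined along axis ", ax,
              " (difference variance >= 2 x value variance)")
      per_axis[ax] <- Inf
    } else {
      per_axis[ax] <- voxel_size[ax] * sqrt(-2 * log(2) / log(ratio))
    }
  }
  names(per_axis) <- c("x", "y", "z")
  list(per_axis = per_axis, fwhm = exp(mean(log(per_axis))))
}
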