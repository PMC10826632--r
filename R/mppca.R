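#' Marchenko-Pastur PCA denoising
#'
#' Patch-wise PCA denoising of a 4-D DWI series. For every sliding patch the
#' volume-centered Casorati matrix (patch voxels x volumes) is eigen-
#' decomposed and the number of noise components is chosen as the largest set
#' of trailing eigenvalues whose spread is consistent with the Marchenko-
#' Pastur bulk edge for the matrix aspect ratio; their average yields the
#' local noise variance. Supra-cutoff components are retained, overlapping
#' patch reconstructions are averaged, and the per-voxel average noise sigma
#' is returned alongside.
#'
#' @param series A [dwi_series] (or a bare 4-D array).
#' @param patch_radius Patch half-width in voxels (patch side
#'   `2 * patch_radius + 1`; default 2).
#' @param stride Step between patch origins (1 = fully sliding, the default).
#'   Patch windows are clamped at the volume border so every voxel is
#'   covered.
#' @return A list: `series` (denoised, same class as the input), `sigma`
#'   (3-D noise-sigma map).
#' @export
denoise_mppca <- function(series, patch_radius = 2L, stride = 1L) {
  arr <- if (inherits(series, "dwi_series")) series$data else series
  stopifnot(length(dim(arr)) == 4)
  d <- dim(arr)
  if (any(2L * patch_radius + 1L > d[1:3]))
    stop("patch larger than volume")
  res <- .mppca_cpp(as.numeric(arr), as.integer(d), as.integer(patch_radius),
                    as.integer(stride))
  den <- array(res$denoised, d)
  sigma <- array(res$sigma, d[1:3])
  out <- if (inherits(series, "dwi_series")) {
    den[den < 0] <- 0  # intensities are non-negative by contract
    dwi_series(den, series$affine, series$scheme, series$motion)
  } else den
  list(series = out, sigma = sigma)
}
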