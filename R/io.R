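#' Write a DWI series to NIfTI-1 plus gradient table
#'
#' Writes `<prefix>.nii.gz`, `<prefix>.bval`, `<prefix>.bvec` (FSL style) and,
#' when a ground-truth trace is attached, `<prefix>_motion.tsv`.
#'
#' @param series A [dwi_series].
#' @param prefix Output path prefix.
#' @return The paths written, invisibly.
#' @export
write_dwi_series <- function(series, prefix) {
  stopifnot(inherits(series, "dwi_series"))
  nii <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(series$data)
  img <- RNifti::`sform<-`(img, structure(series$affine, code = 2L))
  RNifti::writeNifti(img, nii)
  write_bvalbvec(series$scheme, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  paths <- c(nii, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  if (!is.null(series$motion)) {
    mt <- paste0(prefix, "_motion.tsv")
    write_motion_tsv(series$motion, mt)
    paths <- c(paths, mt)
  }
  invisible(paths)
}

#' Read a DWI series from NIfTI-1 plus gradient table
#'
#' @param nii Path to the 4-D NIfTI file.
#' @param bval,bvec Paths to the FSL-style gradient table.
#' @param motion_tsv Optional path to a ground-truth motion TSV.
#' @param name Scheme label.
#' @return A [dwi_series].
#' @export
read_dwi_series <- function(nii, bval, bvec, motion_tsv = NULL,
                            name = "scheme") {
  img <- RNifti::readNifti(nii)
  arr <- array(as.numeric(img), dim(img))
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  scheme <- read_bvalbvec(bval, bvec, name)
  motion <- if (!is.null(motion_tsv)) read_motion_tsv(motion_tsv) else NULL
  dwi_series(pmax(arr, 0), unclass(aff)[1:4, 1:4], scheme, motion)
}
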