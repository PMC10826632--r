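# Internal helpers: brain masking and small array utilities.

# Otsu's threshold on a numeric vector (maximizes between-class variance).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# 3x3x3 max/min filters via shifted copies (used for morphological closing).
shift3 <- function(a, s) {
  d <- dim(a)
  out <- array(0, d)
  src <- lapply(1:3, function(k) {
    i <- seq_len(d[k]) - s[k]
    i[i < 1L] <- 1L
    i[i > d[k]] <- d[k]
    i
  })
  out[] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

morph3 <- function(mask, fun) {
  acc <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    acc <- fun(acc, shift3(mask, c(dx, dy, dz)))
  }
  acc
}

#' Compute a brain mask from a b=0 volume
#'
#' Otsu threshold on the intensity histogram followed by one morphological
#' closing (dilation then erosion with a 3^3 structuring element).
#'
#' @param volume 3-D numeric array.
#' @return Logical 3-D array.
#' @export
make_brain_mask <- function(volume) {
  thr <- otsu_threshold(as.numeric(volume))
  m <- (volume > thr) * 1
  m <- morph3(m, pmax)   # dilate
  m <- morph3(m, pmin)   # erode
  m > 0.5
}

# Gaussian smoothing of a 3-D array, sigma in voxels.
gauss_smooth3 <- function(vol, sigma) {
  d <- dim(vol)
  out <- .gauss_smooth3_cpp(as.numeric(vol), as.integer(d), sigma)
  array(out, d)
}

# Block-mean 2x downsample of a 3-D array.
downsample2 <- function(vol) {
  d <- dim(vol)
  out <- .downsample2_cpp(as.numeric(vol), as.integer(d))
  array(out, attr(out, "odim"))
}
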