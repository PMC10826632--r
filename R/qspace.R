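#' Construct a q-space sampling scheme
#'
#' A sampling scheme is the ordered list of b-values (s/mm^2) and unit
#' gradient directions that defines a dMRI acquisition. b=0 volumes carry a
#' zero direction vector.
#'
#' @param bvals Numeric vector of b-values, one per volume (s/mm^2, >= 0).
#' @param bvecs Numeric matrix with one row per volume and 3 columns; rows for
#'   b>0 volumes must have unit norm, rows for b=0 volumes must be zero.
#' @param name Free-text label.
#' @return An object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(bvals, bvecs, name = "scheme") {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != length(bvals))
    stop("bvals and bvecs must describe the same number of volumes")
  if (ncol(bvecs) != 3L)
    stop("bvecs must have 3 columns")
  if (any(bvals < 0))
    stop("b-values must be non-negative")
  nrm <- sqrt(rowSums(bvecs^2))
  b0 <- bvals == 0
  if (any(abs(nrm[!b0] - 1) > 1e-6))
    stop("gradient directions for b>0 volumes must have unit norm")
  if (any(nrm[b0] > 1e-6))
    stop("b=0 volumes must have a zero direction vector")
  structure(list(bvals = bvals, bvecs = bvecs, name = name),
            class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("<sampling_scheme '%s'> %d volumes (%d b=0, %d b>0), max b = %g s/mm^2\n",
              x$name, length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0),
              max(x$bvals)))
  invisible(x)
}

#' @export
length.sampling_scheme <- function(x) length(x$bvals)

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Spread unit directions by electrostatic repulsion
#'
#' Minimizes a Coulomb-type energy over antipodally symmetric point pairs on
#' the unit sphere, starting from a seeded random configuration. Used to build
#' shelled schemes with well-dispersed directions.
#'
#' @param n Number of directions.
#' @param seed Integer seed (deterministic output).
#' @param iters Gradient-descent iterations.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
disperse_directions <- function(n, seed = 0, iters = 150L) {
  p <- with_seed(seed, {
    m <- matrix(rnorm(3 * n), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
  if (n == 1L) return(p)
  step0 <- 0.1
  for (it in seq_len(iters)) {
    f <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(-p[-i, , drop = FALSE], 2, p[i, ], "+")   # p_i - p_j
      d2 <- sweep(p[-i, , drop = FALSE], 2, p[i, ], "+")    # p_i + p_j
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-6)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-6)
      f[i, ] <- colSums(d1 / r1^3) + colSums(d2 / r2^3)
    }
    # project onto tangent plane and take a normalized decaying step
    f <- f - p * rowSums(f * p)
    mf <- max(sqrt(rowSums(f^2)))
    if (mf < 1e-12) break
    p <- p + (step0 * (1 - it / (iters + 1))) * f / mf
    p <- p / sqrt(rowSums(p^2))
  }
  p
}

# Antipodally-identified q-space distances from each row of q to the single
# point p (1 x 3).
antipodal_dist <- function(q, p) {
  d1 <- sqrt(rowSums(sweep(q, 2, p, "-")^2))
  d2 <- sqrt(rowSums(sweep(q, 2, p, "+")^2))
  pmin(d1, d2)
}

# Half-sphere Cartesian lattice of q-space indices with |q| <= qmax_index.
dsi_lattice <- function(qmax_index = 5L) {
  g <- expand.grid(i = -qmax_index:qmax_index, j = -qmax_index:qmax_index,
                   k = -qmax_index:qmax_index)
  r2 <- g$i^2 + g$j^2 + g$k^2
  keep <- r2 > 0 & r2 <= qmax_index^2 &
    (g$k > 0 | (g$k == 0 & g$j > 0) | (g$k == 0 & g$j == 0 & g$i > 0))
  as.matrix(g[keep, , drop = FALSE])
}

# Interleave n_b0 b=0 volumes evenly through a block of n_dwi b>0 volumes.
interleave_b0 <- function(bvals, bvecs, n_b0) {
  n <- length(bvals) + n_b0
  pos_b0 <- unique(round(seq(1, n, length.out = n_b0)))
  out_b <- numeric(n)
  out_v <- matrix(0, n, 3)
  dwi_pos <- setdiff(seq_len(n), pos_b0)
  out_b[dwi_pos] <- bvals
  out_v[dwi_pos, ] <- bvecs
  list(bvals = out_b, bvecs = out_v)
}

#' Build one of the benchmark sampling schemes
#'
#' Four named designs are available: two multi-shelled schemes (`ABCD`: 96 b>0
#' volumes, max b 3000; `HCP`: 270 b>0 volumes, max b 3000), a Cartesian DSI
#' half-sphere grid (`DSIQ5`: 257 b>0 volumes on the |q-index| <= 5 lattice,
#' max b 5000) and a sparse random Cartesian subset (`HASC55`: 55 lattice
#' points, max b 5000). Shelled directions are spread by electrostatic
#' repulsion; the HASC55 subset is a seeded random draw constrained to retain
#' the outermost lattice radius and at least three distinct b-values.
#'
#' @param name One of `"ABCD"`, `"HCP"`, `"DSIQ5"`, `"HASC55"`.
#' @param seed Integer seed controlling direction dispersion / subset draws.
#' @return A [sampling_scheme].
#' @export
make_scheme <- function(name = c("ABCD", "HCP", "DSIQ5", "HASC55"), seed = 0) {
  if (!is.character(name) || !(name[1] %in% c("ABCD", "HCP", "DSIQ5", "HASC55")))
    stop("unknown scheme name; valid labels are ABCD, HCP, DSIQ5, HASC55")
  name <- match.arg(name)
  if (name %in% c("ABCD", "HCP")) {
    shells <- if (name == "ABCD")
      list(b = c(500, 1000, 2000, 3000), n = c(6, 15, 15, 60), n_b0 = 7L)
    else
      list(b = c(1000, 2000, 3000), n = c(90, 90, 90), n_b0 = 9L)
    bv <- NULL; bb <- NULL
    for (s in seq_along(shells$b)) {
      dirs <- disperse_directions(shells$n[s], seed = seed + 131L * s)
      bv <- rbind(bv, dirs)
      bb <- c(bb, rep(shells$b[s], shells$n[s]))
    }
    ord <- with_seed(seed + 17L, sample.int(length(bb)))
    mix <- interleave_b0(bb[ord], bv[ord, , drop = FALSE], shells$n_b0)
    return(sampling_scheme(mix$bvals, mix$bvecs, name))
  }
  bmax <- 5000
  lat <- dsi_lattice(5L)
  r2 <- rowSums(lat^2)
  if (name == "HASC55") {
    # homogeneous 55-point subset of the grid: seeded random start, then
    # greedy farthest-point (maximin) selection under the antipodal q-space
    # metric, so the subset has no large unsampled holes — the defining
    # property of the homogeneous-angular-sampling CS-DSI schemes
    qall <- sqrt(bmax * r2 / 25) * (lat / sqrt(r2))
    pick <- with_seed(seed + 907L, {
      chosen <- sample.int(nrow(lat), 1L)
      dmin <- antipodal_dist(qall, qall[chosen, , drop = FALSE])
      while (length(chosen) < 55L) {
        nxt <- which.max(dmin)
        chosen <- c(chosen, nxt)
        dmin <- pmin(dmin, antipodal_dist(qall, qall[nxt, , drop = FALSE]))
      }
      chosen
    })
    lat <- lat[pick, , drop = FALSE]
    r2 <- r2[pick]
    n_b0 <- 7L
  } else n_b0 <- 7L
  b <- bmax * r2 / 25
  u <- lat / sqrt(r2)
  mix <- interleave_b0(b, u, n_b0)
  sampling_scheme(mix$bvals, mix$bvecs, name)
}

#' q-space vectors of a scheme
#'
#' Maps each volume to its q-space point `q = sqrt(b) * bvec` (units
#' sqrt(s)/mm; the conventional 1/(2*pi) factor is omitted, which only rescales
#' all radii and is immaterial for neighbor search and basis fitting). b=0
#' volumes map to the origin.
#'
#' @param scheme A [sampling_scheme].
#' @return A matrix (volumes x 3).
#' @export
qvectors <- function(scheme) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  sqrt(scheme$bvals) * scheme$bvecs
}

#' Cluster b-values into shells
#'
#' Greedily clusters sorted b>0 values whose relative spread stays within
#' `tol` of the running cluster mean. The scheme counts as shelled when every
#' nonzero shell holds at least `min_directions` volumes and consecutive shell
#' b-values are separated by more than `tol` relative to the larger one.
#'
#' @param scheme A [sampling_scheme].
#' @param tol Fractional b-value tolerance (default 0.1).
#' @param min_directions Minimum directions per shell for shelled status.
#' @return A list with `shell_id` (0 = b=0), `shell_b`, `is_shelled`.
#' @export
detect_shells <- function(scheme, tol = 0.1, min_directions = 6L) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  b <- scheme$bvals
  shell_id <- integer(length(b))
  pos <- which(b > 0)
  if (length(pos) == 0)
    return(list(shell_id = shell_id, shell_b = 0, is_shelled = FALSE))
  ord <- pos[order(b[pos])]
  cl <- integer(length(ord))
  means <- numeric(0)
  counts <- integer(0)
  for (t in seq_along(ord)) {
    bv <- b[ord[t]]
    k <- length(means)
    if (k > 0 && abs(bv - means[k]) <= tol * means[k]) {
      means[k] <- (means[k] * counts[k] + bv) / (counts[k] + 1L)
      counts[k] <- counts[k] + 1L
      cl[t] <- k
    } else {
      means <- c(means, bv)
      counts <- c(counts, 1L)
      cl[t] <- k + 1L
    }
  }
  shell_id[ord] <- cl
  sep_ok <- length(means) < 2 ||
    all(diff(means) / means[-1] > tol)
  is_shelled <- all(counts >= min_directions) && sep_ok
  list(shell_id = shell_id, shell_b = c(0, means), is_shelled = is_shelled)
}

#' Nearest q-space neighbor of each diffusion-weighted volume
#'
#' For every b>0 volume, finds the other b>0 volume at minimal q-space
#' distance under antipodal identification,
#' `d(i, j) = min(|q_i - q_j|, |q_i + q_j|)` (the dMRI magnitude signal is
#' antipodally symmetric). Ties resolve to the lower volume index.
#'
#' @param scheme A [sampling_scheme].
#' @return A data.frame with columns `i`, `j` (volume indices) and `distance`;
#'   one row per b>0 volume.
#' @export
nearest_qspace_neighbors <- function(scheme) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  q <- qvectors(scheme)
  pos <- which(scheme$bvals > 0)
  if (length(pos) < 2)
    stop("need at least two b>0 volumes for neighbor search")
  qp <- q[pos, , drop = FALSE]
  g <- tcrossprod(qp)
  n2 <- diag(g)
  d_minus <- outer(n2, n2, "+") - 2 * g
  d_plus <- outer(n2, n2, "+") + 2 * g
  d <- sqrt(pmax(pmin(d_minus, d_plus), 0))
  diag(d) <- Inf
  j <- apply(d, 1L, which.min)     # which.min takes the first (lowest) index
  data.frame(i = pos,
             j = pos[j],
             distance = d[cbind(seq_along(pos), j)])
}

#' Read an FSL-style bval/bvec pair
#'
#' @param bval_path,bvec_path Paths to whitespace-separated text files; bvec is
#'   row-major (3 rows of x, y, z components).
#' @param name Label for the resulting scheme.
#' @return A [sampling_scheme].
#' @export
read_bvalbvec <- function(bval_path, bvec_path, name = "scheme") {
  bvals <- scan(bval_path, quiet = TRUE)
  m <- as.matrix(read.table(bvec_path))
  if (nrow(m) != 3)
    stop("bvec file must have exactly 3 rows")
  sampling_scheme(bvals, t(m), name)
}

#' Write an FSL-style bval/bvec pair
#'
#' @param scheme A [sampling_scheme].
#' @param bval_path,bvec_path Output paths.
#' @export
write_bvalbvec <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  rows <- apply(t(scheme$bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " "))
  writeLines(rows, bvec_path)
  invisible(NULL)
}
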