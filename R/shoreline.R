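compose_tf <- function(A, B) A %*% B           # apply B, then A
invert_tf <- function(A) solve(A)

#' SHORELine head-motion correction
#'
#' Full correction loop for a DWI series on any scheme with at least two
#' distinct nonzero b-values:
#'
#' 1. All b=0 volumes are rigidly registered to the first b=0 volume, the
#'    transforms are re-anchored to the consensus (componentwise-median) b=0
#'    transform so the reference frame follows the majority of b=0 volumes,
#'    and a mean b=0 reference plus brain mask are built.
#' 2. For every b>0 volume an L2-regularized 3dSHORE basis is fit to all
#'    *other* b>0 volumes (resampled with their current transforms and
#'    normalized by the b=0 reference) and the predicted signal at the
#'    left-out q-space point becomes the registration target; the observed
#'    volume is registered to it, initialized at its current transform.
#' 3. Step 2 optionally repeats once, with targets refit from the round-1
#'    alignments.
#' 4. Each original volume is resampled exactly once with its final
#'    transform (single interpolation).
#'
#' @param series A [dwi_series].
#' @param model `"rigid"` (6-DOF, default) or `"affine"` (12-DOF).
#' @param iterations 1 or 2 passes over the b>0 volumes (default 2).
#' @param lambda Relative ridge weight for the 3dSHORE fit (default 5e-2;
#'   see the vignette for the choice).
#' @param radial_order 3dSHORE radial order. Default `NULL` picks the largest
#'   even order (at most 6) whose basis still has fewer functions than the
#'   number of b>0 samples; the angular-weighted ridge handles the remaining
#'   ill-conditioning of near-square designs.
#' @param zeta Optional fixed scale parameter; default data-driven via
#'   [estimate_zeta()].
#' @param mask Optional brain mask; default Otsu + closing on the mean b=0.
#' @param metric Registration metric, `"ncc"` (default) or `"nmi"`.
#' @param bound Soft per-volume motion bound (mm / degrees) passed to
#'   [register()]; default 10.
#' @param angular_weight Angular-order weighting of the ridge penalty (see
#'   [shore_fit_l2()]); 0 keeps the identity penalty.
#' @return An object of class `shoreline_result`: `series` (corrected),
#'   `motion` (estimated `motion_trace`), `metric` (per-volume final metric),
#'   `model`, `iterations`.
#' @export
shoreline_correct <- function(series, model = c("rigid", "affine"),
                              iterations = 2L, lambda = 5e-2,
                              radial_order = NULL, zeta = NULL, mask = NULL,
                              metric = "ncc", bound = 10,
                              angular_weight = 0.01, metric_sigma = 0.5) {
  stopifnot(inherits(series, "dwi_series"))
  model <- match.arg(model)
  if (!iterations %in% 1:2) stop("iterations must be 1 or 2")
  sch <- series$scheme
  sh <- detect_shells(sch)
  if (length(sh$shell_b) < 3)
    stop("SHORELine requires sampling schemes with at least two unique non-zero b-values")
  b0_idx <- which(sch$bvals == 0)
  dwi_idx <- which(sch$bvals > 0)
  if (length(b0_idx) == 0) stop("series has no b=0 volume")
  A <- series$affine
  d <- dim(series$data)[1:3]
  n <- dim(series$data)[4]
  vol <- function(i) series$data[, , , i]

  # --- step 1: b=0 alignment and reference -------------------------------
  first_b0 <- vol(b0_idx[1])
  b0_mask <- make_brain_mask(first_b0)
  b0_par <- matrix(0, length(b0_idx), 6)
  for (t in seq_along(b0_idx)[-1]) {
    r <- register(vol(b0_idx[t]), first_b0, A, model = "rigid",
                  mask = b0_mask, metric = metric, bound = bound,
                  metric_sigma = 1.0)
    b0_par[t, ] <- r$params
  }
  # consensus anchor: the largest cluster of mutually-agreeing b=0 transforms
  # (the unmoved majority) defines the reference frame; a plain median would
  # be pulled toward b=0 volumes that themselves carry simulated motion
  reanchor <- function(par) {
    n_b0 <- nrow(par)
    agree <- vapply(seq_len(n_b0), function(j) {
      dt <- sqrt(rowSums((par[, 1:3, drop = FALSE] -
                            matrix(par[j, 1:3], n_b0, 3, byrow = TRUE))^2))
      dr <- sqrt(rowSums((par[, 4:6, drop = FALSE] -
                            matrix(par[j, 4:6], n_b0, 3, byrow = TRUE))^2))
      sum(dt < 1 & dr < 1)
    }, numeric(1))
    j_star <- which.max(agree)
    dt <- sqrt(rowSums((par[, 1:3, drop = FALSE] -
                          matrix(par[j_star, 1:3], n_b0, 3, byrow = TRUE))^2))
    dr <- sqrt(rowSums((par[, 4:6, drop = FALSE] -
                          matrix(par[j_star, 4:6], n_b0, 3, byrow = TRUE))^2))
    subset <- par[dt < 1 & dr < 1, , drop = FALSE]
    anchor_inv <- invert_tf(rigid_matrix(apply(subset, 2, median)))
    lapply(seq_len(n_b0), function(t)
      compose_tf(rigid_matrix(par[t, ]), anchor_inv))
  }
  mean_b0 <- function(mats) {
    al <- vapply(seq_along(b0_idx), function(t)
      resample(vol(b0_idx[t]), mats[[t]], A), array(0, d))
    apply(array(al, c(d, length(b0_idx))), 1:3, mean)
  }
  b0_mats <- reanchor(b0_par)
  b0_ref <- mean_b0(b0_mats)
  if (length(b0_idx) > 1) {
    # second pass against the (sharper, less noisy) mean reference, then
    # re-anchor: reduces the common reference-frame error all volumes inherit
    for (t in seq_along(b0_idx)) {
      r <- register(vol(b0_idx[t]), b0_ref, A, model = "rigid",
                    init = matrix_to_params(b0_mats[[t]]),
                    metric = metric, bound = bound,
                    metric_sigma = 1.0)
      b0_par[t, ] <- r$params
    }
    b0_mats <- reanchor(b0_par)
    b0_ref <- mean_b0(b0_mats)
  }
  if (is.null(mask)) mask <- make_brain_mask(b0_ref)
  nvox <- sum(mask)
  # lightly smoothed normalization reference: its (shared) noise would
  # otherwise imprint a common pattern on every registration target
  ref <- gauss_smooth3(b0_ref, 0.75)[mask]
  ref[ref <= 0] <- 1

  # --- steps 2-3: leave-one-out targets and per-volume registration ------
  q <- qvectors(sch)[dwi_idx, , drop = FALSE]
  npar <- if (model == "rigid") 6L else 12L
  # in the anchored frame unmoved volumes need no correction: start at identity
  cur <- matrix(0, length(dwi_idx), npar)
  met <- numeric(length(dwi_idx))
  basis <- NULL
  for (it in seq_len(iterations)) {
    aligned <- matrix(0, length(dwi_idx), nvox)
    for (t in seq_along(dwi_idx)) {
      av <- resample(vol(dwi_idx[t]), transform_matrix(cur[t, ]), A)
      aligned[t, ] <- av[mask] / ref
    }
    if (is.null(basis)) {
      z <- if (is.null(zeta)) estimate_zeta(sch$bvals[dwi_idx],
                                            rowMeans(aligned)) else zeta
      if (is.null(radial_order)) {
        # largest even order whose basis still fits the sample count; the
        # angular-weighted ridge handles the remaining ill-conditioning
        nbf <- function(ro) (ro / 2 + 1) * (ro / 2 + 2) * (2 * ro + 3) / 6
        cand <- c(6L, 4L, 2L)
        radial_order <- cand[which(vapply(cand, nbf, numeric(1)) <=
                                     length(dwi_idx) - 3L)[1]]
        if (is.na(radial_order)) radial_order <- 2L
      }
      basis <- shore_basis(radial_order, z)
    }
    # anchor the radial extrapolation at q = 0 with the b=0 mean: without it,
    # schemes with sparse low-b coverage can invert the predicted contrast of
    # low-b volumes
    b0_row <- b0_ref[mask] / ref
    targets <- shore_loo_matrix(rbind(b0_row, aligned), basis,
                                rbind(c(0, 0, 0), q), lambda, angular_weight,
                                loo_rows = seq_len(nrow(aligned)) + 1L)
    for (t in seq_along(dwi_idx)) {
      tgt <- array(0, d)
      tgt[mask] <- targets[t, ] * ref
      r <- register(vol(dwi_idx[t]), tgt, A, model = model,
                    init = cur[t, ], mask = mask, metric = metric,
                    bound = bound, dilate_mask = FALSE,
                    metric_sigma = metric_sigma)
      cur[t, ] <- r$params
      met[t] <- r$metric
    }
  }

  # --- step 4: single-interpolation output -------------------------------
  out <- array(0, c(d, n))
  est <- identity_motion(n)
  for (t in seq_along(b0_idx)) {
    i <- b0_idx[t]
    out[, , , i] <- resample(vol(i), b0_mats[[t]], A)
    est[i, c("tx", "ty", "tz", "rx", "ry", "rz")] <-
      as.list(matrix_to_params(b0_mats[[t]]))
  }
  for (t in seq_along(dwi_idx)) {
    i <- dwi_idx[t]
    out[, , , i] <- resample(vol(i), transform_matrix(cur[t, ]), A)
    est[i, c("tx", "ty", "tz", "rx", "ry", "rz")] <- as.list(cur[t, 1:6])
  }
  est$moved <- rowSums(abs(as.matrix(
    est[, c("tx", "ty", "tz", "rx", "ry", "rz")]))) > 1e-8
  metric_all <- rep(NA_real_, n)
  metric_all[dwi_idx] <- met
  structure(list(series = dwi_series(pmax(out, 0), A, sch),
                 motion = est, metric = metric_all, model = model,
                 iterations = iterations, mask = mask, basis = basis),
            class = "shoreline_result")
}

#' @export
print.shoreline_result <- function(x, ...) {
  cat(sprintf("<shoreline_result> %s model, %d iteration(s), %d volumes; median NCC %.3f\n",
              x$model, x$iterations, nrow(x$motion),
              median(x$metric, na.rm = TRUE)))
  invisible(x)
}

#' Serialize a motion trace (true or estimated) to TSV
#'
#' Columns: `volume`, `tx`, `ty`, `tz` (mm), `rx`, `ry`, `rz` (degrees),
#' `moved`.
#' @param trace A `motion_trace`.
#' @param path Output path.
#' @export
write_motion_tsv <- function(trace, path) {
  write.table(as.data.frame(trace), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(NULL)
}

#' Read a motion-trace TSV written by [write_motion_tsv()]
#' @param path Input path.
#' @return A `motion_trace` data.frame.
#' @export
read_motion_tsv <- function(path) {
  tr <- read.table(path, header = TRUE, sep = "\t")
  class(tr) <- c("motion_trace", "data.frame")
  tr
}
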