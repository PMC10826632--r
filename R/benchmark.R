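scheme_info <- function() {
  data.frame(scheme = c("ABCD", "HCP", "DSIQ5", "HASC55"),
             type = c("shelled", "shelled", "cartesian", "random"),
             n_bpos = c(96L, 270L, 257L, 55L),
             max_b = c(3000, 3000, 5000, 5000))
}

#' Enumerate the full factorial benchmark plan
#'
#' Full-scale enumeration of every preprocessing run in the benchmark
#' design: for each shelled scheme (ABCD, HCP), Eddy with linear and
#' quadratic distortion models plus SHORELine with rigid and affine
#' transforms; for each non-shelled scheme (DSIQ5, HASC55), SHORELine only —
#' each crossed with MP-PCA denoising vs none, motion prevalence 15/30/50%,
#' and 30 replicate simulated scans per cell. Eddy rows are enumerated for
#' bookkeeping and external scoring but are never executed by this package
#' (Eddy only supports shelled schemes and is external software).
#'
#' @return A `benchmark_plan` data.frame with columns `scheme`, `algorithm`,
#'   `model`, `denoise`, `prevalence`, `replicate`, `n_bpos` (b>0 volumes per
#'   scan) and `series_seed` (shared by all runs of one simulated scan).
#' @export
build_full_plan <- function() {
  info <- scheme_info()
  rows <- list()
  for (s in seq_len(nrow(info))) {
    algos <- if (info$type[s] == "shelled")
      data.frame(algorithm = c("eddy", "eddy", "shoreline", "shoreline"),
                 model = c("linear", "quadratic", "rigid", "affine"))
    else
      data.frame(algorithm = c("shoreline", "shoreline"),
                 model = c("rigid", "affine"))
    g <- expand.grid(ai = seq_len(nrow(algos)),
                     denoise = c("mppca", "none"),
                     prevalence = c(0.15, 0.30, 0.50),
                     replicate = 1:30,
                     stringsAsFactors = FALSE)
    rows[[s]] <- data.frame(scheme = info$scheme[s],
                            algorithm = algos$algorithm[g$ai],
                            model = algos$model[g$ai],
                            denoise = g$denoise,
                            prevalence = g$prevalence,
                            replicate = g$replicate,
                            n_bpos = info$n_bpos[s],
                            stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, rows)
  # one simulated scan per (scheme, prevalence, replicate), reused across
  # algorithm/model/denoise combinations
  plan$series_seed <- as.integer(
    1000L * match(plan$scheme, info$scheme) +
      100L * round(plan$prevalence * 100) + plan$replicate)
  class(plan) <- c("benchmark_plan", "data.frame")
  plan
}

#' Margins of a benchmark plan
#'
#' Totals that characterize the factorial design: number of runs, number of
#' b>0 images processed, unique simulated series overall and per scheme, and
#' per-scheme b>0 volume totals.
#'
#' @param plan A plan from [build_full_plan()] (or a subset).
#' @return A list of totals.
#' @export
plan_margins <- function(plan) {
  key <- paste(plan$scheme, plan$prevalence, plan$replicate)
  per_scheme_runs <- table(plan$scheme)
  per_scheme_bpos <- tapply(plan$n_bpos, plan$scheme, sum)
  list(n_runs = nrow(plan),
       n_bpos_images = sum(plan$n_bpos),
       n_unique_series = length(unique(key)),
       series_per_scheme = tapply(key, plan$scheme,
                                  function(k) length(unique(k))),
       runs_per_scheme = per_scheme_runs,
       bpos_per_scheme = per_scheme_bpos)
}

#' Execute a (desk-scale) subset of the benchmark plan
#'
#' Runs each SHORELine row of `plan` end to end: simulate the scan with known
#' motion on the given phantom, optionally denoise, correct with
#' [shoreline_correct()], and score the run (motion-parameter mean error and
#' RMSE, NDC before/after correction, FWHM of the corrected mean b=0).
#' Failures are recorded per row and the run continues.
#'
#' @param plan A `benchmark_plan` subset containing only
#'   `algorithm == "shoreline"` rows.
#' @param phantom A [phantom_spec] (default 32^3 crossing-bundle phantom).
#' @param snr Simulation SNR (default 20).
#' @param iterations SHORELine iterations (default 2).
#' @param lambda Ridge weight passed to [shoreline_correct()].
#' @param seed Base seed combined with each row's `series_seed`.
#' @return A `data.frame` with one scored row per run.
#' @export
run_benchmark <- function(plan, phantom = phantom_spec(), snr = 20,
                          iterations = 2L, lambda = 5e-2, seed = 0L) {
  if (any(plan$algorithm != "shoreline"))
    stop("only algorithm == 'shoreline' rows can be executed; subset the plan")
  out <- plan
  out$mean_error_trans <- out$rmse_trans <- NA_real_
  out$mean_error_rot <- out$rmse_rot <- NA_real_
  out$ndc_raw <- out$ndc_corrected <- out$fwhm_b0 <- NA_real_
  out$status <- "ok"
  for (r in seq_len(nrow(plan))) {
    res <- tryCatch({
      sseed <- plan$series_seed[r] + seed
      scheme <- make_scheme(plan$scheme[r], seed = 0)
      mt <- sample_motion(length(scheme), plan$prevalence[r], seed = sseed)
      series <- simulate_series(phantom, scheme, mt, snr = snr, seed = sseed)
      if (plan$denoise[r] == "mppca")
        series <- denoise_mppca(series)$series
      corr <- shoreline_correct(series, model = plan$model[r],
                                iterations = iterations, lambda = lambda)
      err <- motion_error(corr$motion, mt)
      mask <- corr$mask
      b0 <- which(scheme$bvals == 0)
      mb0 <- apply(corr$series$data[, , , b0, drop = FALSE], 1:3, mean)
      fw <- estimate_fwhm(mb0, mask, voxel_size = phantom$voxel_size)
      list(met = err$translation$mean_error, rt = err$translation$rmse,
           mer = err$rotation$mean_error, rr = err$rotation$rmse,
           n_raw = ndc(series, mask), n_cor = ndc(corr$series, mask),
           fw = fw$fwhm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$status[r] <- conditionMessage(res)
    } else {
      out$mean_error_trans[r] <- res$met
      out$rmse_trans[r] <- res$rt
      out$mean_error_rot[r] <- res$mer
      out$rmse_rot[r] <- res$rr
      out$ndc_raw[r] <- res$n_raw
      out$ndc_corrected[r] <- res$n_cor
      out$fwhm_b0[r] <- res$fw
    }
  }
  class(out) <- "data.frame"
  out
}
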