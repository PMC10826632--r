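test_that("basis size follows the even-order counting formula", {
  for (ro in c(0, 2, 4, 6, 8)) {
    n_expect <- (ro / 2 + 1) * (ro / 2 + 2) * (2 * ro + 3) / 6
    expect_equal(nrow(shore_basis(ro)$index), n_expect)
  }
  expect_error(shore_basis(3), "even")
  expect_error(shore_basis(6, zeta = -1), "positive")
})

test_that("design matrix has the required structure", {
  b <- shore_basis(6, 700)
  q <- rbind(c(0, 0, 0), c(sqrt(5000), 0, 0), c(0, sqrt(1200), 0))
  M <- shore_design_matrix(b, q)
  # q = 0 row: only l = 0 columns nonzero
  expect_true(all(M[1, b$index$l > 0] == 0))
  expect_true(all(M[1, b$index$l == 0] != 0))
  expect_true(all(is.finite(M)))
  # doubling zeta rescales the radial Gaussian as exp(-q^2/(4 zeta)) and the
  # normalization as (1/2)^(3/4), checked on the (n=0, l=0) column
  b2 <- shore_basis(6, 1400)
  M2 <- shore_design_matrix(b2, q)
  j <- which(b$index$n == 0 & b$index$l == 0)
  q2 <- 5000
  expect_equal(M2[2, j] / M[2, j], 2^(-3 / 4) * exp(q2 / (4 * 700)),
               tolerance = 1e-10)
  expect_error(shore_design_matrix(b, matrix(numeric(0), 0, 3)), "nonempty")
})

test_that("unregularized fit reproduces signals in the column span", {
  b <- shore_basis(4, 700)
  sch <- make_scheme("HASC55")
  q <- qvectors(sch)[sch$bvals > 0, ]
  Phi <- shore_design_matrix(b, q)
  cset <- with_seed(11, matrix(rnorm(ncol(Phi) * 2), ncol = 2))
  fit <- shore_fit_l2(Phi %*% cset, b, q, lambda = 0)
  expect_lt(max(abs(fit$design %*% fit$coefficients - Phi %*% cset)), 1e-8)
})

test_that("ridge shrinks coefficients monotonically and validates input", {
  b <- shore_basis(4, 700)
  sch <- make_scheme("HASC55")
  pos <- sch$bvals > 0
  q <- qvectors(sch)[pos, ]
  E <- matrix(exp(-sch$bvals[pos] * 9e-4), ncol = 1)
  norms <- vapply(c(0, 1e-4, 1e-2, 1, 100), function(l)
    sqrt(sum(shore_fit_l2(E, b, q, lambda = l)$coefficients^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
  # residual norm grows with lambda (shrinkage trades fit for stability)
  res <- vapply(c(0, 1e-2, 1, 100), function(l) {
    f <- shore_fit_l2(E, b, q, lambda = l)
    sum((f$design %*% f$coefficients - E)^2)
  }, numeric(1))
  expect_true(all(diff(res) >= -1e-10))
  expect_error(shore_fit_l2(E, b, q, lambda = -1), "non-negative")
  # more basis functions than samples without ridge is rank-deficient
  b6 <- shore_basis(6, 700)
  few <- 1:10
  expect_error(shore_fit_l2(E[few, , drop = FALSE], b6, q[few, ], lambda = 0),
               "lambda > 0")
})

test_that("isotropic Gaussian decay is fit within 1% at radial order 6", {
  d <- 0.9e-3
  sch <- make_scheme("HASC55")
  pos <- sch$bvals > 0
  E <- exp(-sch$bvals[pos] * d)
  b <- shore_basis(6, 1 / (2 * d))
  q <- qvectors(sch)[pos, ]
  fit <- shore_fit_l2(matrix(E, ncol = 1), b, q, lambda = 1e-8)
  pred <- drop(fit$design %*% fit$coefficients)
  expect_lt(max(abs(pred - E) / E), 0.01)
  # prediction at q = 0 recovers the E(0) = 1 normalization
  expect_equal(predict_at(fit, c(0, 0, 0)), 1, tolerance = 0.05,
               ignore_attr = TRUE)
  # antipodal q-points give identical predictions (even-l basis)
  qa <- c(sqrt(2200), 0, 0)
  expect_equal(predict_at(fit, qa), predict_at(fit, -qa))
})

test_that("zeta heuristic recovers the mono-exponential diffusivity", {
  bv <- c(500, 1000, 2000, 3000)
  for (md in c(0.7e-3, 1.5e-3)) {
    z <- estimate_zeta(bv, exp(-bv * md))
    expect_equal(z, 1 / (2 * md), tolerance = 1e-6)
  }
})

test_that("leave-one-out prediction is accurate on noiseless phantom data", {
  ph <- one_bundle_phantom()
  sch <- make_scheme("HASC55")
  ser <- simulate_series(ph, sch)
  b0 <- apply(ser$data[, , , sch$bvals == 0, drop = FALSE], 1:3, mean)
  mask <- b0 > 0.7 * median(b0[b0 > 100])
  ref_scale <- mean(b0[mask])
  pos <- which(sch$bvals > 0)
  nr <- vapply(pos[seq(1, 55, by = 5)], function(lo) {
    pred <- loo_predict(ser, lo, mask = mask)
    truth <- ser$data[, , , lo]
    sqrt(mean((pred[mask] - truth[mask])^2)) / ref_scale
  }, numeric(1))
  expect_lt(median(nr), 0.05)
  expect_lt(max(nr), 0.2)   # isolated q-points are honest extrapolations
})

test_that("leave-one-out prediction of a duplicated q-point matches its twin", {
  ph <- tiny_phantom()
  d1 <- disperse_directions(10, seed = 4)
  d2 <- disperse_directions(10, seed = 5)
  # volume 23 duplicates the q-point of volume 13 (same b, same direction)
  sch <- sampling_scheme(c(0, 0, rep(1000, 10), rep(2500, 10), 2500),
                         rbind(matrix(0, 2, 3), d1, d2, d2[1, ]), "dup")
  ser <- simulate_series(ph, sch)
  dup_of <- 13  # first b=2500 volume; volume 23 duplicates its q-point
  pred <- loo_predict(ser, 23, lambda = 1e-4)
  b0 <- apply(ser$data[, , , 1:2], 1:3, mean)
  mask <- make_brain_mask(b0)
  expect_gt(cor(pred[mask], ser$data[, , , dup_of][mask]), 0.99)
})

test_that("leave-one-out prediction rejects invalid requests", {
  ph <- tiny_phantom()
  ser <- simulate_series(ph, two_shell_scheme(4, 4, n_b0 = 2))
  expect_error(loo_predict(ser, 1), "b>0")
  single <- sampling_scheme(c(0, rep(1000, 8)),
                            rbind(c(0, 0, 0), disperse_directions(8, seed = 6)))
  ser1 <- simulate_series(ph, single)
  expect_error(loo_predict(ser1, 2), "two unique non-zero")
})

test_that("predictions scale with global intensity scaling of the series", {
  ph <- tiny_phantom()
  sch <- two_shell_scheme(6, 6, n_b0 = 2)
  ser <- simulate_series(ph, sch, snr = 40, seed = 3)
  scaled <- dwi_series(ser$data * 7.3, ser$affine, sch)
  p1 <- loo_predict(ser, 4, lambda = 1e-3)
  p2 <- loo_predict(scaled, 4, lambda = 1e-3)
  expect_equal(p2, p1 * 7.3, tolerance = 1e-8)
})

test_that("ridge predictions vary continuously with lambda", {
  ph <- tiny_phantom()
  sch <- two_shell_scheme(6, 6, n_b0 = 2)
  ser <- simulate_series(ph, sch, snr = 40, seed = 4)
  p1 <- loo_predict(ser, 4, lambda = 1e-3)
  p2 <- loo_predict(ser, 4, lambda = 1e-3 * (1 + 1e-6))
  expect_lt(max(abs(p1 - p2)), 1e-4 * max(p1))
})
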