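test_that("rigid parameter/matrix round-trip is exact", {
  for (seed in 1:5) {
    p <- with_seed(seed, c(runif(3, -5, 5), runif(3, -5, 5)))
    ctr <- with_seed(seed + 50, runif(3, -10, 10))
    M <- rigid_matrix(p, center = ctr)
    expect_lt(max(abs(matrix_to_params(M, center = ctr) - p)), 1e-10)
    # group closure: compose with inverse gives identity
    expect_lt(max(abs(M %*% solve(M) - diag(4))), 1e-12)
    R <- M[1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
  }
})

test_that("identity resampling with linear interpolation is bit-exact", {
  ph <- tiny_phantom()
  v <- simulate_series(ph, sampling_scheme(0, rbind(c(0, 0, 0))),
                       snr = 15, seed = 1)$data[, , , 1]
  A <- grid_affine(ph)
  expect_identical(resample(v, diag(4), A), v)
})

test_that("linear interpolation reproduces affine intensity ramps", {
  d <- c(16, 16, 16)
  ramp <- array(0, d)
  ramp[] <- as.matrix(expand.grid(1:16, 1:16, 1:16)) %*% c(1, 2, -0.5)
  A <- rbind(cbind(diag(2, 3), -(d - 1)), c(0, 0, 0, 1))
  out <- resample(ramp, rigid_matrix(c(2, 0, 0, 0, 0, 0)), A)
  # interior voxels shift exactly by one voxel along x
  expect_equal(out[2:14, , ], ramp[3:15, , ], tolerance = 1e-12)
})

test_that("one composed resample beats two sequential resamples", {
  ph <- tiny_phantom()
  v <- simulate_series(ph, sampling_scheme(0, rbind(c(0, 0, 0))),
                       snr = 15, seed = 2)$data[, , , 1]
  A <- grid_affine(ph)
  Tf <- rigid_matrix(c(1.3, 0, 0, 0, 0, 0))
  Tb <- solve(Tf)
  core <- array(FALSE, dim(v))
  core[4:13, 4:13, 4:13] <- TRUE
  two_step <- resample(resample(v, Tf, A), Tb, A)
  one_step <- resample(v, Tf %*% Tb, A)   # identity, single interpolation
  err2 <- max(abs(two_step[core] - v[core]))
  err1 <- max(abs(one_step[core] - v[core]))
  expect_equal(err1, 0)
  expect_lt(err1, err2 / 10)
})

test_that("registering a volume to itself returns the identity", {
  ph <- tiny_phantom()
  v <- simulate_series(ph, sampling_scheme(0, rbind(c(0, 0, 0))),
                       snr = 30, seed = 3)$data[, , , 1]
  r <- register(v, v, grid_affine(ph))
  expect_lt(max(abs(r$params[1:3])), 0.05)
  expect_lt(max(abs(r$params[4:6])), 0.05)
  expect_gt(r$metric, 0.999)
})

test_that("known rigid transforms are recovered and invert on swap", {
  ph <- phantom_spec()
  sch <- sampling_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  ref <- simulate_series(ph, sch)$data[, , , 1]
  A <- grid_affine(ph)
  tp <- c(2, -1, 0, 0, 0, 3)
  mt <- set_motion(identity_motion(2), 1, tp)
  mov <- simulate_series(ph, sch, mt)$data[, , , 1]
  fwd <- register(mov, ref, A)
  expect_lt(max(abs(fwd$params[1:3] - tp[1:3])), 0.2)
  expect_lt(max(abs(fwd$params[4:6] - tp[4:6])), 0.2)
  # swapping moving and fixed yields the inverse transform
  bwd <- register(ref, mov, A, mask = make_brain_mask(mov))
  inv <- matrix_to_params(solve(fwd$matrix))
  expect_lt(max(abs(bwd$params - inv)), 0.4)
})

test_that("the achieved metric never falls below the value at init", {
  ph <- tiny_phantom()
  sch <- sampling_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  ref <- simulate_series(ph, sch, snr = 10, seed = 4)$data[, , , 1]
  mt <- set_motion(identity_motion(2), 1, c(3, -2, 1, 2, -2, 2))
  mov <- simulate_series(ph, sch, mt, snr = 10, seed = 5)$data[, , , 1]
  A <- grid_affine(ph)
  mask <- make_brain_mask(ref)
  r0 <- register(mov, ref, A, init = c(3, -2, 1, 2, -2, 2), mask = mask)
  # starting from truth, the optimizer must not end anywhere worse
  start <- register(mov, ref, A, init = r0$params, mask = mask)
  expect_gte(start$metric, r0$metric - 1e-8)
})

test_that("registration rejects degenerate inputs", {
  v <- array(1, c(12, 12, 12))
  A <- diag(4)
  expect_error(register(v, v, A, mask = array(FALSE, dim(v))), "empty")
  bad <- v
  bad[1] <- NA
  expect_error(register(bad, v, A, mask = v > 0), "finite")
  expect_error(register(v, array(1, c(10, 10, 10)), A), "grid")
  expect_error(register(v, v, A, mask = v > 0, init = numeric(3)), "length")
})

test_that("affine model reduces to rigid on rigid-only misalignment", {
  ph <- phantom_spec()
  sch <- sampling_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  ref <- simulate_series(ph, sch)$data[, , , 1]
  mt <- set_motion(identity_motion(2), 1, c(2, 0, -1, 0, 0, 2))
  mov <- simulate_series(ph, sch, mt)$data[, , , 1]
  r <- register(mov, ref, grid_affine(ph), model = "affine")
  expect_length(r$params, 12)
  expect_lt(max(abs(r$params[1:6] - c(2, 0, -1, 0, 0, 2))), 0.35)
  expect_lt(max(abs(r$params[7:9])), 0.02)   # log-scales near 0
  expect_lt(max(abs(r$params[10:12])), 0.02) # shears near 0
})
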