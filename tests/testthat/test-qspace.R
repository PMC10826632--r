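test_that("named schemes reproduce the published design counts", {
  specs <- list(ABCD = c(96, 3000, TRUE), HCP = c(270, 3000, TRUE),
                DSIQ5 = c(257, 5000, FALSE), HASC55 = c(55, 5000, FALSE))
  for (nm in names(specs)) {
    sch <- make_scheme(nm)
    expect_equal(sum(sch$bvals > 0), specs[[nm]][1], info = nm)
    expect_equal(max(sch$bvals), specs[[nm]][2], info = nm)
    expect_gte(sum(sch$bvals == 0), 1)
    expect_equal(detect_shells(sch)$is_shelled, as.logical(specs[[nm]][3]),
                 info = nm)
    nrm <- sqrt(rowSums(sch$bvecs^2))
    expect_true(all(abs(nrm[sch$bvals > 0] - 1) < 1e-6))
    # deterministic given (name, seed)
    expect_identical(sch, make_scheme(nm, seed = 0))
  }
  expect_error(make_scheme("XYZ"), "ABCD")
})

test_that("DSIQ5 q-vectors lie on the Cartesian lattice", {
  sch <- make_scheme("DSIQ5")
  q <- qvectors(sch)[sch$bvals > 0, ]
  # lattice spacing: |q| of a unit q-index point is sqrt(5000/25)
  unit <- sqrt(5000 / 25)
  qi <- q / unit
  expect_lt(max(abs(qi - round(qi))), 1e-9)
  expect_lte(max(rowSums(round(qi)^2)), 25)
})

test_that("q-vectors follow the sqrt(b) convention", {
  sch <- sampling_scheme(c(0, 3000, 3000),
                         rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)))
  q <- qvectors(sch)
  expect_equal(q[1, ], c(0, 0, 0))
  expect_equal(q[2, ], c(sqrt(3000), 0, 0))
  expect_equal(q[3, ], -q[2, ])   # antipodal directions map to antipodes
})

test_that("scheme construction validates its invariants", {
  expect_error(sampling_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 1, 0))),
               "unit norm")
  expect_error(sampling_scheme(c(0), rbind(c(0.5, 0, 0))), "zero direction")
  expect_error(sampling_scheme(c(-5), rbind(c(0, 0, 0))), "non-negative")
  expect_error(sampling_scheme(c(0, 1000), rbind(c(0, 0, 0))), "same number")
})

test_that("shell clustering finds single and multiple shells", {
  one <- sampling_scheme(c(0, rep(1000, 30)),
                         rbind(c(0, 0, 0), disperse_directions(30, seed = 3)))
  sh <- detect_shells(one)
  expect_equal(length(sh$shell_b), 2)  # shell 0 plus one nonzero shell
  expect_true(sh$is_shelled)
  expect_true(all(sh$shell_id[one$bvals == 0] == 0))
  # b-values within the tolerance merge into one shell
  jit <- sampling_scheme(c(0, rep(c(980, 1000, 1020), 10)),
                         rbind(c(0, 0, 0), disperse_directions(30, seed = 3)))
  expect_equal(length(detect_shells(jit)$shell_b), 2)
})

test_that("nearest q-space neighbors match a brute-force oracle", {
  # brute force with antipodal identification
  brute <- function(sch) {
    q <- qvectors(sch)
    pos <- which(sch$bvals > 0)
    vapply(pos, function(i) {
      d <- vapply(pos, function(j) {
        if (i == j) return(Inf)
        min(sqrt(sum((q[i, ] - q[j, ])^2)), sqrt(sum((q[i, ] + q[j, ])^2)))
      }, numeric(1))
      pos[which.min(d)]
    }, numeric(1))
  }
  for (seed in 1:3) {
    u <- with_seed(seed, {
      m <- matrix(rnorm(36), ncol = 3)
      m / sqrt(rowSums(m^2))
    })
    b <- with_seed(seed + 100, round(runif(12, 500, 5000)))
    sch <- sampling_scheme(c(0, b), rbind(c(0, 0, 0), u))
    nb <- nearest_qspace_neighbors(sch)
    expect_equal(nb$j, brute(sch))
    # every b>0 volume appears as a source exactly once
    expect_setequal(nb$i, which(sch$bvals > 0))
  }
})

test_that("neighbor search handles collinear, duplicate and antipodal cases", {
  # 3 collinear q-points at radii 1, 2, 10 (b = 1, 4, 100)
  sch <- sampling_scheme(c(1, 4, 100),
                         rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0)))
  nb <- nearest_qspace_neighbors(sch)
  expect_equal(nb$j, c(2, 1, 2))
  # duplicated direction: distance 0, tie broken to lower index
  dup <- sampling_scheme(c(1000, 1000, 2000),
                         rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  nbd <- nearest_qspace_neighbors(dup)
  expect_equal(nbd$j[1:2], c(2, 1))
  expect_equal(nbd$distance[1], 0)
  # antipodal duplicate: also distance 0
  anti <- sampling_scheme(c(1000, 1000, 2000),
                          rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0)))
  expect_equal(nearest_qspace_neighbors(anti)$distance[1], 0)
  expect_error(nearest_qspace_neighbors(
    sampling_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))), "two b>0")
})

test_that("bval/bvec files round-trip through FSL text format", {
  sch <- make_scheme("HASC55")
  td <- withr::local_tempdir()
  write_bvalbvec(sch, file.path(td, "x.bval"), file.path(td, "x.bvec"))
  back <- read_bvalbvec(file.path(td, "x.bval"), file.path(td, "x.bvec"))
  expect_equal(back$bvals, sch$bvals)
  expect_equal(back$bvecs, sch$bvecs, ignore_attr = TRUE, tolerance = 1e-12)
  # bvec file is row-major: 3 rows
  expect_length(readLines(file.path(td, "x.bvec")), 3)
})
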