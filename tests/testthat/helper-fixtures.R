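# Shared fixtures: all synthetic, built in code at test time.

# Small phantom for fast unit tests (16^3 voxels, 2 mm).
tiny_phantom <- function() {
  phantom_spec(dim = c(16L, 16L, 16L), voxel_size = 2,
               head_radii = c(12, 10, 9), rim = 2.5,
               bundles = list(
                 list(axis = c(1, 0, 0), radius = 3.5, fraction = 0.8,
                      offset = c(0, 2, 2)),
                 list(axis = c(0.5, sqrt(0.75) * 0.8, 0.48), radius = 3,
                      fraction = 0.8, offset = c(2, -2, -1))))
}

# Compact two-shell scheme with dispersed directions.
two_shell_scheme <- function(n1 = 12L, n2 = 12L, b1 = 1000, b2 = 2500,
                             n_b0 = 3L) {
  d1 <- disperse_directions(n1, seed = 1)
  d2 <- disperse_directions(n2, seed = 2)
  sampling_scheme(c(rep(0, n_b0), rep(b1, n1), rep(b2, n2)),
                  rbind(matrix(0, n_b0, 3), d1, d2), "two-shell")
}

# One-bundle phantom whose diffusion signal has a simple closed form.
one_bundle_phantom <- function() {
  phantom_spec(bundles = list(list(axis = c(1, 0, 0), radius = 30,
                                   fraction = 0.9)))
}

rigid_cols <- c("tx", "ty", "tz", "rx", "ry", "rz")

set_motion <- function(trace, i, params) {
  trace[i, rigid_cols] <- as.list(params)
  trace$moved[i] <- any(params != 0)
  trace
}
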