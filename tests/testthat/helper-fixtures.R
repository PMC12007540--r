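# Shared fixtures and independent oracles used across the suite.

# Isotropic grid with voxel centers at integer multiples of `vs` offset by
# `origin` (world coordinate of voxel (0,0,0)).
iso_grid <- function(dims, vs = 1, origin = c(0, 0, 0)) {
  aff <- diag(c(vs, vs, vs, 1))
  aff[1:3, 4] <- origin
  reference_grid(aff, dims)
}

# Independent arc-length oracle: plain sum of segment norms.
segment_sum_length <- function(pts) {
  s <- 0
  for (i in seq_len(nrow(pts) - 1L))
    s <- s + sqrt(sum((pts[i + 1L, ] - pts[i, ])^2))
  s
}

# Exhaustive neighbor-pair surface-area oracle: loops over every set voxel
# and its 6 neighbors, counting exposed faces one at a time.
brute_surface_area <- function(mask) {
  m <- mask$mask
  vs <- mask$grid$voxel_sizes
  d <- dim(m)
  face <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  area <- 0
  set <- which(m, arr.ind = TRUE)
  for (r in seq_len(nrow(set))) {
    v <- set[r, ]
    for (k in 1:6) {
      w <- v + nb[k, ]
      outside <- any(w < 1L) || any(w > d)
      if (outside || !m[w[1], w[2], w[3]])
        area <- area + face[ceiling(k / 2)]
    }
  }
  area
}

# Brute-force tract mean: explicit loop over set voxels.
brute_tract_mean <- function(scalar, mask) {
  idx <- which(mask$mask, arr.ind = TRUE)
  total <- 0; n <- 0L
  for (r in seq_len(nrow(idx))) {
    v <- scalar$values[idx[r, 1], idx[r, 2], idx[r, 3]]
    if (!is.na(v)) { total <- total + v; n <- n + 1L }
  }
  total / n
}

# A small straight bundle entirely inside iso_grid(c(30,12,12)).
small_straight_bundle <- function(n = 10, length = 25, seed = 1) {
  make_bundle("straight", params = list(length = length, spread = 1.5),
              n_streamlines = n, grid = iso_grid(c(30, 12, 12)),
              seed = seed, origin = c(2, 5, 5))
}

# Canonical smooth lifespan-like trajectory lying exactly in the span of
# the default restricted cubic basis (positive over 0-100, peak near 26):
# obtained once by projecting a Gaussian bump plus slow decline onto the
# basis. Used wherever a known in-span ground truth is needed.
lifespan_beta <- c(1.220363, 0.008777, 2.228508, -2.725575, 0.740187,
                   -0.166739)

lifespan_truth_spec <- function(noise_sd = 0.2, cohort_offsets = NULL,
                                offset_mode = "additive",
                                n_per_cohort = 700) {
  trajectory_spec("rcs_coefficients",
                  list(knots = c(2, 4, 22, 35, 75, 90),
                       coefficients = lifespan_beta),
                  noise_sd = noise_sd, cohort_offsets = cohort_offsets,
                  offset_mode = offset_mode, n_per_cohort = n_per_cohort)
}

# Companion in-span inverted-U whose exact maximum (on a 0.1-year grid)
# sits at age 25, for peak-recovery checks free of model-class bias:
# derived once by bisecting the center of a projected Gaussian bump.
peak25_beta <- c(1.220398, 0.003128, 5.238722, -6.340734, 1.797332,
                 -0.642148)

peak25_spec <- function(noise_sd = 0.1, n_per_cohort = 250) {
  trajectory_spec("rcs_coefficients",
                  list(knots = c(2, 4, 22, 35, 75, 90),
                       coefficients = peak25_beta),
                  noise_sd = noise_sd, n_per_cohort = n_per_cohort)
}

# Fisher-z 95% sampling interval for a correlation estimated at n pairs.
fisher_interval <- function(rho, n) {
  z <- atanh(rho) + c(-1, 1) * 1.96 / sqrt(n - 3)
  tanh(z)
}
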