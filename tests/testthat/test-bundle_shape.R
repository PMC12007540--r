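test_that("a unit line along x marks exactly the voxels it crosses", {
  g <- iso_grid(c(10, 3, 3))
  b <- streamline_bundle(list(rbind(c(0, 1, 1), c(4, 1, 1))), grid = g)
  m <- voxelize_bundle(b)
  expect_equal(sum(m$mask), 5L)  # voxel centers 0..4 along x
  expect_true(all(which(m$mask, arr.ind = TRUE)[, 1] %in% 1:5))
})

test_that("points outside the grid are an error, not silently dropped", {
  g <- iso_grid(c(5, 5, 5))
  b <- streamline_bundle(list(rbind(c(0, 0, 0), c(40, 0, 0))), grid = g)
  expect_error(voxelize_bundle(b), "outside the grid")
})

test_that("digitized cylinder volume approaches the analytic value", {
  g <- iso_grid(c(220, 56, 56), vs = 0.5, origin = c(-2, -7, -7))
  b <- make_bundle("cylinder_fill", params = list(radius = 5, length = 100),
                   grid = g, seed = 1)
  vol <- mask_volume(voxelize_bundle(b))
  truth <- pi * 5^2 * 100
  expect_lt(abs(vol - truth) / truth, 0.02)
  # halving the resample step barely changes the voxel count
  vol2 <- mask_volume(voxelize_bundle(b, step_factor = 0.1))
  expect_lt(abs(vol2 - vol) / vol, 0.005)
})

test_that("length, span and curl match analytic geometry", {
  straight <- make_bundle("straight", params = list(length = 80),
                          n_streamlines = 50, seed = 1)
  geo <- streamline_geometry(straight)
  expect_equal(geo$length_mm, 80)
  expect_equal(geo$span_mm, 80)
  expect_identical(geo$curl, 1)

  arc <- make_bundle("arc", params = list(radius = 20, angle = pi),
                     n_streamlines = 50, seed = 2)
  geo_a <- streamline_geometry(arc)
  expect_equal(geo_a$length_mm, pi * 20, tolerance = 1e-4)
  expect_equal(geo_a$span_mm, 40, tolerance = 1e-6)
  expect_equal(geo_a$curl, pi / 2, tolerance = 1e-4)

  # mixed bundle of the two: length is the hand-averaged value
  mixed <- streamline_bundle(c(straight$streamlines, arc$streamlines))
  geo_m <- streamline_geometry(mixed)
  expect_equal(geo_m$length_mm, (geo$length_mm + geo_a$length_mm) / 2,
               tolerance = 1e-9)
})

test_that("closed-loop streamlines are named in the span error", {
  theta <- seq(0, 2 * pi, length.out = 40)
  loop <- cbind(cos(theta), sin(theta), 0)
  loop[40, ] <- loop[1, ]  # exact closure
  b <- streamline_bundle(list(rbind(c(0, 0, 0), c(1, 0, 0)), loop))
  expect_error(streamline_geometry(b), "streamline 2")
})

test_that("head is the lower-coordinate end and masks ignore stored orientation", {
  g <- iso_grid(c(12, 40, 12))
  set.seed(9)
  sl <- lapply(1:20, function(i) {
    y0 <- runif(1, 2, 3)
    cbind(5 + rnorm(1, 0, 0.3), seq(y0, y0 + 30, by = 0.5),
          5 + rnorm(1, 0, 0.3))
  })
  b <- streamline_bundle(sl, grid = g)
  em <- endpoint_mask(b)
  head_y <- mean(which(em$head$mask, arr.ind = TRUE)[, 2])
  tail_y <- mean(which(em$tail$mask, arr.ind = TRUE)[, 2])
  expect_lt(head_y, tail_y)

  # flip a random half of the streamlines: identical masks
  flip <- sample(20, 10)
  sl2 <- sl
  sl2[flip] <- lapply(sl[flip], function(s) s[nrow(s):1, , drop = FALSE])
  em2 <- endpoint_mask(streamline_bundle(sl2, grid = g))
  expect_identical(em$head$mask, em2$head$mask)
  expect_identical(em$tail$mask, em2$tail$mask)

  # and to a reshuffled input order
  em3 <- endpoint_mask(streamline_bundle(sl2[sample(20)], grid = g))
  expect_identical(em$head$mask, em3$head$mask)
})

test_that("streamlines starting in one voxel give a single-voxel head mask", {
  g <- iso_grid(c(30, 12, 12))
  set.seed(3)
  sl <- lapply(1:50, function(i)
    cbind(seq(2, 27, by = 0.5), 5 + runif(1, -0.2, 0.2),
          5 + runif(1, -0.2, 0.2)))
  em <- endpoint_mask(streamline_bundle(sl, grid = g))
  expect_equal(sum(em$head$mask), 1L)
})

test_that("mask volume scales with voxel volume", {
  g1 <- iso_grid(c(5, 5, 5))
  m <- array(FALSE, dim = c(5, 5, 5)); m[1:5] <- TRUE
  expect_equal(mask_volume(voxel_mask(m, g1)), 5)
  g15 <- iso_grid(c(5, 5, 5), vs = 1.5)
  expect_equal(mask_volume(voxel_mask(m, g15)), 16.875)  # 5 * 1.5^3
  expect_equal(mask_volume(voxel_mask(array(FALSE, c(5, 5, 5)), g1)), 0)
})

test_that("surface area counts exposed faces, matching the exhaustive oracle", {
  g <- iso_grid(c(6, 6, 6))
  one <- array(FALSE, dim = c(6, 6, 6)); one[3, 3, 3] <- TRUE
  expect_equal(mask_surface_area(voxel_mask(one, g)), 6)
  two <- one; two[4, 3, 3] <- TRUE
  expect_equal(mask_surface_area(voxel_mask(two, g)), 10)
  # block touching the grid boundary: outside faces are exposed
  corner <- array(FALSE, dim = c(6, 6, 6)); corner[1, 1, 1] <- TRUE
  expect_equal(mask_surface_area(voxel_mask(corner, g)), 6)

  # digitized cylinder against the brute-force neighbor-pair oracle
  gc <- iso_grid(c(40, 20, 20), vs = 0.8, origin = c(-2, -7, -7))
  b <- make_bundle("cylinder_fill",
                   params = list(radius = 4, length = 25, spacing = 0.4),
                   grid = gc, seed = 1)
  mk <- voxelize_bundle(b)
  expect_equal(mask_surface_area(mk), brute_surface_area(mk))
})

test_that("anisotropic voxels weight each face by its own area", {
  aff <- diag(c(1, 2, 3, 1))
  g <- reference_grid(aff, c(4, 4, 4))
  m <- array(FALSE, dim = c(4, 4, 4)); m[2, 2, 2] <- TRUE
  expect_equal(mask_surface_area(voxel_mask(m, g)),
               2 * (2 * 3 + 1 * 3 + 1 * 2))
})

test_that("compute_shape_features returns the 10 metrics with consistent values", {
  b <- small_straight_bundle()
  sf <- compute_shape_features(b)
  expect_s3_class(sf, "shape_features")
  expect_named(sf, c("volume_mm3", "endpoint_volume_mm3", "length_mm",
                     "span_mm", "curl", "diameter_mm", "elongation",
                     "surface_area_mm2", "head_surface_area_mm2",
                     "tail_surface_area_mm2"))
  expect_length(unclass(sf), 10L)
  expect_true(all(unlist(sf) >= 0))
  expect_identical(sf$curl, 1)
  expect_equal(sf$diameter_mm,
               2 * sqrt(sf$volume_mm3 / (pi * sf$length_mm)))
  expect_equal(sf$elongation, sf$length_mm / sf$diameter_mm)
})

test_that("cylinder fixture recovers diameter and elongation of the true cylinder", {
  g <- iso_grid(c(220, 56, 56), vs = 0.5, origin = c(-2, -7, -7))
  b <- make_bundle("cylinder_fill", params = list(radius = 5, length = 100),
                   grid = g, seed = 1)
  sf <- compute_shape_features(b)
  expect_lt(abs(sf$diameter_mm - 10) / 10, 0.05)
  expect_lt(abs(sf$elongation - 10) / 10, 0.05)
})

test_that("curl >= 1 for arbitrary bundles and metrics are rigid-motion invariant", {
  for (seed in 1:5) {
    b <- make_bundle("helix",
                     params = list(radius = 6, pitch = 12, turns = 1.5,
                                   jitter_sd = 0.2),
                     n_streamlines = 8, seed = seed)
    geo <- streamline_geometry(b)
    expect_gte(geo$curl, 1)
  }
  # translation invariance of the full feature set (grid moves with bundle)
  b <- small_straight_bundle()
  shift <- c(7, -3, 2)
  g2 <- reference_grid(b$grid$affine + cbind(matrix(0, 4, 3),
                                             c(shift, 0)), b$grid$dims)
  b2 <- streamline_bundle(lapply(b$streamlines,
                                 function(s) sweep(s, 2, shift, "+")),
                          grid = g2)
  expect_equal(unclass(compute_shape_features(b2)),
               unclass(compute_shape_features(b)), tolerance = 1e-10)
  # rotation invariance of streamline-geometry metrics
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  b3 <- streamline_bundle(lapply(b$streamlines, function(s) s %*% t(R)))
  expect_equal(streamline_geometry(b3), streamline_geometry(b),
               tolerance = 1e-10)
})

test_that("volume never decreases when streamlines are added", {
  b <- small_straight_bundle(n = 12, seed = 7)
  g <- b$grid
  vols <- vapply(c(3, 6, 12), function(k) {
    mask_volume(voxelize_bundle(
      streamline_bundle(b$streamlines[seq_len(k)], grid = g)))
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("voxel-count volume converges toward the analytic value with finer voxels", {
  truth <- pi * 4^2 * 30
  err <- vapply(c(1, 0.5), function(vs) {
    g <- iso_grid(ceiling(c(34 / vs, 18 / vs, 18 / vs)), vs = vs,
                  origin = c(-2, -8, -8))
    b <- make_bundle("cylinder_fill",
                     params = list(radius = 4, length = 30, spacing = vs),
                     grid = g, seed = 1)
    abs(mask_volume(voxelize_bundle(b)) - truth) / truth
  }, numeric(1))
  expect_lt(err[2], err[1])
})
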