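test_that("FA and MD match their closed forms", {
  expect_equal(compute_fa(c(1, 1, 1)), 0)
  expect_equal(compute_fa(c(1, 0, 0)), 1)
  expect_equal(compute_fa(c(2, 1, 1)), 1 / sqrt(6), tolerance = 1e-12)
  expect_equal(compute_fa(c(0, 0, 0)), 0)
  expect_equal(compute_md(c(1, 1, 1)), 1)
  expect_equal(compute_md(c(3, 0, 0)), 1)
  expect_equal(compute_md(c(2, 1, 1)), 4 / 3)
  # matrix form agrees with the eigenvalue form
  u <- c(1, 2, 2) / 3
  Dt <- 0.4 * diag(3) + 1.1 * tcrossprod(u)
  lam <- c(1.5, 0.4, 0.4)
  expect_equal(compute_fa(Dt), compute_fa(lam), tolerance = 1e-10)
  expect_equal(compute_md(Dt), compute_md(lam), tolerance = 1e-10)
})

test_that("phantom bundles have the requested FA and isotropic background", {
  ph <- straight_phantom(fa_inside = 0.8)
  fa <- netdiscrim:::fa_map(ph$field)
  md <- netdiscrim:::md_map(ph$field)
  expect_true(all(md > 0))
  # background voxel
  expect_equal(fa[1, 1, 1], 0)
  # bundle-core voxel hits fa_inside to numerical precision
  expect_equal(fa[20, 5, 5], 0.8, tolerance = 1e-6)
  # the two end-cap regions are disjoint, nonempty voxel sets
  expect_gt(sum(ph$parcellation == 1), 0)
  expect_gt(sum(ph$parcellation == 2), 0)
  expect_equal(sum(ph$parcellation == 1 & ph$parcellation == 2), 0)
})

test_that("phantom rejects bundles outside the volume and overlapping caps", {
  expect_error(generate_tensor_phantom(
    shape = c(10, 10, 10),
    bundles = list(list(start = c(-1, 0.4, 0.4), end = c(0.7, 0.4, 0.4),
                        radius = 0.1))
  ), "leaves the volume")
  expect_error(generate_tensor_phantom(
    shape = c(20, 8, 8),
    bundles = list(
      list(start = c(0.1, 0.3, 0.3), end = c(1.5, 0.3, 0.3), radius = 0.12),
      list(start = c(0.1, 0.34, 0.3), end = c(1.5, 0.34, 0.3), radius = 0.12)
    )
  ), "overlap")
})

test_that("seed selection returns exactly the voxels above the FA threshold", {
  ph <- straight_phantom()
  fa <- netdiscrim:::fa_map(ph$field)
  seeds <- select_seeds(ph$field, 0.12)
  expect_equal(nrow(seeds), sum(fa > 0.12))
  expect_true(all(fa[seeds] > 0.12))
  # isotropic field yields no seeds; threshold 0 yields every positive-FA voxel
  iso <- tensor_field(array(rep(c(1, 1, 1, 0, 0, 0), each = 27),
                            c(3, 3, 3, 6)), 0.1)
  expect_equal(nrow(select_seeds(iso, 0.12)), 0)
  expect_equal(nrow(select_seeds(ph$field, 0)), sum(fa > 0))
})

test_that("all three trackers follow a straight bundle collinearly", {
  ph <- straight_phantom()
  seeds <- select_seeds(ph$field, 0.12)
  for (mode in c("FACT", "TL", "TEND")) {
    trajs <- track(ph$field, seeds, track_params(mode = mode), md = ph$md)
    expect_gt(length(trajs), 0)
    for (tr in trajs) {
      pts <- tr$points
      expect_gt(nrow(pts), 10)
      # perpendicular deviation from the bundle axis direction (x axis)
      dev <- max(abs(pts[, 2] - pts[1, 2]), abs(pts[, 3] - pts[1, 3]))
      expect_lt(dev, 0.025)
      # per-step MD samples recorded
      expect_length(tr$samples$md, nrow(pts))
    }
  }
})

test_that("trackers agree on constant axially-symmetric fields", {
  ph <- straight_phantom()
  seed <- matrix(c(20L, 5L, 5L), 1)
  p_fact <- track(ph$field, seed, track_params(mode = "FACT"))[[1]]$points
  p_tl   <- track(ph$field, seed, track_params(mode = "TL"))[[1]]$points
  p_tend <- track(ph$field, seed, track_params(mode = "TEND"))[[1]]$points
  expect_equal(p_fact, p_tl, tolerance = 1e-8)
  expect_equal(p_fact, p_tend, tolerance = 1e-8)
})

test_that("tracking from the two bundle ends is reversal-symmetric", {
  ph <- straight_phantom()
  fa <- netdiscrim:::fa_map(ph$field)
  xs <- which(apply(fa > 0.12, 1, any))
  s1 <- matrix(c(min(xs), 5L, 5L), 1)
  s2 <- matrix(c(max(xs), 5L, 5L), 1)
  t1 <- track(ph$field, s1, track_params())[[1]]$points
  t2 <- track(ph$field, s2, track_params())[[1]]$points
  hausdorff <- function(a, b) {
    da <- apply(a, 1, function(p) min(sqrt(colSums((t(b) - p)^2))))
    db <- apply(b, 1, function(p) min(sqrt(colSums((t(a) - p)^2))))
    max(da, db)
  }
  expect_lte(hausdorff(t1, t2), 0.025 + 1e-9)
})

test_that("trajectories respect the length bound and curvature threshold", {
  ph <- generate_tensor_phantom(
    shape = c(30, 30, 7),
    bundles = list(list(start = c(0.3, 0.3, 0.28), end = c(2.1, 0.3, 0.28),
                        via = c(2.1, 2.1, 0.28), radius = 0.12)),
    fa_inside = 0.7, voxel_size = 0.08
  )
  seeds <- select_seeds(ph$field, 0.12)
  params <- track_params()
  trajs <- track(ph$field, seeds[seq(1, nrow(seeds), by = 7), , drop = FALSE],
                 params)
  cos_thresh <- cos(params$max_angle * pi / 180)
  for (tr in trajs) {
    expect_lte(netdiscrim:::trajectory_length(tr), params$max_length)
    if (nrow(tr$points) > 2) {
      steps <- diff(tr$points)
      steps <- steps / sqrt(rowSums(steps^2))
      dots <- rowSums(steps[-nrow(steps), , drop = FALSE] *
                        steps[-1, , drop = FALSE])
      expect_true(all(dots >= cos_thresh - 1e-9))
    }
  }
})

test_that("seeds outside the volume are rejected", {
  ph <- straight_phantom()
  expect_error(track(ph$field, matrix(c(99L, 1L, 1L), 1), track_params()),
               "outside the volume")
})

test_that("trajectories round-trip through the plain-text format", {
  ph <- straight_phantom()
  trajs <- track(ph$field, select_seeds(ph$field)[1:3, ], track_params(),
                 md = ph$md)
  path <- withr::local_tempfile(fileext = ".txt")
  write_trajectories(trajs, path)
  back <- read_trajectories(path)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(back[[k]]$points, unname(trajs[[k]]$points),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(back[[k]]$samples$md, trajs[[k]]$samples$md, tolerance = 1e-6)
  }
})

test_that("phantoms export to NIfTI volumes", {
  skip_if_not_installed("RNifti")
  ph <- straight_phantom()
  prefix <- file.path(withr::local_tempdir(), "phantom")
  paths <- write_phantom_nifti(ph, prefix)
  expect_true(all(file.exists(paths)))
  md_back <- RNifti::readNifti(paths[2])
  expect_equal(dim(md_back), dim(ph$md))
  expect_equal(as.array(md_back), ph$md, tolerance = 1e-6, ignore_attr = TRUE)
})
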