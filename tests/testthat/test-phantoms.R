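test_that("membrane phantoms match analytic shell volumes and are seeded", {
  ph <- membrane_phantom(c(128, 128, 128), n_shells = 1,
                         radius_range = c(30, 30),
                         thickness_range = c(5, 5), seed = 3)
  R <- ph$truth$params$radii[1]; t <- ph$truth$params$thickness[1]
  expect_equal(sum(ph$seg$data), 4 * pi * R^2 * t, tolerance = 0.05)
  # ground-truth points sit on the exact mid-surface
  d <- sqrt(colSums((t(ph$truth$gt_points) - ph$truth$params$centers[1, ])^2))
  expect_lt(max(abs(d - R)), 0.5)
  ph2 <- membrane_phantom(c(128, 128, 128), n_shells = 1,
                          radius_range = c(30, 30),
                          thickness_range = c(5, 5), seed = 3)
  expect_identical(ph$seg$data, ph2$seg$data)
  expect_error(membrane_phantom(c(32, 32, 32), n_shells = 10, seed = 1),
               class = "skeletrace_param_error")
})

test_that("filament phantoms have capsule volumes and true topology", {
  fp <- filament_phantom(c(80, 80, 80), kind = "straight", n_filaments = 1,
                         seed = 3, tube_radius = 4)
  gt <- fp$truth$gt_points
  L <- sum(sqrt(rowSums(diff(gt)^2)))
  capsule <- pi * 16 * L + 4 / 3 * pi * 64    # tube + two hemispherical caps
  expect_equal(sum(fp$seg$data), capsule, tolerance = 0.05)

  fb <- filament_phantom(c(96, 96, 96), kind = "branched", n_filaments = 1,
                         params = list(n_branches = 1), seed = 7)
  g <- fb$truth$gt_graph
  deg <- tabulate(c(match(g$edges$source, g$nodes$id),
                    match(g$edges$target, g$nodes$id)), nrow(g$nodes))
  expect_equal(sum(deg == 3), 1)              # exactly one branch point
  expect_lte(max(deg), 3)
  # every ground-truth point lies inside the segmentation
  pr <- skeleton_precision(fb$truth$gt_points, fb$seg)
  expect_equal(pr$precision, 1.0)
})

test_that("wormlike phantom centerlines carry their persistence length", {
  # pool tangent correlations over several phantoms: a single 128^3 chain
  # is short relative to the 100-voxel persistence length
  curves <- list()
  for (s in 0:4) {
    fp <- filament_phantom(c(128, 128, 128), kind = "wormlike",
                           n_filaments = 2,
                           params = list(persistence = 100), seed = s)
    curves <- c(curves, extract_curves(fp$truth$gt_graph))
  }
  pooled <- pooled_persistence_length(curves)
  expect_lt(abs(pooled - 100), 20)
})

test_that("blob phantoms pack non-overlapping seeded spheres", {
  ph <- blob_phantom(c(128, 128, 128), n_blobs = 20, radius = 5,
                     min_separation = 20, seed = 1)
  expect_equal(nrow(ph$truth$gt_centers), 20)
  expect_gte(min(dist(ph$truth$gt_centers)), 20)
  expect_equal(sum(ph$seg$data), 20 * 4 / 3 * pi * 125, tolerance = 0.05)
  ph2 <- blob_phantom(c(128, 128, 128), n_blobs = 20, radius = 5,
                      min_separation = 20, seed = 1)
  expect_identical(ph$seg$data, ph2$seg$data)
  pr <- skeleton_precision(ph$truth$gt_centers, ph$seg)
  expect_equal(pr$precision, 1.0)
})

test_that("dilation grows by the chosen structuring element", {
  a <- array(0L, c(7, 7, 7)); a[4, 4, 4] <- 1L
  seg <- binary_volume(a)
  expect_identical(dilate(seg, 0)$data, seg$data)
  d1 <- dilate(seg, 1)
  expect_equal(sum(d1$data), 7)               # center + 6 faces
  d26 <- dilate(seg, 1, 26)
  expect_equal(sum(d26$data), 27)
  db <- dilate(seg, 1, "ball")
  expect_equal(sum(db$data), 7)               # unit Euclidean ball on the grid
  # monotone growth
  counts <- vapply(0:3, function(k) sum(dilate(seg, k)$data), numeric(1))
  expect_true(all(diff(counts) > 0))
  # ball dilation of a sphere stays spherical: the result is sandwiched
  # between the balls of radius r + k - 1 and r + k around the center
  # (voxel-to-voxel growth loses at most one voxel of radius)
  bp <- blob_phantom(c(48, 48, 48), n_blobs = 1, radius = 6,
                     min_separation = 1, seed = 2)
  grown <- dilate(bp$seg, 3, "ball")
  ctr <- bp$truth$gt_centers[1, ]
  idx <- which(grown$data == 1L, arr.ind = TRUE) - 1L
  dists <- sqrt(colSums((t(idx) - ctr)^2))
  expect_lte(max(dists), 9 + 1e-9)
  inner <- which(array(TRUE, c(48, 48, 48)), arr.ind = TRUE) - 1L
  din <- sqrt(colSums((t(inner) - ctr)^2))
  expect_true(all(grown$data[din <= 7.2] == 1L))
})
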