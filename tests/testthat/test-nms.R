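gaussian_field <- function(n, f) {
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  scalar_volume(array(f(g$x, g$y, g$z), c(n, n, n)))
}

test_that("NMS finds analytic blob centers, ridge lines and slab planes", {
  n <- 21; c0 <- 10.0
  # isotropic Gaussian blob, d = 0: only the voxel at the center survives
  Sb <- gaussian_field(n, function(x, y, z)
    exp(-((x - c0)^2 + (y - c0)^2 + (z - c0)^2) / (2 * 9)))
  eb <- eig3_symmetric(hessian(Sb))
  k0 <- nms(Sb, eb, 0)
  expect_equal(k0$points, matrix(c(c0, c0, c0), 1,
                                 dimnames = list(NULL, c("x", "y", "z"))))

  # z-invariant Gaussian ridge, d = 1: the line (c0, c0, z)
  Sr <- gaussian_field(n, function(x, y, z)
    exp(-((x - c0)^2 + (y - c0)^2) / (2 * 9)))
  er <- eig3_symmetric(hessian(Sr))
  k1 <- nms(Sr, er, 1)
  expect_true(all(k1$points[, 1] == c0 & k1$points[, 2] == c0))
  expect_setequal(k1$points[, 3], 1:(n - 2))

  # Gaussian slab, d = 2: the mid-plane x = c0
  Ss <- gaussian_field(n, function(x, y, z) exp(-(x - c0)^2 / (2 * 9)))
  es <- eig3_symmetric(hessian(Ss))
  k2 <- nms(Ss, es, 2)
  expect_true(all(k2$points[, 1] == c0))
  expect_equal(nrow(k2$points), (n - 2)^2)

  # constant volume: strict inequalities never hold
  Sc <- scalar_volume(array(1, c(8, 8, 8)))
  ec <- eig3_symmetric(hessian(Sc))
  for (d in 0:2) expect_equal(nrow(nms(Sc, ec, d)$points), 0)
})

test_that("NMS equals the literal brute-force oracle and nests across d", {
  S <- smooth_random_volume(20, seed = 9)
  eg <- eig3_symmetric(hessian(S))
  oracle <- brute_nms_all(S)
  clouds <- lapply(0:2, function(d) nms(S, eg, d)$points)
  expect_setequal(point_key(clouds[[1]]), point_key(oracle$d0))
  expect_setequal(point_key(clouds[[2]]), point_key(oracle$d1))
  expect_setequal(point_key(clouds[[3]]), point_key(oracle$d2))
  # nesting: a maximum along all three directions is one along the top two
  expect_true(all(point_key(clouds[[1]]) %in% point_key(clouds[[2]])))
  expect_true(all(point_key(clouds[[2]]) %in% point_key(clouds[[3]])))
  # raising the threshold never adds points
  hi <- nms(S, eg, 2, threshold = 0.2)$points
  expect_true(all(point_key(hi) %in% point_key(clouds[[3]])))
  expect_lte(nrow(hi), nrow(clouds[[3]]))
})

test_that("voxel-grid downsampling keeps one point per occupied cell", {
  line <- skeleton_cloud(cbind(0:99, 0, 0), d = 1)
  expect_identical(downsample(line, 0), line)
  ds <- downsample(line, 10)
  expect_equal(nrow(ds$points), 10)            # one survivor per cell
  clump <- skeleton_cloud(cbind(runif(100, 0, 9.9), runif(100, 0, 9.9),
                                runif(100, 0, 9.9)), d = 0)
  expect_equal(nrow(downsample(clump, 10)$points), 1)
})

test_that("skeletonize recovers phantom ground truth per dimension", {
  # solid ball, d = 0: survivors cluster within 1 voxel of the center
  bp <- blob_phantom(c(32, 32, 32), n_blobs = 1, radius = 6,
                     min_separation = 1, seed = 2)
  k0 <- skeletonize(bp$seg, d = 0)
  expect_gt(nrow(k0$points), 0)
  ctr <- bp$truth$gt_centers[1, ]
  expect_lt(max(sqrt(colSums((t(k0$points) - ctr)^2))), 1.74)

  # full-length tube along z, d = 1: skeleton points stay on the axis
  n <- 40; cx <- 20; cy <- 20
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  tube <- as.integer((g$x - cx)^2 + (g$y - cy)^2 <= 16)
  disc <- array(rep(tube, n), c(n, n, n))
  k1 <- skeletonize(binary_volume(disc), d = 1)
  expect_gt(nrow(k1$points), 20)
  expect_true(all(abs(k1$points[, 1] - cx) <= 1 &
                  abs(k1$points[, 2] - cy) <= 1))

  # spherical shell, d = 2: every skeleton point is inside the segmentation
  mp <- membrane_phantom(c(64, 64, 64), n_shells = 1,
                         radius_range = c(15, 20),
                         thickness_range = c(5, 7), seed = 1)
  k2 <- skeletonize(mp$seg, d = 2)
  pr <- skeleton_precision(k2, mp$seg)
  expect_gt(nrow(k2$points), 1000)
  expect_equal(pr$precision, 1.0)
})
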