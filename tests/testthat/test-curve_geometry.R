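test_that("curve descriptors vanish on straight lines and hit closed forms", {
  line <- filament_curve(cbind(0:10, 0, 0))
  lp <- local_properties(line)
  expect_equal(lp$s, 0:10)
  expect_true(all(lp$curvature == 0) && all(lp$torsion == 0))
  expect_true(all(abs(sqrt(rowSums(lp$tangent^2)) - 1) < 1e-9))
  gp <- global_properties(line)
  expect_equal(gp$sinuosity, 1)
  expect_equal(gp$total_curvature, 0)

  # circle of radius 10: Menger curvature is exactly the inverse radius
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- filament_curve(cbind(10 * cos(th), 10 * sin(th), 0))
  cp <- local_properties(circ)
  expect_true(all(abs(cp$curvature - 0.1) < 0.001))
  expect_true(all(abs(cp$torsion) < 1e-6))     # planar curve

  # helix r = 2, c = 1: kappa -> r/(r^2+c^2), |tau| -> c/(r^2+c^2)
  t <- seq(0, 4 * pi, length.out = 200)
  hx <- filament_curve(cbind(2 * cos(t), 2 * sin(t), t))
  hp <- local_properties(hx)
  expect_true(all(abs(hp$curvature - 0.4) < 0.4 * 0.02))
  expect_true(all(abs(abs(hp$torsion) - 0.2) < 0.2 * 0.02))
  expect_true(all(hp$torsion > 0))             # right-handed helix

  # semicircle: sinuosity pi/2, total curvature pi
  ths <- seq(0, pi, length.out = 100)
  semi <- filament_curve(cbind(7 * cos(ths), 7 * sin(ths), 0))
  sp <- global_properties(semi)
  expect_equal(sp$sinuosity, pi / 2, tolerance = 0.01)
  expect_equal(sp$total_curvature, pi, tolerance = 0.02)

  # arc subtending a given angle integrates curvature to that angle
  tha <- seq(0, 1.2, length.out = 100)
  arc <- global_properties(filament_curve(cbind(25 * cos(tha),
                                                25 * sin(tha), 0)))
  expect_equal(arc$total_curvature, 1.2, tolerance = 0.02 * 1.2)
})

test_that("descriptors are rigid-motion invariant and respect bounds", {
  set.seed(8)
  pts <- wormlike_chain(60, 40, seed = 12)
  base_l <- local_properties(filament_curve(pts))
  base_g <- global_properties(filament_curve(pts))
  # random rotation (QR of a random matrix) + translation
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_); if (det(R) < 0) R[, 1] <- -R[, 1]
  moved <- pts %*% t(R) + matrix(c(5, -3, 11), nrow(pts), 3, byrow = TRUE)
  mov_l <- local_properties(filament_curve(moved))
  mov_g <- global_properties(filament_curve(moved))
  expect_equal(mov_l$curvature, base_l$curvature, tolerance = 1e-6)
  expect_equal(mov_l$torsion, base_l$torsion, tolerance = 1e-6)
  expect_equal(mov_g$length, base_g$length, tolerance = 1e-9)
  expect_equal(mov_g$sinuosity, base_g$sinuosity, tolerance = 1e-9)
  # triangle inequality: geodesic length >= end-to-end, so sinuosity >= 1
  expect_gte(base_g$sinuosity, 1)
  expect_gte(base_g$length,
             sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)) - 1e-12)
  # nm scaling through voxel_size
  gp2 <- global_properties(filament_curve(pts, voxel_size = 1.5))
  expect_equal(gp2$length, base_g$length * 1.5, tolerance = 1e-9)
})

test_that("persistence length is recovered from wormlike chains", {
  lp_true <- 100
  set.seed(21)
  chains <- lapply(1:50, function(i)
    filament_curve(wormlike_chain(200, lp_true)))
  pooled <- pooled_persistence_length(chains)
  expect_lt(abs(pooled - lp_true), 0.2 * lp_true)
  # per-curve estimates are noisier but center near the truth
  est <- vapply(chains, function(c)
    global_properties(c)$persistence_length, numeric(1))
  expect_lt(abs(median(est[is.finite(est)]) - lp_true), 0.25 * lp_true)
})

test_that("degenerate curves warn and pad with zeros", {
  two <- filament_curve(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_warning(expect_warning(lp <- local_properties(two)))
  expect_equal(lp$curvature, c(0, 0))
  expect_equal(lp$torsion, c(0, 0))
  # closed curve: coincident endpoints flagged as infinite sinuosity
  th <- seq(0, 2 * pi, length.out = 20)
  closed <- filament_curve(cbind(cos(th), sin(th), 0))
  expect_warning(g <- global_properties(closed), "sinuosity")
  expect_equal(g$sinuosity, Inf)
})
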