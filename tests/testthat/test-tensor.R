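grid_volume <- function(f, n = 12) {
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  scalar_volume(array(f(g$x, g$y, g$z), c(n, n, n)))
}

interior <- function(a, m = 2) {
  d <- dim(a)
  a[(1 + m):(d[1] - m), (1 + m):(d[2] - m), (1 + m):(d[3] - m)]
}

test_that("finite-difference stencils are exact on polynomial fields", {
  lin <- grid_volume(function(x, y, z) 2 * x)
  for (scheme in c("centered", "forward")) {
    g <- first_derivatives(lin, scheme)
    expect_true(all(interior(g$x) == 2))
    expect_true(all(interior(g$y) == 0) && all(interior(g$z) == 0))
  }
  const <- grid_volume(function(x, y, z) 7)
  g <- first_derivatives(const)
  expect_true(all(g$x == 0) && all(g$y == 0) && all(g$z == 0))

  # centered differences are exact for quadratics
  quad <- grid_volume(function(x, y, z) x^2)
  gq <- first_derivatives(quad, "centered")
  xs <- interior(grid_volume(function(x, y, z) x)$data)
  expect_equal(interior(gq$x), 2 * xs)

  bil <- grid_volume(function(x, y, z) x * y)
  H <- hessian(bil)
  expect_true(all(interior(H$xy) == 1))
  expect_true(all(interior(H$xx) == 0) && all(interior(H$yy) == 0))
  Hq <- hessian(quad, "centered")
  expect_true(all(interior(Hq$xx) == 2))
})

test_that("mixed second derivatives commute", {
  # the stencils commute exactly in exact arithmetic; in floating point the
  # two evaluation orders round intermediates differently, so agreement is
  # to the last ulp rather than bit-identical
  S <- smooth_random_volume(16, seed = 3)
  for (scheme in c("centered", "forward")) {
    g <- first_derivatives(S, scheme)
    dxy <- first_derivatives(scalar_volume(g$y), scheme)$x
    dyx <- first_derivatives(scalar_volume(g$x), scheme)$y
    expect_equal(dxy, dyx, tolerance = 1e-14)
    expect_lt(max(abs(dxy - dyx)), 4 * .Machine$double.eps * max(abs(dxy)))
  }
})

make_hfield <- function(mats) {
  # pack a list of symmetric 3x3 matrices into a 1 x 1 x n hessian field
  n <- length(mats)
  comp <- function(i, j) array(vapply(mats, function(m) m[i, j], numeric(1)),
                               c(n, 1, 1))
  structure(list(xx = comp(1, 1), yy = comp(2, 2), zz = comp(3, 3),
                 xy = comp(1, 2), xz = comp(1, 3), yz = comp(2, 3),
                 dim = c(n, 1, 1), voxel_size = 1),
            class = "hessian_field")
}

test_that("analytic eigen-decomposition matches the Jacobi oracle", {
  set.seed(11)
  mats <- replicate(1000, {
    a <- matrix(rnorm(9, sd = sample(c(0.01, 1, 100), 1)), 3)
    (a + t(a)) / 2
  }, simplify = FALSE)
  mats <- c(mats, list(diag(3), diag(c(-5, 2, 1)), matrix(0, 3, 3),
                       diag(c(1, 1, 1e-7))))
  eg <- eig3_symmetric(make_hfield(mats))
  for (i in seq_along(mats)) {
    w <- eg$values[i, ]
    expect_true(all(diff(abs(w)) <= 1e-12 + 1e-12 * abs(w[1])))  # |l1|>=|l2|>=|l3|
    wj <- jacobi_eigvals(mats[[i]])
    wj <- wj[order(-abs(wj))]
    scale <- max(abs(wj), 1e-12)
    expect_lt(max(abs(w - wj)), 1e-8 * scale)
  }
  # explicit sorted example with eigenvector along x
  idx <- length(mats) - 2L
  expect_equal(eg$values[idx, ], c(-5, 2, 1))
  expect_equal(abs(eg$vectors[idx, 1:3]), c(1, 0, 0), tolerance = 1e-12)
})

test_that("eigenpairs reconstruct the tensor and are orthonormal", {
  S <- smooth_random_volume(10, seed = 5)
  H <- hessian(S)
  eg <- eig3_symmetric(H)
  n <- prod(dim(S$data))
  set.seed(2)
  for (i in sample(n, 200)) {
    Hm <- matrix(c(H$xx[i], H$xy[i], H$xz[i],
                   H$xy[i], H$yy[i], H$yz[i],
                   H$xz[i], H$yz[i], H$zz[i]), 3, 3)
    V <- matrix(eg$vectors[i, ], 3, 3)          # column k = eigenvector v_k
    w <- eg$values[i, ]
    rec <- V %*% diag(w) %*% t(V)
    nrm <- max(abs(Hm), 1e-12)
    expect_lt(max(abs(rec - Hm)), 1e-6 * nrm)
    expect_lt(max(abs(crossprod(V) - diag(3))), 1e-5)
    expect_lt(abs(sum(w) - sum(diag(Hm))), 1e-8 * nrm)
    expect_lt(abs(prod(w) - det(Hm)), 1e-8 * max(nrm^3, 1e-12))
  }
  expect_error(eig3_symmetric(make_hfield(list(matrix(NaN, 3, 3)))),
               "non-finite")
})
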