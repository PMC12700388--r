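# Independent oracles and small generators used across the suite. These
# deliberately avoid the package's own computational paths: dense
# eigensolvers from base R, literal probing, and exhaustive enumeration.

# random smooth scalar volume: white noise blurred by an R-side separable
# Gaussian (stats::filter-free, plain convolution) so it does not reuse the
# package's filtering kernel
smooth_random_volume <- function(n, sigma = 2.5, seed = 1) {
  set.seed(seed)
  a <- array(rnorm(n^3), c(n, n, n))
  r <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  k <- k / sum(k)
  pad_idx <- function(i, n) pmin(pmax(i, 1L), n)  # replicate padding
  conv_axis <- function(a, axis) {
    out <- array(0, dim(a))
    for (o in (-r):r) {
      idx <- lapply(dim(a), seq_len)
      idx[[axis]] <- pad_idx(idx[[axis]] + o, dim(a)[axis])
      out <- out + k[o + r + 1] * do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    out
  }
  scalar_volume(conv_axis(conv_axis(conv_axis(a, 1), 2), 3))
}

# vectorized trilinear interpolation with clamped coordinates
r_trilinear <- function(vol, x, y, z) {
  d <- dim(vol)
  x <- pmin(pmax(x, 0), d[1] - 1)
  y <- pmin(pmax(y, 0), d[2] - 1)
  z <- pmin(pmax(z, 0), d[3] - 1)
  x0 <- pmin(pmax(floor(x), 0), d[1] - 2)
  y0 <- pmin(pmax(floor(y), 0), d[2] - 2)
  z0 <- pmin(pmax(floor(z), 0), d[3] - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  g <- function(ix, iy, iz) vol[cbind(x0 + ix + 1, y0 + iy + 1, z0 + iz + 1)]
  (g(0,0,0) * (1-fx) + g(1,0,0) * fx) * (1-fy) * (1-fz) +
  (g(0,1,0) * (1-fx) + g(1,1,0) * fx) * fy * (1-fz) +
  (g(0,0,1) * (1-fx) + g(1,0,1) * fx) * (1-fy) * fz +
  (g(0,1,1) * (1-fx) + g(1,1,1) * fx) * fy * fz
}

# Literal non-maximum suppression oracle: per-voxel dense eigensolver
# (base R eigen) sorted by |eigenvalue|, probes at +/- delta along each
# direction, strict inequalities. Returns the skeleton point sets for all
# three dimensions at once (they share the probe results).
brute_nms_all <- function(S, delta = 1/3, threshold = 0,
                          scheme = "centered") {
  dm <- dim(S$data)
  H <- hessian(S, scheme)
  gx <- expand.grid(x = 1:(dm[1] - 2), y = 1:(dm[2] - 2), z = 1:(dm[3] - 2))
  li <- gx$x + dm[1] * (gx$y + dm[2] * gx$z) + 1
  svals <- S$data[li]
  eval_mask <- svals >= threshold
  gx <- gx[eval_mask, ]; li <- li[eval_mask]; svals <- svals[eval_mask]
  n <- nrow(gx)
  V <- array(NA_real_, c(n, 3, 3))   # [point, direction j, component]
  for (r in seq_len(n)) {
    i <- li[r]
    Hm <- matrix(c(H$xx[i], H$xy[i], H$xz[i],
                   H$xy[i], H$yy[i], H$yz[i],
                   H$xz[i], H$yz[i], H$zz[i]), 3, 3)
    ev <- eigen(Hm, symmetric = TRUE)
    ord <- order(-abs(ev$values))
    V[r, , ] <- t(ev$vectors[, ord])
  }
  ok <- matrix(NA, n, 3)
  for (j in 1:3) {
    sm <- r_trilinear(S$data, gx$x - delta * V[, j, 1],
                      gx$y - delta * V[, j, 2], gx$z - delta * V[, j, 3])
    sp <- r_trilinear(S$data, gx$x + delta * V[, j, 1],
                      gx$y + delta * V[, j, 2], gx$z + delta * V[, j, 3])
    ok[, j] <- (svals > sm) & (svals > sp)
  }
  pts <- cbind(gx$x, gx$y, gx$z)
  list(d0 = pts[ok[, 1] & ok[, 2] & ok[, 3], , drop = FALSE],
       d1 = pts[ok[, 1] & ok[, 2], , drop = FALSE],
       d2 = pts[ok[, 1], , drop = FALSE])
}

point_key <- function(m) paste(m[, 1], m[, 2], m[, 3])

# cyclic Jacobi eigenvalues of a symmetric 3x3 matrix (iterative oracle)
jacobi_eigvals <- function(A) {
  M <- A
  for (sweep in 1:100) {
    off <- abs(M[1, 2]) + abs(M[1, 3]) + abs(M[2, 3])
    if (off < 1e-300) break
    for (p in 1:2) for (q in (p + 1):3) {
      if (abs(M[p, q]) == 0) next
      theta <- (M[q, q] - M[p, p]) / (2 * M[p, q])
      t <- sign(theta + (theta == 0)) / (abs(theta) + sqrt(theta^2 + 1))
      cc <- 1 / sqrt(t^2 + 1); ss <- t * cc
      R <- diag(3); R[p, p] <- cc; R[q, q] <- cc; R[p, q] <- ss; R[q, p] <- -ss
      M <- t(R) %*% M %*% R
    }
  }
  diag(M)
}

# exhaustive minimum spanning forest weight: try all edge subsets of the
# right size, keep acyclic spanning ones of minimum weight
brute_msf_weight <- function(n_nodes, edges) {
  # edges: data.frame(source, target, length) with node ids 1..n_nodes
  comp_of <- function(sel) {
    parent <- seq_len(n_nodes)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in sel) {
      a <- find(edges$source[e]); b <- find(edges$target[e])
      if (a == b) return(NULL)          # cycle
      parent[a] <- b
    }
    length(unique(vapply(seq_len(n_nodes), find, integer(1))))
  }
  ncomp_full <- {
    parent <- seq_len(n_nodes)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in seq_len(nrow(edges))) {
      a <- find(edges$source[e]); b <- find(edges$target[e])
      if (a != b) parent[a] <- b
    }
    length(unique(vapply(seq_len(n_nodes), find, integer(1))))
  }
  k <- n_nodes - ncomp_full
  if (k == 0) return(0)
  best <- Inf
  for (sel in utils::combn(nrow(edges), k, simplify = FALSE)) {
    nc <- comp_of(sel)
    if (!is.null(nc) && nc == ncomp_full)
      best <- min(best, sum(edges$length[sel]))
  }
  best
}

# directed Hausdorff distance from point set a to point set b
hausdorff_to <- function(a, b) {
  max(apply(a, 1, function(q) min(sqrt(colSums((t(b) - q)^2)))))
}

# extend an ordered centerline beyond both ends by `len` (tube phantoms are
# capsules, so their medial axis genuinely reaches into the end caps)
extend_centerline <- function(pts, len, step = 0.5) {
  n <- nrow(pts)
  t0 <- pts[1, ] - pts[2, ]; t0 <- t0 / sqrt(sum(t0^2))
  t1 <- pts[n, ] - pts[n - 1, ]; t1 <- t1 / sqrt(sum(t1^2))
  ss <- seq(step, len, by = step)
  rbind(t(sapply(ss, function(s) pts[1, ] + s * t0)),
        pts,
        t(sapply(ss, function(s) pts[n, ] + s * t1)))
}

# random spatial graph on <= max_nodes nodes for forest tests
random_small_graph <- function(seed, max_nodes = 8, max_edges = 12) {
  set.seed(seed)
  n <- sample(3:max_nodes, 1)
  pts <- matrix(runif(3 * n, 0, 10), n, 3)
  all_pairs <- t(utils::combn(n, 2))
  m <- min(max_edges, nrow(all_pairs))
  pick <- all_pairs[sample(nrow(all_pairs), sample(seq_len(m), 1)), ,
                    drop = FALSE]
  nodes <- data.frame(id = seq_len(n), x = pts[, 1], y = pts[, 2],
                      z = pts[, 3])
  edges <- data.frame(source = pick[, 1], target = pick[, 2])
  spatial_graph(nodes, edges)
}
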