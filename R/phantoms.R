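# Geometric phantoms: synthetic binary segmentations with exact ground
# truth (mid-surfaces, centerlines, centers) so the whole pipeline is
# testable without any external data, plus the dilation utility used in
# the metric-robustness experiments.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

phantom_truth <- function(kind, gt_points, gt_graph = NULL, gt_centers = NULL,
                          params = list(), seed = NA) {
  structure(list(kind = kind, gt_points = gt_points, gt_graph = gt_graph,
                 gt_centers = gt_centers, params = params, seed = seed),
            class = "phantom_truth")
}

# quasi-uniform points on a sphere (Fibonacci lattice)
fibonacci_sphere <- function(n, center, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * sin(phi) * cos(theta),
        center[2] + radius * sin(phi) * sin(theta),
        center[3] + radius * cos(phi))
}

#' Spherical-shell membrane phantom
#'
#' A union of non-overlapping spherical shells `| ||x - c|| - R | <= t/2`
#' with per-shell thickness drawn from `thickness_range` (membrane
#' segmentations in tomograms have non-uniform thickness, which this
#' emulates). Ground-truth points sample the exact mid-surfaces.
#'
#' @param shape volume dimensions (length-3 integer, or a scalar for a cube).
#' @param n_shells number of shells.
#' @param radius_range range the mid-surface radius is drawn from (voxels).
#' @param thickness_range range the shell thickness is drawn from
#'   (voxels, minimum 3).
#' @param seed RNG seed (mandatory: phantoms are reproducible by
#'   construction).
#' @param voxel_size nm per voxel.
#' @return A list with `seg` (a [binary_volume()]) and `truth`
#'   (kind `"membrane"`, `gt_points` on the mid-surfaces).
#' @export
membrane_phantom <- function(shape = c(128, 128, 128), n_shells = 2,
                             radius_range = c(18, 32),
                             thickness_range = c(4, 7), seed,
                             voxel_size = 1) {
  if (missing(seed)) stop_param("phantom generation requires a seed")
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  if (min(thickness_range) < 3) stop_param("shell thickness must be >= 3 voxels")
  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 3)
    radii <- numeric(0)
    thick <- numeric(0)
    attempts <- 0
    while (nrow(centers) < n_shells) {
      attempts <- attempts + 1
      if (attempts > 1000)
        stop_param("could not pack %d shells into the volume after 1000 attempts",
                   n_shells)
      R <- runif(1, radius_range[1], radius_range[2])
      t <- runif(1, thickness_range[1], thickness_range[2])
      outer <- R + t / 2
      lo <- outer + 2
      hi <- shape - 1 - outer - 2
      if (any(hi <= lo)) next
      c0 <- runif(3, lo, hi)
      if (nrow(centers) > 0) {
        dd <- sqrt(colSums((t(centers) - c0)^2))
        if (any(dd < outer + radii + thick / 2 + 2)) next
      }
      centers <- rbind(centers, c0)
      radii <- c(radii, R)
      thick <- c(thick, t)
    }
    vol <- array(0L, dim = shape)
    for (k in seq_len(n_shells)) {
      outer <- radii[k] + thick[k] / 2
      x0 <- max(0, floor(centers[k, 1] - outer)); x1 <- min(shape[1] - 1, ceiling(centers[k, 1] + outer))
      y0 <- max(0, floor(centers[k, 2] - outer)); y1 <- min(shape[2] - 1, ceiling(centers[k, 2] + outer))
      z0 <- max(0, floor(centers[k, 3] - outer)); z1 <- min(shape[3] - 1, ceiling(centers[k, 3] + outer))
      xs <- x0:x1; ys <- y0:y1; zs <- z0:z1
      dx2 <- (xs - centers[k, 1])^2
      dy2 <- (ys - centers[k, 2])^2
      dz2 <- (zs - centers[k, 3])^2
      dist <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
      sub <- abs(dist - radii[k]) <= thick[k] / 2
      block <- vol[xs + 1, ys + 1, zs + 1]
      block[sub] <- 1L
      vol[xs + 1, ys + 1, zs + 1] <- block
    }
    gt <- do.call(rbind, lapply(seq_len(n_shells), function(k) {
      npt <- max(100L, ceiling(4 * pi * radii[k]^2))
      fibonacci_sphere(npt, centers[k, ], radii[k])
    }))
    colnames(gt) <- c("x", "y", "z")
    list(seg = binary_volume(vol, voxel_size),
         truth = phantom_truth("membrane", gt,
                               params = list(centers = centers, radii = radii,
                                             thickness = thick), seed = seed))
  })
}

#' Wormlike-chain centerline
#'
#' Discrete wormlike chain: at each unit step the tangent is perturbed by
#' independent Gaussian angles of variance `step / persistence` in the two
#' transverse directions (small-angle regime), giving tangent correlations
#' `<t(s) . t(s + lag)> = exp(-lag / persistence)`.
#'
#' @param n_steps number of segments.
#' @param persistence persistence length in step units.
#' @param step segment length.
#' @param origin start point (length 3).
#' @param t0 initial tangent (normalized internally).
#' @param seed optional RNG seed; omit to consume the current RNG stream.
#' @return An `(n_steps + 1) x 3` matrix of points.
#' @export
wormlike_chain <- function(n_steps, persistence, step = 1,
                           origin = c(0, 0, 0), t0 = c(0, 0, 1),
                           seed = NULL) {
  gen <- function() {
    p <- matrix(0, n_steps + 1, 3)
    p[1, ] <- origin
    tv <- t0 / sqrt(sum(t0^2))
    sdev <- sqrt(step / persistence)
    for (i in seq_len(n_steps)) {
      # orthonormal transverse pair
      a <- if (abs(tv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- a - sum(a * tv) * tv
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(tv[2] * e1[3] - tv[3] * e1[2],
              tv[3] * e1[1] - tv[1] * e1[3],
              tv[1] * e1[2] - tv[2] * e1[1])
      g <- rnorm(2, 0, sdev)
      tv <- tv + g[1] * e1 + g[2] * e2
      tv <- tv / sqrt(sum(tv^2))
      p[i + 1, ] <- p[i, ] + step * tv
    }
    p
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# densify a polyline to roughly `spacing` between consecutive samples
densify_polyline <- function(p, spacing = 0.25) {
  out <- list()
  for (i in seq_len(nrow(p) - 1)) {
    a <- p[i, ]; b <- p[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / spacing))
    tt <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(a[1] + tt * (b[1] - a[1]),
                      a[2] + tt * (b[2] - a[2]),
                      a[3] + tt * (b[3] - a[3]))
  }
  rbind(do.call(rbind, out), p[nrow(p), , drop = FALSE])
}

# resample a polyline at unit arc spacing (for gt nodes)
resample_polyline <- function(p, spacing = 1) {
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  stargets <- seq(0, s[length(s)], by = spacing)
  idx <- findInterval(stargets, s, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(p) - 1L)
  f <- (stargets - s[idx]) / pmax(s[idx + 1L] - s[idx], 1e-12)
  p[idx, , drop = FALSE] + (p[idx + 1L, , drop = FALSE] -
                            p[idx, , drop = FALSE]) * f
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# straight polyline from a random interior point along a random direction,
# clipped to the margin box
random_segment <- function(shape, margin, min_len = 40) {
  lo <- margin
  hi <- shape - 1 - margin
  for (k in 1:50) {
    p0 <- runif(3, lo, hi)
    dirv <- random_unit_vector()
    tmax <- suppressWarnings(min(ifelse(dirv > 0, (hi - p0) / dirv,
                                        (lo - p0) / dirv)))
    tmin <- suppressWarnings(max(ifelse(dirv > 0, (lo - p0) / dirv,
                                        (hi - p0) / dirv)))
    if (tmax - tmin < min_len) next
    a <- p0 + tmin * dirv
    b <- p0 + tmax * dirv
    return(rbind(a, b))
  }
  NULL
}

#' Filament phantom: tubes around generated centerlines
#'
#' The foreground is the set of voxels within `tube_radius` of a generated
#' centerline. Kinds: `"straight"` line segments, `"helix"` (parameters
#' `helix_radius`, `pitch`), `"wormlike"` chains (parameter `persistence`,
#' voxels), and `"branched"` random trees with branch angles in
#' 60--150 degrees. The exact centerlines are returned as ground truth
#' together with their topology as a [spatial_graph()] (branch points have
#' degree 3).
#'
#' @inheritParams membrane_phantom
#' @param kind centerline type.
#' @param tube_radius tube radius in voxels (>= 2).
#' @param n_filaments number of filaments (trees for `"branched"`).
#' @param params optional list of kind-specific parameters (see above).
#' @return A list with `seg` (a [binary_volume()]) and `truth` (kind
#'   `"filament"`, `gt_points` at unit spacing along the exact centerlines,
#'   `gt_graph` the true topology).
#' @export
filament_phantom <- function(shape = c(128, 128, 128),
                             kind = c("straight", "helix", "wormlike",
                                      "branched"),
                             tube_radius = 4, n_filaments = 3,
                             params = list(), seed, voxel_size = 1) {
  kind <- match.arg(kind)
  if (missing(seed)) stop_param("phantom generation requires a seed")
  if (tube_radius < 2) stop_param("tube_radius must be >= 2 voxels")
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  margin <- tube_radius + 3
  with_seed(seed, {
    # each filament: list(polylines = list of point matrices,
    #                     joins = list of c(polyline_a, index_a, polyline_b))
    filaments <- list()
    all_coarse <- matrix(numeric(0), 0, 3)
    attempts <- 0
    while (length(filaments) < n_filaments) {
      attempts <- attempts + 1
      if (attempts > 1000)
        stop_param("could not place %d filaments after 1000 attempts",
                   n_filaments)
      fil <- generate_filament(kind, shape, margin, params)
      if (is.null(fil)) next
      coarse <- do.call(rbind, lapply(fil$polylines, resample_polyline,
                                      spacing = 2))
      if (nrow(all_coarse) > 0) {
        pr <- cross_radius_pairs_cpp(coarse, all_coarse, 2 * tube_radius + 3)
        if (length(pr$i) > 0) next
      }
      filaments[[length(filaments) + 1L]] <- fil
      all_coarse <- rbind(all_coarse, coarse)
    }
    dense <- do.call(rbind, lapply(filaments, function(f)
      do.call(rbind, lapply(f$polylines, densify_polyline, spacing = 0.25))))
    vol <- paint_balls_cpp(as.integer(shape), dense, tube_radius)
    gt_graph <- filament_gt_graph(filaments, voxel_size)
    gt_points <- cbind(gt_graph$nodes$x, gt_graph$nodes$y, gt_graph$nodes$z)
    colnames(gt_points) <- c("x", "y", "z")
    list(seg = binary_volume(array(vol, dim = shape), voxel_size),
         truth = phantom_truth("filament", gt_points, gt_graph = gt_graph,
                               params = c(params, list(kind = kind,
                                                       tube_radius = tube_radius)),
                               seed = seed))
  })
}

# one filament of the requested kind; NULL on placement failure
generate_filament <- function(kind, shape, margin, params) {
  lo <- margin
  hi <- shape - 1 - margin
  if (kind == "straight") {
    seg <- random_segment(shape, margin)
    if (is.null(seg)) return(NULL)
    return(list(polylines = list(seg), joins = list()))
  }
  if (kind == "helix") {
    r <- params$helix_radius %||% 10
    pitch <- params$pitch %||% 25
    cx <- runif(1, lo[1] + r, hi[1] - r)
    cy <- runif(1, lo[2] + r, hi[2] - r)
    if (cx - r < lo[1] || cy - r < lo[2]) return(NULL)
    z0 <- lo[3]; z1 <- hi[3]
    tt <- seq(0, (z1 - z0) / pitch * 2 * pi, length.out = 400)
    phase <- runif(1, 0, 2 * pi)
    p <- cbind(cx + r * cos(tt + phase), cy + r * sin(tt + phase),
               z0 + pitch * tt / (2 * pi))
    return(list(polylines = list(p), joins = list()))
  }
  if (kind == "wormlike") {
    pers <- params$persistence %||% 100
    p0 <- runif(3, lo + 10, hi - 10)
    p <- wormlike_chain(300, pers, step = 1, origin = p0,
                        t0 = random_unit_vector())
    inside <- p[, 1] >= lo[1] & p[, 1] <= hi[1] &
              p[, 2] >= lo[2] & p[, 2] <= hi[2] &
              p[, 3] >= lo[3] & p[, 3] <= hi[3]
    cut <- which(!inside)[1]
    if (!is.na(cut)) {
      if (cut < 60) return(NULL)
      p <- p[seq_len(cut - 1L), , drop = FALSE]
    }
    return(list(polylines = list(p), joins = list()))
  }
  # branched: straight trunk plus straight branches at 60-150 degrees
  trunk <- random_segment(shape, margin, min_len = 50)
  if (is.null(trunk)) return(NULL)
  trunk_pts <- resample_polyline(trunk, spacing = 1)
  n_branch <- params$n_branches %||% 2
  polylines <- list(trunk_pts)
  joins <- list()
  tangent <- trunk_pts[nrow(trunk_pts), ] - trunk_pts[1, ]
  tangent <- tangent / sqrt(sum(tangent^2))
  for (b in seq_len(n_branch)) {
    placed <- FALSE
    for (k in 1:50) {
      at <- sample(seq(10L, nrow(trunk_pts) - 10L), 1)
      base <- trunk_pts[at, ]
      ang <- runif(1, 60, 150) * pi / 180
      az <- runif(1, 0, 2 * pi)
      a <- if (abs(tangent[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- a - sum(a * tangent) * tangent
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(tangent[2] * e1[3] - tangent[3] * e1[2],
              tangent[3] * e1[1] - tangent[1] * e1[3],
              tangent[1] * e1[2] - tangent[2] * e1[1])
      dirv <- cos(ang) * tangent +
        sin(ang) * (cos(az) * e1 + sin(az) * e2)
      tmax <- suppressWarnings(min(ifelse(dirv > 0, (hi - base) / dirv,
                                          (lo - base) / dirv)))
      blen <- min(tmax, runif(1, 30, 60))
      if (blen < 20) next
      bp <- resample_polyline(rbind(base, base + blen * dirv), spacing = 1)
      polylines[[length(polylines) + 1L]] <- bp
      joins[[length(joins) + 1L]] <- c(1L, at, length(polylines))
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  list(polylines = polylines, joins = joins)
}

# ground-truth topology graph: unit-spaced nodes along each polyline,
# consecutive edges, plus join edges at branch points. The duplicated base
# point of a branch polyline is dropped: the branch chain attaches directly
# to its trunk node, which then has degree 3.
filament_gt_graph <- function(filaments, voxel_size) {
  nodes <- list()
  edges <- list()
  offset <- 0L
  for (f in filaments) {
    branch_of <- vapply(seq_along(f$polylines), function(pi) {
      hit <- Filter(function(j) j[3] == pi, f$joins)
      if (length(hit)) hit[[1]][2] else NA_integer_
    }, integer(1))
    starts <- integer(length(f$polylines))
    for (pi in seq_along(f$polylines)) {
      p <- resample_polyline(f$polylines[[pi]], spacing = 1)
      if (!is.na(branch_of[pi])) p <- p[-1, , drop = FALSE]
      idx <- offset + seq_len(nrow(p))
      starts[pi] <- idx[1]
      nodes[[length(nodes) + 1L]] <-
        data.frame(id = idx, x = p[, 1], y = p[, 2], z = p[, 3])
      if (nrow(p) > 1)
        edges[[length(edges) + 1L]] <-
          data.frame(source = idx[-length(idx)], target = idx[-1])
      offset <- offset + nrow(p)
    }
    for (j in f$joins) {
      trunk_node <- starts[j[1]] + j[2] - 1L
      edges[[length(edges) + 1L]] <-
        data.frame(source = trunk_node, target = starts[j[3]])
    }
  }
  nd <- do.call(rbind, nodes)
  ed <- if (length(edges)) do.call(rbind, edges) else NULL
  spatial_graph(nd, ed, voxel_size)
}

#' Solid-sphere blob phantom
#'
#' `n_blobs` non-overlapping solid balls with pairwise center separation at
#' least `min_separation`; the exact centers are the ground truth.
#'
#' @inheritParams membrane_phantom
#' @param n_blobs number of spheres.
#' @param radius sphere radius in voxels.
#' @param min_separation minimum pairwise center distance in voxels.
#' @return A list with `seg` and `truth` (kind `"blob"`, `gt_centers`).
#' @export
blob_phantom <- function(shape = c(128, 128, 128), n_blobs = 20, radius = 5,
                         min_separation = 20, seed, voxel_size = 1) {
  if (missing(seed)) stop_param("phantom generation requires a seed")
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  with_seed(seed, {
    lo <- radius + 2
    hi <- shape - 1 - radius - 2
    centers <- matrix(numeric(0), 0, 3)
    attempts <- 0
    while (nrow(centers) < n_blobs) {
      attempts <- attempts + 1
      if (attempts > 1000)
        stop_param("could not pack %d blobs after 1000 attempts", n_blobs)
      c0 <- runif(3, lo, hi)
      if (nrow(centers) > 0 &&
          any(sqrt(colSums((t(centers) - c0)^2)) < min_separation)) next
      centers <- rbind(centers, c0)
    }
    colnames(centers) <- c("x", "y", "z")
    vol <- paint_balls_cpp(as.integer(shape), centers, radius)
    list(seg = binary_volume(array(vol, dim = shape), voxel_size),
         truth = phantom_truth("blob", centers, gt_centers = centers,
                               params = list(radius = radius,
                                             min_separation = min_separation),
                               seed = seed))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# zero-padding shift (dilation must not replicate border planes)
shift_zero <- function(a, axis, by) {
  d <- dim(a)
  out <- array(0L, dim = d)
  src <- lapply(d, seq_len)
  dst <- lapply(d, seq_len)
  if (by > 0) {
    dst[[axis]] <- (1 + by):d[axis]
    src[[axis]] <- 1:(d[axis] - by)
  } else if (by < 0) {
    dst[[axis]] <- 1:(d[axis] + by)
    src[[axis]] <- (1 - by):d[axis]
  }
  out <- do.call(`[<-`, c(list(out), dst,
                          list(do.call(`[`, c(list(a), src,
                                              list(drop = FALSE))))))
  out
}

#' Morphological dilation of a binary volume
#'
#' Iterative dilation with the 6-connected (face-neighbor) structuring
#' element by default, or the full 26-connected cube. Used to emulate
#' segmentations of growing thickness when studying metric robustness.
#' Note that iterating a discrete structuring element grows a shape by its
#' L1 (6-connected) or Linf (26-connected) ball, which progressively facets
#' curved surfaces; `connectivity = "ball"` instead grows the foreground by
#' an exact Euclidean distance of `iterations` voxels (computed from the
#' distance transform of the complement), which thickens a shape without
#' deforming it and is the right control when only thickness differences
#' are under study.
#'
#' @param seg a [binary_volume()].
#' @param iterations number of dilation iterations (>= 0; 0 is the
#'   identity). For `"ball"`, the Euclidean growth radius in voxels.
#' @param connectivity 6 (faces), 26 (full neighborhood), or `"ball"`
#'   (Euclidean).
#' @return A [binary_volume()].
#' @export
dilate <- function(seg, iterations, connectivity = 6) {
  if (!inherits(seg, "binary_volume")) stop_param("expected a binary_volume")
  if (!is.numeric(iterations) || iterations < 0)
    stop_param("iterations must be >= 0")
  if (!(as.character(connectivity) %in% c("6", "26", "ball")))
    stop_param("connectivity must be 6, 26 or \"ball\"")
  if (identical(as.character(connectivity), "ball")) {
    if (iterations == 0) return(seg)
    d <- dim(seg$data)
    # distance of every background voxel to the nearest foreground voxel:
    # run the transform on the complement, padded so that the transform's
    # border-as-background convention cannot reach back into the volume
    pad <- as.integer(ceiling(iterations) + 1L)
    dp <- d + 2L * pad
    comp <- array(1L, dim = dp)
    comp[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
      1L - seg$data
    dt2 <- array(edt_sq_cpp(as.integer(comp), as.integer(dp)), dim = dp)
    dt2 <- dt2[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])]
    grown <- array(as.integer(seg$data == 1L | dt2 <= iterations^2), dim = d)
    return(binary_volume(grown, seg$voxel_size))
  }
  a <- seg$data
  for (it in seq_len(iterations)) {
    if (connectivity == 6) {
      b <- a
      for (axis in 1:3) {
        b <- b | shift_zero(a, axis, 1L) | shift_zero(a, axis, -1L)
      }
      a <- array(as.integer(b), dim = dim(a))
    } else {
      b <- a
      for (axis in 1:3) {
        b <- b | shift_zero(b, axis, 1L) | shift_zero(b, axis, -1L)
      }
      a <- array(as.integer(b), dim = dim(a))
    }
  }
  binary_volume(a, seg$voxel_size)
}
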