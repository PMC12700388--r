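#' Skeleton point cloud
#'
#' The set of non-maximum-suppression survivors at a given intrinsic
#' dimension `d`: blob centers (`d = 0`), filament centerlines (`d = 1`),
#' or membrane center-surfaces (`d = 2`). Points carry 0-based voxel-unit
#' coordinates.
#'
#' @param points `n x 3` numeric matrix of coordinates (voxel units).
#' @param d skeleton dimension, 0, 1 or 2.
#' @param voxel_size nm per voxel.
#' @param shape dimensions of the source volume.
#' @return An object of class `skeleton_cloud`.
#' @export
skeleton_cloud <- function(points, d, voxel_size = 1, shape = NULL) {
  points <- as.matrix(points)
  if (nrow(points) > 0 && ncol(points) != 3L)
    stop_param("skeleton points must be an n x 3 matrix")
  if (nrow(points) == 0L) points <- matrix(numeric(0), 0, 3)
  if (!(d %in% 0:2)) stop_param("skeleton dimension d must be 0, 1 or 2")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, d = as.integer(d),
                 voxel_size = voxel_size, shape = shape),
            class = "skeleton_cloud")
}

#' @export
print.skeleton_cloud <- function(x, ...) {
  cat(sprintf("<skeleton_cloud> d = %d, %d points, voxel size %g nm\n",
              x$d, nrow(x$points), x$voxel_size))
  invisible(x)
}

#' Non-maximum suppression along Hessian eigenvector directions
#'
#' A voxel with saliency at least `threshold` belongs to the dimension-`d`
#' skeleton iff its value strictly exceeds the interpolated saliency at
#' `+/- delta` along each of the top `3 - d` eigenvector directions:
#' all three directions for blob centers (`d = 0`), the top two for
#' centerlines (`d = 1`), the principal one for center-surfaces (`d = 2`).
#' Probes are trilinearly interpolated with coordinates clamped to the
#' volume; the one-voxel border is excluded. Strict inequalities keep the
#' skeleton one voxel thick (a plateau never qualifies).
#'
#' @param S a [scalar_volume()] saliency map.
#' @param eig an `eigen_field` from [eig3_symmetric()] of the same shape.
#' @param d skeleton dimension (0, 1 or 2).
#' @param delta probe step in voxels (> 0). Default 1/3 voxel: sub-voxel
#'   probing is consistent with a one-voxel-thick skeleton; a multi-voxel
#'   step can be selected explicitly.
#' @param threshold minimum saliency for a voxel to be evaluated (>= 0).
#' @return A [skeleton_cloud()].
#' @export
nms <- function(S, eig, d, delta = 1/3, threshold = 0) {
  if (!inherits(S, "scalar_volume")) stop_param("S must be a scalar_volume")
  if (!inherits(eig, "eigen_field")) stop_param("eig must be an eigen_field")
  if (!identical(dim(S$data), as.integer(eig$dim)) &&
      !identical(as.integer(dim(S$data)), as.integer(eig$dim)))
    stop_param("saliency map and eigen field shapes differ")
  if (!(d %in% 0:2)) stop_param("d must be 0, 1 or 2")
  if (!is.numeric(delta) || delta <= 0) stop_param("delta must be positive")
  if (!is.numeric(threshold) || threshold < 0)
    stop_param("threshold must be non-negative")
  pts <- nms_cpp(as.vector(S$data), as.integer(dim(S$data)), eig$vectors,
                 as.integer(d), delta, threshold)
  skeleton_cloud(matrix(as.numeric(pts), ncol = 3,
                        dimnames = list(NULL, c("x", "y", "z"))),
                 d, S$voxel_size, dim(S$data))
}

#' Voxel-grid downsampling of a skeleton cloud
#'
#' Partitions space into cubic cells of edge `spacing` and keeps, per
#' occupied cell, the point nearest the cell centroid (ties broken by the
#' lowest original index). Subsampling reduces the impact of isolated false
#' detections and the cost of graph construction.
#'
#' @param cloud a [skeleton_cloud()].
#' @param spacing cell edge in voxels; 0 disables downsampling.
#' @return A [skeleton_cloud()] with at most as many points as the input.
#' @export
downsample <- function(cloud, spacing) {
  if (!inherits(cloud, "skeleton_cloud")) stop_param("expected a skeleton_cloud")
  if (!is.numeric(spacing) || spacing < 0)
    stop_param("spacing must be non-negative")
  if (spacing == 0 || nrow(cloud$points) == 0L) return(cloud)
  p <- cloud$points
  cell <- floor(p / spacing)
  keyf <- interaction(cell[, 1], cell[, 2], cell[, 3], drop = TRUE)
  centroid <- (cell + 0.5) * spacing
  d2 <- rowSums((p - centroid)^2)
  ord <- order(keyf, d2, seq_len(nrow(p)))
  keep <- ord[!duplicated(keyf[ord])]
  keep <- sort(keep)
  skeleton_cloud(p[keep, , drop = FALSE], cloud$d, cloud$voxel_size,
                 cloud$shape)
}

#' Skeletonize a binary segmentation
#'
#' Convenience composition of the full common path:
#' [saliency_from_segmentation()] (distance transform + Gaussian),
#' [hessian()], [eig3_symmetric()], [nms()] and [downsample()].
#'
#' @inheritParams nms
#' @inheritParams saliency_from_segmentation
#' @param seg a [binary_volume()].
#' @param spacing downsampling cell edge in voxels (0 = off).
#' @param scheme finite-difference scheme, see [first_derivatives()].
#' @return A [skeleton_cloud()].
#' @export
skeletonize <- function(seg, d, sigma = 2, delta = 1/3, threshold = 0,
                        spacing = 0, scheme = c("centered", "forward")) {
  scheme <- match.arg(scheme)
  S <- saliency_from_segmentation(seg, sigma)
  eig <- eig3_symmetric(hessian(S, scheme))
  cloud <- nms(S, eig, d, delta, threshold)
  downsample(cloud, spacing)
}
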