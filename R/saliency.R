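#' Saliency map from a binary segmentation
#'
#' Converts a binary segmentation into a smooth, differentiable scalar map
#' whose ridges are the structure's skeleton: each foreground voxel gets its
#' Euclidean distance to the nearest background voxel (the volume border
#' counts as background), background stays 0, and the distance map is then
#' smoothed with an isotropic Gaussian. The result is non-negative and
#' vanishes far from the foreground, and its ridge at the middle of a
#' structure is what non-maximum suppression later extracts.
#'
#' When a float saliency map is already available (e.g. a network
#' probability map), this step is unnecessary: [nms()] and [skeletonize()]
#' accept any [scalar_volume()] directly.
#'
#' @param seg a [binary_volume()] with at least one foreground voxel.
#' @param sigma Gaussian standard deviation in voxels (> 0); default 2,
#'   the value used for the worked filament-tracing example.
#' @return A [scalar_volume()] of the same shape; an empty segmentation
#'   yields an all-zero volume with a warning.
#' @export
saliency_from_segmentation <- function(seg, sigma = 2) {
  if (!inherits(seg, "binary_volume"))
    stop_param("saliency_from_segmentation expects a binary_volume")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_param("sigma must be a single positive number")
  d <- dim(seg$data)
  if (sum(seg$data) == 0L) {
    warning("segmentation has no foreground voxels; returning zero saliency")
    return(scalar_volume(array(0, dim = d), seg$voxel_size))
  }
  dt <- sqrt(edt_sq_cpp(as.integer(seg$data), as.integer(d)))
  sm <- gauss3_cpp(dt, as.integer(d), sigma)
  scalar_volume(array(sm, dim = d), seg$voxel_size)
}
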