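#' @useDynLib skeletrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm
#' @importFrom utils read.csv write.csv head
NULL

# condition helpers: typed errors so callers (and the CLI) can distinguish
# bad parameters from bad files
stop_param <- function(...) {
  stop(errorCondition(sprintf(...), class = c("skeletrace_param_error", "error")))
}
stop_format <- function(...) {
  stop(errorCondition(sprintf(...), class = c("skeletrace_format_error", "error")))
}
stop_io <- function(...) {
  stop(errorCondition(sprintf(...), class = c("skeletrace_io_error", "error")))
}

check_shape3 <- function(data) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L)
    stop_param("volume data must be a 3D array")
  if (any(d < 3L))
    stop_param("volume must span at least 3 voxels per axis, got %s",
               paste(d, collapse = "x"))
  d
}

#' Scalar volume (saliency map)
#'
#' A 3D field of real values indexed `(x, y, z)` with isotropic voxel size in
#' nanometres. This is the container for saliency maps: scalar fields whose
#' ridges trace the skeleton of a segmented structure. Coordinates used
#' throughout the package are 0-based voxel indices; positions in nanometres
#' are `index * voxel_size`.
#'
#' @param data 3D numeric array, all values finite, at least 3 voxels per axis.
#' @param voxel_size voxel edge length in nm (> 0).
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, voxel_size = 1) {
  check_shape3(data)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop_param("voxel_size must be a single positive number")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop_param("scalar volume contains non-finite values")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = c("scalar_volume", "volume"))
}

#' Binary volume (segmentation mask)
#'
#' A 3D mask of `{0, 1}` values with voxel size metadata, the form in which
#' single-structure segmentations enter the pipeline.
#'
#' @inheritParams scalar_volume
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(data, voxel_size = 1) {
  check_shape3(data)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop_param("voxel_size must be a single positive number")
  storage.mode(data) <- "integer"
  if (anyNA(data) || !all(data == 0L | data == 1L))
    stop_param("binary volume values must all be 0 or 1")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = c("binary_volume", "volume"))
}

#' Label volume (multi-class segmentation)
#'
#' A 3D grid of small non-negative integer class labels; label 0 is reserved
#' for background.
#'
#' @inheritParams scalar_volume
#' @param label_names optional named character vector mapping label -> class name.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_size = 1, label_names = NULL) {
  check_shape3(data)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop_param("voxel_size must be a single positive number")
  storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0L))
    stop_param("label volume values must be non-negative integers")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 label_names = label_names),
            class = c("label_volume", "volume"))
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, voxel size %g nm\n",
              class(x)[1], d[1], d[2], d[3], x$voxel_size))
  if (inherits(x, "binary_volume")) {
    cat(sprintf("  foreground voxels: %d\n", sum(x$data)))
  } else if (inherits(x, "label_volume")) {
    cat(sprintf("  labels: %s\n", paste(sort(unique(as.vector(x$data))),
                                        collapse = ", ")))
  } else {
    cat(sprintf("  value range: [%g, %g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' Isolate one label of a multi-class segmentation as a binary mask
#'
#' @param vol a [label_volume()] (a [binary_volume()] is also accepted).
#' @param label integer label to isolate; 0 selects the background.
#' @return A [binary_volume()] that is 1 exactly where `vol` equals `label`.
#'   An absent label yields an all-zero mask with a warning.
#' @export
isolate_label <- function(vol, label) {
  if (!inherits(vol, "volume") || inherits(vol, "scalar_volume"))
    stop_param("isolate_label expects a label or binary volume")
  label <- as.integer(label)
  mask <- array(as.integer(vol$data == label), dim = dim(vol$data))
  if (label != 0L && sum(mask) == 0L)
    warning(sprintf("label %d not present in volume; mask is empty", label))
  binary_volume(mask, vol$voxel_size)
}
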