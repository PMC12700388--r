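# MRC2014 volume I/O.
#
# MRC stores the data grid column-fastest; with the default axis mapping
# (mapc, mapr, maps) = (1, 2, 3) the fastest axis is x, which matches R's
# column-major array layout directly, so a volume reads into an array
# indexed [x, y, z] with no copy. Non-default axis mappings are permuted to
# (x, y, z) order on read. Cell dimensions are stored in Angstrom; voxel
# sizes in this package are nm, so headers are converted by a factor 10.
# Files are read and written little-endian.

MRC_HEADER_BYTES <- 1024L

#' Read a tomographic volume from an MRC2014 file
#'
#' Integer modes (0: int8, 1: int16, 6: uint16) yield a [binary_volume()]
#' when only values 0/1 are present and a [label_volume()] otherwise;
#' float mode 2 yields a [scalar_volume()]. The voxel size (nm) is taken
#' from the header cell spacing (Angstrom / 10).
#'
#' @param path path to an MRC2014 file.
#' @return A `scalar_volume`, `binary_volume` or `label_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_io("cannot read '%s': no such file", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- function(n) readBin(con, "integer", n = n, size = 4L,
                                  endian = "little")
  hdr_floats <- function(n) readBin(con, "double", n = n, size = 4L,
                                    endian = "little")
  nxyz <- hdr_ints(3)
  mode <- hdr_ints(1)
  invisible(hdr_ints(3))             # nxstart, nystart, nzstart
  mxyz <- hdr_ints(3)
  cella <- hdr_floats(3)
  invisible(hdr_floats(3))           # cellb
  mapcrs <- hdr_ints(3)
  if (length(mode) < 1L || length(mapcrs) < 3L)
    stop_format("truncated MRC header in '%s'", path)
  if (any(nxyz <= 0L) || any(nxyz > 16384L))
    stop_format("implausible MRC dimensions in '%s'", path)
  if (!(mode %in% c(0L, 1L, 2L, 6L)))
    stop_format("unsupported MRC mode %d in '%s' (supported: 0, 1, 2, 6)",
                mode, path)
  invisible(hdr_floats(3))           # dmin, dmax, dmean
  invisible(hdr_ints(1))             # ispg
  nsymbt <- hdr_ints(1)
  if (length(nsymbt) < 1L) stop_format("truncated MRC header in '%s'", path)
  seek(con, MRC_HEADER_BYTES + nsymbt)

  n <- prod(nxyz)
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                  endian = "little"))
  if (length(data) < n)
    stop_format("truncated MRC data in '%s': expected %d values, got %d",
                path, n, length(data))
  arr <- array(data, dim = nxyz)
  if (!identical(mapcrs, 1:3)) {
    if (!setequal(mapcrs, 1:3))
      stop_format("invalid MRC axis mapping (%s) in '%s'",
                  paste(mapcrs, collapse = ","), path)
    arr <- aperm(arr, match(1:3, mapcrs))
  }
  voxel_size <- 1
  if (all(mxyz > 0L) && all(cella > 0)) {
    vs <- cella / mxyz / 10          # Angstrom -> nm
    voxel_size <- vs[1]
  }
  if (mode == 2L) {
    scalar_volume(arr, voxel_size)
  } else if (all(arr == 0L | arr == 1L)) {
    binary_volume(arr, voxel_size)
  } else if (all(arr >= 0L)) {
    label_volume(arr, voxel_size)
  } else {
    stop_format("integer MRC '%s' holds negative labels", path)
  }
}

#' Write a volume to an MRC2014 file
#'
#' Binary volumes are stored as mode 0 (int8), label volumes as mode 1
#' (int16), scalar volumes as mode 2 (float32). The voxel size is recorded
#' in the header cell dimensions (Angstrom).
#'
#' @param vol a volume object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "volume")) stop_param("write_volume expects a volume")
  d <- dim(vol$data)
  mode <- if (inherits(vol, "scalar_volume")) 2L
          else if (inherits(vol, "binary_volume")) 0L
          else 1L
  if (mode == 1L && max(vol$data) > 32767L)
    stop_param("label values exceed int16 range")
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_io("cannot write '%s'", path))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  cella <- d * vol$voxel_size * 10   # nm -> Angstrom
  dat <- as.vector(vol$data)
  wi(d)                              # nx ny nz
  wi(mode)
  wi(c(0L, 0L, 0L))                  # nxstart
  wi(d)                              # mx my mz
  wf(cella)
  wf(c(90, 90, 90))                  # cellb
  wi(1:3)                            # mapc mapr maps
  if (mode == 2L) {
    wf(c(min(dat), max(dat), mean(dat)))
  } else {
    wf(c(min(dat), max(dat), mean(dat)))
  }
  wi(1L)                             # ispg: volume
  wi(0L)                             # nsymbt
  writeBin(raw(100), con)            # extra
  wf(c(0, 0, 0))                     # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(dat))                 # rms
  wi(0L)                             # nlabl
  writeBin(raw(800), con)            # labels
  switch(as.character(mode),
    "0" = writeBin(as.integer(dat), con, size = 1L),
    "1" = writeBin(as.integer(dat), con, size = 2L, endian = "little"),
    "2" = writeBin(as.numeric(dat), con, size = 4L, endian = "little"))
  invisible(path)
}

#' Write a point table to CSV
#'
#' Writes columns `x,y,z` (voxel units) plus any extra per-point columns,
#' one row per point, with 9 significant digits so coordinates round-trip
#' to well below 1e-6 voxel.
#'
#' @param points an `n x 3` matrix, a data frame with columns `x,y,z`
#'   (plus extras), or a [skeleton_cloud()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path) {
  df <- as_point_df(points)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 9))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write points to '%s'", path)
  invisible(path)
}

as_point_df <- function(points) {
  if (inherits(points, "skeleton_cloud")) {
    points <- points$points
  }
  if (is.matrix(points)) {
    if (ncol(points) < 3L && nrow(points) > 0L)
      stop_param("point matrix must have at least 3 columns")
    if (nrow(points) == 0L)
      return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
    df <- as.data.frame(points)
    names(df)[1:3] <- c("x", "y", "z")
    return(df)
  }
  if (is.data.frame(points)) {
    if (!all(c("x", "y", "z") %in% names(points)))
      stop_param("point data frame must have columns x, y, z")
    return(points)
  }
  stop_param("unsupported point container of class '%s'", class(points)[1])
}

#' Read a point table written by [write_points()]
#'
#' @param path CSV path with at least columns `x,y,z`.
#' @return A data frame.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop_io("cannot read '%s': no such file", path)
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df)))
    stop_format("'%s' lacks x,y,z columns", path)
  df
}

#' Write a spatial graph to CSV tables (and optionally VTK polydata)
#'
#' Writes `<prefix>_nodes.csv` with columns `id,x,y,z,filament_id` and
#' `<prefix>_edges.csv` with columns `source,target,length`. With
#' `vtk = TRUE` a legacy-ASCII VTK polydata file `<prefix>.vtk` holding the
#' same polyline set is written for visualization.
#'
#' @param graph a [spatial_graph()].
#' @param path_prefix path prefix for the output files.
#' @param vtk also write `<prefix>.vtk`.
#' @return The node table path, invisibly.
#' @export
write_graph <- function(graph, path_prefix, vtk = FALSE) {
  if (!inherits(graph, "spatial_graph")) stop_param("expected a spatial_graph")
  nodes <- graph$nodes
  edges <- graph$edges
  nd <- data.frame(id = nodes$id,
                   x = signif(nodes$x, 9), y = signif(nodes$y, 9),
                   z = signif(nodes$z, 9),
                   filament_id = if (is.null(nodes$filament_id))
                     rep(NA_integer_, nrow(nodes)) else nodes$filament_id)
  ed <- data.frame(source = edges$source, target = edges$target,
                   length = signif(edges$length, 9))
  npath <- paste0(path_prefix, "_nodes.csv")
  epath <- paste0(path_prefix, "_edges.csv")
  ok <- tryCatch({
    utils::write.csv(nd, npath, row.names = FALSE, quote = FALSE)
    utils::write.csv(ed, epath, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write graph tables with prefix '%s'", path_prefix)
  if (isTRUE(vtk)) {
    vpath <- paste0(path_prefix, ".vtk")
    lines <- c("# vtk DataFile Version 3.0", "spatial graph", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(nd)))
    pts <- sprintf("%g %g %g", nd$x, nd$y, nd$z)
    lines <- c(lines, pts,
               sprintf("LINES %d %d", nrow(ed), 3L * nrow(ed)))
    src0 <- match(ed$source, nd$id) - 1L
    dst0 <- match(ed$target, nd$id) - 1L
    lines <- c(lines, sprintf("2 %d %d", src0, dst0))
    writeLines(lines, vpath)
  }
  invisible(npath)
}
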