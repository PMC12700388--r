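# Finite-difference derivatives, the Hessian tensor field and its
# per-voxel eigen-decomposition.

# shift a 3D array by one voxel along an axis with replicate padding
shift_arr <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]] + by
  i[i < 1L] <- 1L
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

diff_axis <- function(a, axis, scheme) {
  if (scheme == "centered") {
    (shift_arr(a, axis, 1L) - shift_arr(a, axis, -1L)) / 2
  } else {
    shift_arr(a, axis, 1L) - a
  }
}

#' First partial derivatives of a scalar volume
#'
#' Derivatives are taken by direct subtraction of adjacent voxel values:
#' `forward` uses `S(x + e_i) - S(x)`, `centered` (the default) uses
#' `(S(x + e_i) - S(x - e_i)) / 2`. Boundaries use replicate padding. The
#' forward scheme is the literal one-sided stencil; it shifts features by
#' half a voxel, so the centered scheme is preferred for unbiased skeletons
#' on symmetric structures.
#'
#' @param S a [scalar_volume()].
#' @param scheme `"centered"` or `"forward"`.
#' @return A list with components `x`, `y`, `z`, each a 3D array.
#' @export
first_derivatives <- function(S, scheme = c("centered", "forward")) {
  scheme <- match.arg(scheme)
  if (!inherits(S, "scalar_volume")) stop_param("expected a scalar_volume")
  list(x = diff_axis(S$data, 1L, scheme),
       y = diff_axis(S$data, 2L, scheme),
       z = diff_axis(S$data, 3L, scheme))
}

#' Hessian tensor field of a scalar volume
#'
#' Second derivatives are obtained by differentiating the first
#' derivatives with the same stencil, so the discrete operators commute and
#' the tensor is symmetric by construction; only the six independent
#' components are stored.
#'
#' @inheritParams first_derivatives
#' @return An object of class `hessian_field` with components `xx`, `yy`,
#'   `zz`, `xy`, `xz`, `yz` (3D arrays), plus `dim` and `voxel_size`.
#' @export
hessian <- function(S, scheme = c("centered", "forward")) {
  scheme <- match.arg(scheme)
  g <- first_derivatives(S, scheme)
  structure(list(
    xx = diff_axis(g$x, 1L, scheme),
    yy = diff_axis(g$y, 2L, scheme),
    zz = diff_axis(g$z, 3L, scheme),
    xy = diff_axis(g$y, 1L, scheme),
    xz = diff_axis(g$z, 1L, scheme),
    yz = diff_axis(g$z, 2L, scheme),
    dim = dim(S$data), voxel_size = S$voxel_size),
    class = "hessian_field")
}

#' Per-voxel eigen-decomposition of a Hessian field
#'
#' Solves the symmetric 3x3 eigenproblem analytically at every voxel: the
#' characteristic cubic by the trigonometric Cardano formula, eigenvectors
#' by cross products of rows of `H - lambda I`. When the spectrum is nearly
#' degenerate (relative eigenvalue gap below `degtol`) the voxel falls back
#' to cyclic Jacobi rotations, which are unconditionally stable. Output is
#' sorted by descending eigenvalue magnitude, `|lambda1| >= |lambda2| >=
#' |lambda3|`; eigenvectors are unit length and mutually orthogonal.
#' Eigenvector sign is arbitrary (downstream non-maximum suppression probes
#' both `+delta v` and `-delta v`).
#'
#' @param H a `hessian_field` from [hessian()].
#' @param degtol relative eigenvalue-gap threshold for the Jacobi fallback.
#' @return An object of class `eigen_field` with `values` (`n x 3` matrix,
#'   voxels in linear x-fastest order) and `vectors` (`n x 9` matrix, rows
#'   `v1x v1y v1z v2x ... v3z`), plus `dim` and `voxel_size`.
#' @export
eig3_symmetric <- function(H, degtol = 1e-6) {
  if (!inherits(H, "hessian_field")) stop_param("expected a hessian_field")
  res <- eig3_field_cpp(as.vector(H$xx), as.vector(H$yy), as.vector(H$zz),
                        as.vector(H$xy), as.vector(H$xz), as.vector(H$yz),
                        degtol)
  structure(list(values = res$values, vectors = res$vectors,
                 dim = H$dim, voxel_size = H$voxel_size),
            class = "eigen_field")
}
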