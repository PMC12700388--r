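# Local and global geometric descriptors of discrete filament curves.

#' Discrete filament curve
#'
#' An ordered 3D point sequence representing one traced filament.
#' Consecutive points must be distinct.
#'
#' @param points `n x 3` matrix of ordered coordinates (voxel units),
#'   `n >= 2`.
#' @param voxel_size nm per voxel.
#' @return An object of class `filament_curve`.
#' @export
filament_curve <- function(points, voxel_size = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 2L || ncol(points) != 3L)
    stop_param("a curve needs an n x 3 matrix with n >= 2")
  seglen <- sqrt(rowSums((points[-1, , drop = FALSE] -
                          points[-nrow(points), , drop = FALSE])^2))
  if (any(seglen == 0))
    stop_param("consecutive curve points must be distinct")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, voxel_size = voxel_size),
            class = "filament_curve")
}

#' @export
print.filament_curve <- function(x, ...) {
  gp <- global_properties(x)
  cat(sprintf("<filament_curve> %d points, length %.2f nm, sinuosity %.3f\n",
              nrow(x$points), gp$length, gp$sinuosity))
  invisible(x)
}

#' Local geometric properties of a discrete curve
#'
#' Per-point descriptors, all in nm-based units:
#' * `s` — geodesic (cumulative chord) distance to the curve origin;
#' * `tangent` — unit tangent, centered difference at interior points and
#'   one-sided at the endpoints;
#' * `curvature` — unsigned Menger curvature of each interior point triple,
#'   `4 * Area / (a b c)` with `a, b, c` the triangle side lengths (1/nm);
#' * `torsion` — signed discrete torsion from the tetrahedron spanned by
#'   four consecutive points: with difference vectors `e1, e2, e3`,
#'   `tau = ((e1 x e2) . e3) / (|e1 x e2| |e2 x e3|)`, which converges to
#'   the Frenet torsion (verified against the analytic helix); the sign
#'   carries handedness (1/nm).
#'
#' Endpoint values of curvature and torsion are replicated from the
#' nearest interior point. Curves too short for an estimator (3 points for
#' curvature, 4 for torsion) get zero-padded arrays with a warning.
#'
#' @param curve a [filament_curve()].
#' @return A list with `s`, `tangent` (`n x 3`), `curvature`, `torsion`.
#' @export
local_properties <- function(curve) {
  if (!inherits(curve, "filament_curve")) stop_param("expected a filament_curve")
  p <- curve$points * curve$voxel_size
  n <- nrow(p)
  seg <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
  seglen <- sqrt(rowSums(seg^2))
  s <- c(0, cumsum(seglen))

  tangent <- matrix(0, n, 3)
  if (n >= 3) {
    ctr <- p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]
    tangent[2:(n - 1), ] <- ctr / sqrt(rowSums(ctr^2))
  }
  tangent[1, ] <- seg[1, ] / seglen[1]
  tangent[n, ] <- seg[n - 1, ] / seglen[n - 1]

  curvature <- numeric(n)
  if (n >= 3) {
    a <- p[1:(n - 2), , drop = FALSE]
    b <- p[2:(n - 1), , drop = FALSE]
    cc <- p[3:n, , drop = FALSE]
    ab <- b - a; acv <- cc - a; bc <- cc - b
    cr <- cbind(ab[, 2] * acv[, 3] - ab[, 3] * acv[, 2],
                ab[, 3] * acv[, 1] - ab[, 1] * acv[, 3],
                ab[, 1] * acv[, 2] - ab[, 2] * acv[, 1])
    area2 <- sqrt(rowSums(cr^2))           # twice the triangle area
    la <- sqrt(rowSums(ab^2))
    lb <- sqrt(rowSums(bc^2))
    lc <- sqrt(rowSums(acv^2))
    curvature[2:(n - 1)] <- 2 * area2 / (la * lb * lc)
    curvature[1] <- curvature[2]
    curvature[n] <- curvature[n - 1]
  } else {
    warning("curve too short for curvature; returning zeros")
  }

  torsion <- numeric(n)
  if (n >= 4) {
    e1 <- seg[1:(n - 3), , drop = FALSE]
    e2 <- seg[2:(n - 2), , drop = FALSE]
    e3 <- seg[3:(n - 1), , drop = FALSE]
    c12 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    c23 <- cbind(e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
                 e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
                 e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
    det <- rowSums(c12 * e3)
    denom <- sqrt(rowSums(c12^2)) * sqrt(rowSums(c23^2))
    tau <- ifelse(denom > 1e-12, det / denom, 0)
    torsion[2:(n - 2)] <- tau
    torsion[1] <- torsion[2]
    torsion[n - 1] <- torsion[n - 2]
    torsion[n] <- torsion[n - 1]
  } else {
    warning("curve too short for torsion; returning zeros")
  }

  list(s = s, tangent = tangent, curvature = curvature, torsion = torsion)
}

#' Global geometric properties of a discrete curve
#'
#' * `length` — geodesic length `L` (nm);
#' * `sinuosity` — `L` over end-to-end distance (`Inf` for coincident
#'   endpoints, with a warning); always >= 1;
#' * `total_curvature` — `sum(kappa_i * ds_i)` (radians), with `ds_i` the
#'   half-neighborhood arc length of point i;
#' * `total_torsion` — `sum(|tau_i| * ds_i)` (radians);
#' * `persistence_length` — decay length of the tangent-tangent
#'   correlation: least-squares fit through the origin of
#'   `log <t(s) . t(s + lag)> = -lag / Lp` over lags up to `L / 2`
#'   (only lags with positive mean correlation enter the log fit); `Inf`
#'   for a perfectly straight curve. Correlations use the segment
#'   directions (chord tangents), which are unsmoothed; centered-difference
#'   tangents would inflate the estimate. Per-curve estimates on chains
#'   not much longer than `Lp` are noisy — prefer
#'   [pooled_persistence_length()] across a filament population.
#'
#' @param curve a [filament_curve()].
#' @return A list with the fields above.
#' @export
global_properties <- function(curve) {
  if (!inherits(curve, "filament_curve")) stop_param("expected a filament_curve")
  lp <- local_properties(curve)
  p <- curve$points * curve$voxel_size
  n <- nrow(p)
  L <- lp$s[n]
  ee <- sqrt(sum((p[n, ] - p[1, ])^2))
  if (ee < 1e-9 * max(1, L)) {
    warning("coincident curve endpoints; sinuosity undefined (Inf)")
    sinuosity <- Inf
  } else {
    sinuosity <- L / ee
  }
  ds <- diff(lp$s)
  w <- c(ds[1] / 2, (ds[-1] + ds[-length(ds)]) / 2, ds[length(ds)] / 2)
  total_curvature <- sum(lp$curvature * w)
  total_torsion <- sum(abs(lp$torsion) * w)
  seg_t <- (p[-1, , drop = FALSE] - p[-n, , drop = FALSE]) / ds
  smid <- (lp$s[-1] + lp$s[-n]) / 2
  list(length = L, sinuosity = sinuosity,
       total_curvature = total_curvature, total_torsion = total_torsion,
       persistence_length = persistence_length(seg_t, smid))
}

# tangent-correlation persistence length; unit tangents at arc positions s
persistence_length <- function(tangent, s) {
  n <- nrow(tangent)
  if (n < 3) return(Inf)
  L <- s[n] - s[1]
  lags <- numeric(0)
  cors <- numeric(0)
  for (k in seq_len(n - 1L)) {
    i <- seq_len(n - k)
    dl <- mean(s[i + k] - s[i])
    if (dl > L / 2) break
    ck <- mean(rowSums(tangent[i, , drop = FALSE] *
                       tangent[i + k, , drop = FALSE]))
    lags <- c(lags, dl)
    cors <- c(cors, ck)
  }
  ok <- cors > 0
  if (sum(ok) < 2) return(NA_real_)
  x <- lags[ok]; y <- log(cors[ok])
  slope <- sum(x * y) / sum(x^2)
  if (!is.finite(slope) || slope >= 0) return(Inf)
  -1 / slope
}

#' Pooled persistence length of a set of curves
#'
#' Tangent-correlation persistence length estimated jointly over several
#' filaments: per-lag correlations are averaged across curves before the
#' log-linear fit. Pooling suppresses the heavy-tailed noise of per-curve
#' estimates, which for chains not much longer than the persistence length
#' can individually be off by several tens of percent.
#'
#' @param curves a list of [filament_curve()] objects.
#' @return The pooled persistence length in nm (`Inf` if the pooled
#'   correlation does not decay).
#' @export
pooled_persistence_length <- function(curves) {
  if (!length(curves)) return(NA_real_)
  lags <- numeric(0); cors <- numeric(0)
  for (curve in curves) {
    if (!inherits(curve, "filament_curve"))
      stop_param("pooled_persistence_length expects filament_curve objects")
    p <- curve$points * curve$voxel_size
    n <- nrow(p)
    if (n < 4) next
    seg <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    tang <- seg / len
    s <- cumsum(c(0, len))
    smid <- (s[-1] + s[-n]) / 2
    L <- smid[n - 1] - smid[1]
    for (k in seq_len(n - 2L)) {
      i <- seq_len(n - 1L - k)
      dl <- mean(smid[i + k] - smid[i])
      if (dl > L / 2) break
      lags <- c(lags, dl)
      cors <- c(cors, mean(rowSums(tang[i, , drop = FALSE] *
                                   tang[i + k, , drop = FALSE])))
    }
  }
  if (!length(lags)) return(NA_real_)
  agg <- tapply(cors, round(lags, 6), mean)
  x <- as.numeric(names(agg)); y <- as.numeric(agg)
  ok <- y > 0
  if (sum(ok) < 2) return(NA_real_)
  slope <- sum(x[ok] * log(y[ok])) / sum(x[ok]^2)
  if (!is.finite(slope) || slope >= 0) return(Inf)
  -1 / slope
}

#' All geometric properties of a curve
#'
#' Convenience wrapper returning both [local_properties()] and
#' [global_properties()].
#'
#' @param curve a [filament_curve()].
#' @return A list with components `local` and `global`.
#' @export
curve_properties <- function(curve) {
  list(local = local_properties(curve), global = global_properties(curve))
}
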