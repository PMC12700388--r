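# Spatially embedded graphs: epsilon-ball construction, minimum spanning
# forest, branch splitting into filament instances, and curve extraction.

#' Spatially embedded graph
#'
#' Nodes carry 3D coordinates (geometry, voxel units); undirected edges
#' carry their Euclidean length (topology). After [split_filaments()] each
#' node additionally carries the id of the filament instance it belongs to.
#'
#' @param nodes data frame with columns `id, x, y, z` and optionally
#'   `filament_id`.
#' @param edges data frame with columns `source, target, length`.
#' @param voxel_size nm per voxel.
#' @return An object of class `spatial_graph`.
#' @export
spatial_graph <- function(nodes, edges, voxel_size = 1) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (nrow(nodes) > 0 && !all(c("id", "x", "y", "z") %in% names(nodes)))
    stop_param("nodes need columns id, x, y, z")
  if (nrow(edges) > 0) {
    if (!all(c("source", "target") %in% names(edges)))
      stop_param("edges need columns source, target")
    if (any(edges$source == edges$target)) stop_param("self-loops not allowed")
    key <- paste(pmin(edges$source, edges$target),
                 pmax(edges$source, edges$target))
    if (anyDuplicated(key)) stop_param("duplicate edges not allowed")
    if (is.null(edges$length)) {
      si <- match(edges$source, nodes$id)
      ti <- match(edges$target, nodes$id)
      edges$length <- sqrt((nodes$x[si] - nodes$x[ti])^2 +
                           (nodes$y[si] - nodes$y[ti])^2 +
                           (nodes$z[si] - nodes$z[ti])^2)
    }
  } else {
    edges <- data.frame(source = integer(0), target = integer(0),
                        length = numeric(0))
  }
  if (nrow(nodes) == 0)
    nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                        z = numeric(0))
  structure(list(nodes = nodes, edges = edges, voxel_size = voxel_size),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d nodes, %d edges, voxel size %g nm\n",
              nrow(x$nodes), nrow(x$edges), x$voxel_size))
  invisible(x)
}

graph_components <- function(g) {
  n <- nrow(g$nodes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  si <- match(g$edges$source, g$nodes$id)
  ti <- match(g$edges$target, g$nodes$id)
  for (e in seq_along(si)) {
    a <- find(si[e]); b <- find(ti[e])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

is_acyclic <- function(g) {
  n <- nrow(g$nodes)
  if (n == 0) return(TRUE)
  ncomp <- length(unique(graph_components(g)))
  nrow(g$edges) == n - ncomp
}

#' Build a spatially embedded graph from a skeleton point cloud
#'
#' One node per point; an edge for every unordered pair of points at
#' Euclidean distance strictly below `epsilon` (the epsilon-ball
#' criterion), weighted by that distance. Neighbor search uses a uniform
#' spatial hash, so construction is O(n log n) expected. Coincident points
#' are merged into a single node first, since zero-length edges would break
#' downstream angle computations.
#'
#' @param cloud a [skeleton_cloud()] (or an `n x 3` coordinate matrix).
#' @param epsilon neighborhood radius in voxels (> 0).
#' @return A [spatial_graph()].
#' @export
build_graph <- function(cloud, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop_param("epsilon must be a single positive number")
  voxel_size <- 1
  if (inherits(cloud, "skeleton_cloud")) {
    voxel_size <- cloud$voxel_size
    p <- cloud$points
  } else {
    p <- as.matrix(cloud)
  }
  if (nrow(p) == 0)
    return(spatial_graph(NULL, NULL, voxel_size))
  key <- paste(signif(p[, 1], 12), signif(p[, 2], 12), signif(p[, 3], 12))
  keep <- !duplicated(key)
  p <- p[keep, , drop = FALSE]
  n <- nrow(p)
  pr <- radius_pairs_cpp(p, epsilon)
  nodes <- data.frame(id = seq_len(n), x = p[, 1], y = p[, 2], z = p[, 3])
  edges <- data.frame(source = pr$i, target = pr$j, length = pr$dist)
  spatial_graph(nodes, edges, voxel_size)
}

#' Minimum spanning forest of a spatial graph
#'
#' Removes cycles by keeping, per connected component, the spanning tree of
#' minimum total edge length (Kruskal's algorithm). Since edges are
#' weighted by Euclidean length the result is essentially unique; exact
#' weight ties are broken deterministically by (weight, smaller node id,
#' larger node id).
#'
#' @param g a [spatial_graph()].
#' @return A [spatial_graph()] with the same nodes and an acyclic edge set
#'   of minimal total weight.
#' @export
spanning_forest <- function(g) {
  if (!inherits(g, "spatial_graph")) stop_param("expected a spatial_graph")
  m <- nrow(g$edges)
  if (m == 0) return(g)
  e <- g$edges
  lo <- pmin(e$source, e$target)
  hi <- pmax(e$source, e$target)
  ord <- order(e$length, lo, hi)
  n <- nrow(g$nodes)
  idmap <- match(e$source, g$nodes$id)
  idmap2 <- match(e$target, g$nodes$id)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(m)
  for (k in ord) {
    a <- find(idmap[k]); b <- find(idmap2[k])
    if (a != b) {
      parent[a] <- b
      keep[k] <- TRUE
    }
  }
  spatial_graph(g$nodes, e[keep, , drop = FALSE], g$voxel_size)
}

#' Split branch nodes into filament instances
#'
#' For every node of degree m > 2 (in ascending node-id order) the angle at
#' the node is computed for each pair of incident edges; the pair forming
#' the largest angle — the straightest continuation — is preserved, and
#' each of the remaining m - 2 edges is re-attached to a fresh duplicate
#' node at the same coordinates. The result has maximum degree 2, the edge
#' count is conserved, and every connected component is a simple path
#' (a filament instance). Equal maximal angles are resolved
#' deterministically: the pair whose edges come first in ascending
#' edge-index order wins.
#'
#' @param g an acyclic [spatial_graph()] (see [spanning_forest()]).
#' @return A [spatial_graph()] with `filament_id` assigned per node.
#' @export
split_filaments <- function(g) {
  if (!inherits(g, "spatial_graph")) stop_param("expected a spatial_graph")
  if (!is_acyclic(g)) stop_param("split_filaments requires an acyclic graph")
  nodes <- g$nodes
  n0 <- nrow(nodes)
  xs <- nodes$x; ys <- nodes$y; zs <- nodes$z
  ids <- nodes$id
  esrc <- match(g$edges$source, ids)
  edst <- match(g$edges$target, ids)
  elen <- g$edges$length
  m <- length(esrc)
  # incidence lists by internal row index
  inc <- vector("list", n0)
  for (e in seq_len(m)) {
    inc[[esrc[e]]] <- c(inc[[esrc[e]]], e)
    inc[[edst[e]]] <- c(inc[[edst[e]]], e)
  }
  next_id <- if (n0 > 0) max(ids) else 0L
  ord_nodes <- order(ids)
  for (i in ord_nodes) {
    eidx <- inc[[i]]
    deg <- length(eidx)
    if (deg <= 2L) next
    eidx <- sort(eidx)
    other <- ifelse(esrc[eidx] == i, edst[eidx], esrc[eidx])
    vx <- xs[other] - xs[i]; vy <- ys[other] - ys[i]; vz <- zs[other] - zs[i]
    nv <- sqrt(vx^2 + vy^2 + vz^2)
    best <- c(NA_integer_, NA_integer_)
    amax <- 0
    for (j in seq_len(deg - 1L)) {
      for (k in seq.int(j + 1L, deg)) {
        cosv <- (vx[j] * vx[k] + vy[j] * vy[k] + vz[j] * vz[k]) /
          (nv[j] * nv[k])
        ang <- acos(pmin(1, pmax(-1, cosv)))
        if (ang > amax) {
          amax <- ang
          best <- c(j, k)
        }
      }
    }
    drop_local <- setdiff(seq_len(deg), best)
    for (j in drop_local) {
      e <- eidx[j]
      next_id <- next_id + 1L
      xs <- c(xs, xs[i]); ys <- c(ys, ys[i]); zs <- c(zs, zs[i])
      ids <- c(ids, next_id)
      dup_row <- length(ids)
      inc[[dup_row]] <- e
      # re-attach edge e: endpoint i -> duplicate
      if (esrc[e] == i) esrc[e] <- dup_row else edst[e] <- dup_row
    }
    inc[[i]] <- eidx[best]
  }
  nodes_out <- data.frame(id = ids, x = xs, y = ys, z = zs)
  edges_out <- data.frame(source = ids[esrc], target = ids[edst],
                          length = elen)
  out <- spatial_graph(nodes_out, edges_out, g$voxel_size)
  out$nodes$filament_id <- graph_components(out)
  out
}

#' Extract ordered curves from a filament graph
#'
#' Every connected component of a max-degree-2 acyclic graph is a simple
#' path; each path with at least 2 nodes becomes a [filament_curve()],
#' ordered starting from the endpoint with lexicographically smallest
#' coordinates. Curves shorter than `min_length` (geodesic length in nm)
#' and singleton nodes are discarded.
#'
#' @param g a [spatial_graph()] with maximum degree 2 (see
#'   [split_filaments()]).
#' @param min_length minimum geodesic curve length in nm.
#' @return A list of [filament_curve()] objects.
#' @export
extract_curves <- function(g, min_length = 0) {
  if (!inherits(g, "spatial_graph")) stop_param("expected a spatial_graph")
  n <- nrow(g$nodes)
  if (n == 0) return(list())
  ids <- g$nodes$id
  esrc <- match(g$edges$source, ids)
  edst <- match(g$edges$target, ids)
  deg <- tabulate(c(esrc, edst), nbins = n)
  if (any(deg > 2L)) stop_param("extract_curves requires maximum degree 2")
  adj <- vector("list", n)
  for (e in seq_along(esrc)) {
    adj[[esrc[e]]] <- c(adj[[esrc[e]]], edst[e])
    adj[[edst[e]]] <- c(adj[[edst[e]]], esrc[e])
  }
  comp <- graph_components(g)
  if (nrow(g$edges) != n - length(unique(comp)))
    stop_param("extract_curves requires an acyclic graph")
  pts <- cbind(g$nodes$x, g$nodes$y, g$nodes$z)
  curves <- list()
  for (ci in unique(comp)) {
    members <- which(comp == ci)
    if (length(members) < 2L) next
    ends <- members[deg[members] == 1L]
    # choose lexicographically smallest endpoint as start
    ep <- pts[ends, , drop = FALSE]
    ordend <- order(ep[, 1], ep[, 2], ep[, 3])
    start <- ends[ordend[1]]
    path <- integer(length(members))
    path[1] <- start
    prev <- 0L
    cur <- start
    for (step in seq.int(2L, length(members))) {
      nxt <- setdiff(adj[[cur]], prev)
      path[step] <- nxt
      prev <- cur
      cur <- nxt
    }
    cpts <- pts[path, , drop = FALSE]
    glen <- sum(sqrt(rowSums((cpts[-1, , drop = FALSE] -
                              cpts[-nrow(cpts), , drop = FALSE])^2))) *
      g$voxel_size
    if (glen < min_length) next
    curves[[length(curves) + 1L]] <- filament_curve(cpts, g$voxel_size)
  }
  curves
}
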