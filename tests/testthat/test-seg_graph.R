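test_that("epsilon-ball graph construction uses strict distances", {
  # three collinear points, eps = 1.5: no edge between the outer pair
  g <- build_graph(cbind(0:2, 0, 0), 1.5)
  expect_equal(nrow(g$edges), 2)
  # unit-square corners, eps = 1.6: 4 sides + 2 diagonals
  sq <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0)
  g2 <- build_graph(sq, 1.6)
  expect_equal(nrow(g2$edges), 6)
  expect_equal(sort(g2$edges$length), c(1, 1, 1, 1, sqrt(2), sqrt(2)))
  # two points at exactly eps: strict inequality, no edge
  g3 <- build_graph(cbind(c(0, 2), 0, 0), 2)
  expect_equal(nrow(g3$edges), 0)
  # coincident points are merged
  g4 <- build_graph(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), 1.5)
  expect_equal(nrow(g4$nodes), 2)
  expect_equal(nrow(build_graph(matrix(numeric(0), 0, 3), 1)$nodes), 0)
})

test_that("spanning forest is minimal, idempotent and component-preserving", {
  sq <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0)
  f <- spanning_forest(build_graph(sq, 1.6))
  expect_equal(sum(f$edges$length), 3)         # three unit sides survive
  expect_equal(nrow(f$edges), 3)

  # a tree comes back unchanged
  tree <- spatial_graph(data.frame(id = 1:4, x = c(0, 1, 2, 3), y = 0, z = 0),
                        data.frame(source = 1:3, target = 2:4))
  ft <- spanning_forest(tree)
  expect_equal(ft$edges[order(ft$edges$source), ],
               tree$edges[order(tree$edges$source), ],
               ignore_attr = TRUE)

  # two disjoint triangles: 2 components, 2 edges kept per triangle
  tri2 <- rbind(cbind(c(0, 1, 0.5), c(0, 0, 1), 0),
                cbind(c(10, 11, 10.5), c(0, 0, 1), 0))
  f2 <- spanning_forest(build_graph(tri2, 2))
  expect_equal(nrow(f2$edges), 4)
})

test_that("spanning forest matches exhaustive enumeration on random graphs", {
  for (seed in 1:100) {
    g <- random_small_graph(seed)
    f <- spanning_forest(g)
    expect_true(skeletrace:::is_acyclic(f))
    w_brute <- brute_msf_weight(nrow(g$nodes), g$edges)
    expect_equal(sum(f$edges$length), w_brute, tolerance = 1e-12)
    if (seed <= 20 && requireNamespace("igraph", quietly = TRUE)) {
      ig <- igraph::graph_from_data_frame(
        cbind(g$edges[, c("source", "target")], weight = g$edges$length),
        directed = FALSE, vertices = data.frame(name = g$nodes$id))
      mst <- igraph::mst(ig)
      expect_equal(sum(f$edges$length), sum(igraph::E(mst)$weight),
                   tolerance = 1e-12)
    }
  }
})

test_that("branch splitting keeps the straightest pair and conserves edges", {
  # Y-junction: the two collinear edges survive, the third moves to a
  # duplicate node
  y <- spatial_graph(
    data.frame(id = 1:4, x = c(0, 1, -1, 0), y = c(0, 0, 0, 1), z = 0),
    data.frame(source = c(1, 1, 1), target = c(2, 3, 4)))
  s <- split_filaments(y)
  expect_equal(nrow(s$nodes), 5)               # one duplicate created
  expect_equal(nrow(s$edges), 3)               # edge count conserved
  deg <- tabulate(c(match(s$edges$source, s$nodes$id),
                    match(s$edges$target, s$nodes$id)), nrow(s$nodes))
  expect_lte(max(deg), 2)
  comp <- sort(table(s$nodes$filament_id))
  expect_equal(as.integer(comp), c(2L, 3L))    # a 2-path and a 3-path
  # the duplicate sits at the branch-node coordinates
  dup <- s$nodes[5, ]
  expect_equal(c(dup$x, dup$y, dup$z), c(0, 0, 0))

  # X-junction: 180-degree tie between (+x,-x) and (+y,-y); the pair first
  # in edge-index order wins
  x <- spatial_graph(
    data.frame(id = 1:5, x = c(0, 1, -1, 0, 0), y = c(0, 0, 0, 1, -1), z = 0),
    data.frame(source = rep(1, 4), target = 2:5))
  sx <- split_filaments(x)
  expect_equal(nrow(sx$nodes), 7)              # 2 duplicates
  expect_equal(nrow(sx$edges), 4)
  expect_equal(length(unique(sx$nodes$filament_id)), 3)
  kept <- sx$edges[sx$edges$source == 1 | sx$edges$target == 1, ]
  expect_setequal(setdiff(c(kept$source, kept$target), 1), c(2, 3))

  # simple path untouched; cyclic input rejected
  p <- spatial_graph(data.frame(id = 1:3, x = 0:2, y = 0, z = 0),
                     data.frame(source = 1:2, target = 2:3))
  expect_equal(nrow(split_filaments(p)$nodes), 3)
  cyc <- spatial_graph(data.frame(id = 1:3, x = c(0, 1, 0), y = c(0, 0, 1), z = 0),
                       data.frame(source = c(1, 2, 3), target = c(2, 3, 1)))
  expect_error(split_filaments(cyc), class = "skeletrace_param_error")
})

test_that("splitting invariants hold on random forests", {
  for (seed in 1:25) {
    g <- spanning_forest(random_small_graph(seed, max_nodes = 8))
    deg_in <- tabulate(c(match(g$edges$source, g$nodes$id),
                         match(g$edges$target, g$nodes$id)), nrow(g$nodes))
    extra <- sum(pmax(deg_in - 2, 0))
    s <- split_filaments(g)
    expect_equal(nrow(s$edges), nrow(g$edges))           # |E| conserved
    expect_equal(nrow(s$nodes), nrow(g$nodes) + extra)   # sum(m - 2) duplicates
    deg_out <- tabulate(c(match(s$edges$source, s$nodes$id),
                          match(s$edges$target, s$nodes$id)), nrow(s$nodes))
    expect_lte(max(deg_out, 0), 2)
    ncomp_in <- length(unique(skeletrace:::graph_components(g)))
    ncomp_out <- length(unique(skeletrace:::graph_components(s)))
    expect_equal(ncomp_out, ncomp_in + extra)
  }
})

test_that("curves come out ordered, filtered by geodesic length", {
  p5 <- spatial_graph(data.frame(id = 1:5, x = c(4, 3, 2, 1, 0), y = 0, z = 0),
                      data.frame(source = 1:4, target = 2:5))
  cv <- extract_curves(p5)
  expect_length(cv, 1)
  expect_equal(cv[[1]]$points[1, ], c(x = 0, y = 0, z = 0))  # lexicographic start
  expect_equal(nrow(cv[[1]]$points), 5)

  # 85 nm threshold: an 84 nm curve is removed, an 86 nm one retained
  mk_path <- function(len) {
    n <- len + 1
    spatial_graph(data.frame(id = 1:n, x = 0:len, y = 0, z = 0),
                  data.frame(source = 1:(n - 1), target = 2:n))
  }
  expect_length(extract_curves(mk_path(84), min_length = 85), 0)
  expect_length(extract_curves(mk_path(86), min_length = 85), 1)

  # Y-junction after splitting: one 3-point and one 2-point curve
  y <- spatial_graph(
    data.frame(id = 1:4, x = c(0, 1, -1, 0), y = c(0, 0, 0, 1), z = 0),
    data.frame(source = c(1, 1, 1), target = c(2, 3, 4)))
  cv2 <- extract_curves(split_filaments(y))
  expect_setequal(vapply(cv2, function(c) nrow(c$points), integer(1)), c(3L, 2L))

  bad <- spatial_graph(
    data.frame(id = 1:4, x = c(0, 1, -1, 0), y = c(0, 0, 0, 1), z = 0),
    data.frame(source = c(1, 1, 1), target = c(2, 3, 4)))
  expect_error(extract_curves(bad), class = "skeletrace_param_error")
})

test_that("disjoint tubes are traced into exactly k accurate curves", {
  fp <- filament_phantom(c(80, 80, 80), kind = "straight", n_filaments = 2,
                         seed = 2)
  sk <- skeletonize(fp$seg, d = 1)
  cv <- extract_curves(split_filaments(spanning_forest(build_graph(sk, 2.2))),
                       min_length = 25)
  expect_length(cv, 2)
  gt_curves <- extract_curves(fp$truth$gt_graph)
  gt_ext <- do.call(rbind, lapply(gt_curves, function(c)
    extend_centerline(c$points, 4)))
  for (curve in cv)
    expect_lt(hausdorff_to(curve$points, gt_ext), 1.5)
})
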