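test_that("a thick horizontal band thins to its middle row", {
  mask <- band_mask(60, 200, y0 = 30, radius = 4)  # 9 rows: 26..34
  skel <- skeletonize(mask)
  pos <- which(skel, arr.ind = TRUE)
  # away from the ends the skeleton is the single central row
  core <- pos[pos[, 2] > 10 & pos[, 2] < 190, , drop = FALSE]
  expect_true(all(core[, 1] == 30))
  expect_true(all(table(core[, 2]) == 1))
})

test_that("a plus-sign mask keeps exactly one crossing node", {
  mask <- matrix(FALSE, 101, 101)
  mask[abs(seq_len(101) - 51) <= 3, ] <- TRUE
  mask[, abs(seq_len(101) - 51) <= 3] <- mask[, abs(seq_len(101) - 51) <= 3] |
    matrix(TRUE, 101, sum(abs(seq_len(101) - 51) <= 3))
  mask <- matrix(FALSE, 101, 101)
  mask[48:54, ] <- TRUE
  mask[, 48:54] <- TRUE
  skel <- skeletonize(mask)
  cn <- crossing_number(skel)
  expect_equal(sum(cn >= 3 & skel), 1)
  expect_equal(which(cn >= 3 & skel, arr.ind = TRUE)[1, ], c(row = 51, col = 51),
               ignore_attr = TRUE)
})

test_that("thinning preserves the Euler number of random blobs", {
  set.seed(5)
  for (k in 1:4) {
    m <- matrix(FALSE, 64, 64)
    # random unions of disks, possibly with holes
    for (j in 1:6) {
      cx <- runif(1, 10, 54); cy <- runif(1, 10, 54); r <- runif(1, 3, 9)
      m <- m | (radial_dist(64, 64, cx, cy) <= r)
    }
    ring <- radial_dist(64, 64, 32, 32)
    m <- m | (ring <= 20 & ring >= 15)
    skel <- skeletonize(m, prune = 0)
    expect_equal(euler_number(skel), euler_number(m))
  }
})

test_that("a straight vessel yields 2 endpoints, 1 segment, 0 bifurcations", {
  seg <- straight_segment(20, 40, 160, 40, radius = 4)
  mask <- rasterize_segments(list(seg), c(80, 180))
  g <- build_graph(skeletonize(mask), mask)
  expect_length(g$segments, 1)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2)
  expect_equal(sum(g$nodes$degree >= 3), 0)
})

test_that("a Y-mask yields 3 endpoints, 1 bifurcation, 3 segments", {
  mask <- y_mask(30)
  g <- build_graph(skeletonize(mask), mask)
  expect_length(g$segments, 3)
  expect_equal(sum(g$nodes$kind == "bifurcation"), 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 3)
})

test_that("per-point radii on an ideal band are within half a pixel", {
  mask <- band_mask(60, 240, y0 = 30.5, radius = 4)  # 8-row band
  g <- build_graph(skeletonize(mask), mask)
  s <- g$segments[[which.max(vapply(g$segments, function(s)
    nrow(s$points), numeric(1)))]]
  interior <- s$points[, 1] > 15 & s$points[, 1] < 225
  expect_true(all(abs(s$radius[interior] - 4) <= 0.5))
})

test_that("the empty skeleton gives an empty graph, not an error", {
  g <- build_graph(matrix(FALSE, 32, 32), matrix(FALSE, 32, 32))
  expect_length(g$segments, 0)
  expect_equal(nrow(g$nodes), 0)
})

test_that("graph is a consistent multigraph and round-trips the mask", {
  sc <- small_scene(1)
  mask <- sc$truth$vessel_mask
  g <- build_graph(skeletonize(mask), mask,
                   labels = list(artery_mask = sc$truth$artery_mask,
                                 vein_mask = sc$truth$vein_mask))
  # handshake: total degree equals twice the segment count
  expect_equal(sum(g$nodes$degree), 2 * length(g$segments))
  # every incident node id exists
  for (s in g$segments) expect_true(all(s$nodes %in% g$nodes$id))
  # segment endpoints coincide with node positions
  for (s in g$segments) {
    n1 <- g$nodes[g$nodes$id == s$nodes[1], ]
    expect_lt(sqrt((s$points[1, 1] - n1$x)^2 + (s$points[1, 2] - n1$y)^2),
              1e-9)
  }
  # mask -> graph -> mask recovery
  m2 <- stamp_graph(g, dim(mask))
  expect_gte(sum(m2 & mask) / sum(mask), 0.95)
})

test_that("graphs round-trip losslessly through JSON", {
  mask <- y_mask(35)
  g <- build_graph(skeletonize(mask), mask)
  g2 <- graph_from_json(graph_to_json(g))
  expect_equal(nrow(g2$nodes), nrow(g$nodes))
  expect_length(g2$segments, length(g$segments))
  for (k in seq_along(g$segments)) {
    expect_equal(unname(g2$segments[[k]]$points),
                 unname(g$segments[[k]]$points))
    expect_equal(g2$segments[[k]]$radius, g$segments[[k]]$radius)
    expect_equal(g2$segments[[k]]$nodes, g$segments[[k]]$nodes)
  }
})
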