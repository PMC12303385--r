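test_that("skeletonization of simple shapes matches known medial axes", {
  # 100 x 5 bar: 1-px centerline, interior widths exactly 5
  mask <- matrix(FALSE, 30, 120)
  mask[13:17, 11:110] <- TRUE
  sk <- skeletonize_mask(mask)
  expect_true(all(sk$skeleton[mask == FALSE] == FALSE))  # skeleton in mask
  nd <- detect_skeleton_nodes(sk)
  expect_identical(nrow(nd$endpoints), 2L)
  expect_identical(nrow(nd$branchpoints), 0L)
  interior <- sk$width[15, 20:100]
  expect_true(all(interior == 5, na.rm = TRUE))

  # solid disk: skeleton collapses to the center, width about the diameter
  mk <- matrix(FALSE, 41, 41)
  mk[(row(mk) - 21)^2 + (col(mk) - 21)^2 <= 15^2] <- TRUE
  skd <- skeletonize_mask(mk)
  expect_lt(sum(skd$skeleton), 8)
  expect_equal(max(skd$width, na.rm = TRUE), 30, tolerance = 0.05)

  expect_error(skeletonize_mask(matrix(FALSE, 5, 5)), "empty")
})

test_that("node detection finds endpoints and merged branch clusters", {
  # straight line: 2 endpoints, no branch points
  ml <- matrix(FALSE, 5, 104)
  ml[3, 3:102] <- TRUE
  nd <- detect_skeleton_nodes(skeletonize_mask(ml))
  expect_identical(nrow(nd$endpoints), 2L)
  expect_identical(nrow(nd$branchpoints), 0L)

  # Y-shape: 3 endpoints, 1 branch point
  yg <- venation_graph(
    nodes = data.frame(x = c(0, 40, -40, 0), y = c(0, 30, 30, -45), area = NA),
    edges = data.frame(tail = c(1, 1, 1), head = c(2, 3, 4),
                       length = c(50, 50, 45), width = 5),
    source = 1, validate = FALSE
  )
  ndy <- detect_skeleton_nodes(skeletonize_mask(render_mask(yg, 1)))
  expect_identical(nrow(ndy$endpoints), 3L)
  expect_identical(nrow(ndy$branchpoints), 1L)

  # X-shape: 4 endpoints, one merged branch cluster
  mx <- matrix(FALSE, 61, 61)
  for (t in seq(0, 1, length.out = 200)) {
    r <- round(1 + t * 59)
    mx[r, r] <- TRUE
    mx[r, 62 - r] <- TRUE
  }
  ndx <- detect_skeleton_nodes(skeletonize_mask(mx))
  expect_identical(nrow(ndx$endpoints), 4L)
  expect_identical(nrow(ndx$branchpoints), 1L)
})

test_that("tracing a Y recovers three edges with correct lengths and widths", {
  yg <- venation_graph(
    nodes = data.frame(x = c(0, 40, -40, 0), y = c(0, 30, 30, -45), area = NA),
    edges = data.frame(tail = c(1, 1, 1), head = c(2, 3, 4),
                       length = c(50, 50, 45), width = 5),
    source = 1, validate = FALSE
  )
  g <- extract_venation(render_mask(yg, 1))
  expect_identical(n_nodes(g), 4L)
  expect_identical(n_edges(g), 3L)
  expect_true(all(abs(edge_widths(g) - 5) / 5 < 0.15))
  expect_true(all(abs(sort(edge_lengths(g)) - sort(c(45, 50, 50))) < 8))

  # straight 100-px 1-px line traces to one edge of length about 100
  ml <- matrix(FALSE, 5, 104)
  ml[3, 3:102] <- TRUE
  gl <- trace_graph(skeletonize_mask(ml))
  expect_identical(n_edges(gl), 1L)
  expect_gte(edge_lengths(gl), 99)
  expect_lte(edge_lengths(gl), 101)
})

test_that("pruning merges, removes degree-2 nodes, and is idempotent", {
  # chain a-b-c with b of degree 2: lengths (2,3), widths (4,1)
  # concatenates to length 5, length-weighted width 2.2
  gch <- venation_graph(
    nodes = data.frame(x = c(0, 2, 5), y = 0, area = NA),
    edges = data.frame(tail = c(1, 2), head = c(2, 3), length = c(2, 3),
                       width = c(4, 1)),
    source = 1
  )
  gp <- prune_graph(gch, merge_radius = 0, merge_width_factor = 0)
  expect_identical(n_edges(gp), 1L)
  expect_equal(edge_lengths(gp), 5)
  expect_equal(edge_widths(gp), 2.2)

  # two nodes 0.5 px apart with merge radius 2 collapse to one
  gm <- venation_graph(
    nodes = data.frame(x = c(0, 10, 10.5), y = 0, area = NA),
    edges = data.frame(tail = c(1, 2), head = c(2, 3), length = c(10, 0.5),
                       width = 1),
    source = 1
  )
  gmp <- prune_graph(gm, merge_radius = 2, merge_width_factor = 0)
  expect_identical(n_nodes(gmp), 2L)
  expect_identical(n_edges(gmp), 1L)

  # idempotence on a messy traced graph
  sh <- leaf_shape(length = 4, width = 2, spacing = 0.5, jitter = 0.15,
                   width0 = 0.1, perturb = 0, seed = 2)
  gt <- trace_graph(skeletonize_mask(render_mask(generate_leaf_lattice(sh), 50)))
  p1 <- prune_graph(gt)
  p2 <- prune_graph(p1)
  expect_identical(n_nodes(p2), n_nodes(p1))
  expect_identical(n_edges(p2), n_edges(p1))
  expect_equal(p2$edges$length, p1$edges$length)
})

test_that("render-extract round trip recovers the exact topology", {
  for (seed in c(0, 2)) {
    sh <- leaf_shape(length = 8, width = 4, spacing = 1, jitter = 0.15,
                     width0 = 0.16, perturb = 0, seed = seed)
    g <- generate_leaf_lattice(sh)
    m <- render_mask(g, 50)
    ge <- extract_venation(m)
    expect_identical(n_nodes(ge), n_nodes(g))
    expect_identical(n_edges(ge), n_edges(g))
    expect_identical(cycle_rank(ge), cycle_rank(g))
    # every stroke had the same width, so all extracted widths must sit
    # within 15% of it
    expect_true(all(abs(edge_widths(ge) - 8) / 8 < 0.15))
  }
})

test_that("the petiole argument selects the source node", {
  sh <- leaf_shape(length = 8, width = 4, spacing = 1, jitter = 0.15,
                   width0 = 0.16, perturb = 0, seed = 0)
  g <- generate_leaf_lattice(sh)
  m <- render_mask(g, 50)
  org <- attr(m, "origin")
  pet_px <- c((g$nodes$x[g$source] - org[1]) * 50,
              (g$nodes$y[g$source] - org[2]) * 50)
  ge <- extract_venation(m, petiole = pet_px)
  d <- sqrt((ge$nodes$x[ge$source] - pet_px[1])^2 +
              (ge$nodes$y[ge$source] - pet_px[2])^2)
  expect_lt(d, 10)
})

test_that("clipped Voronoi areas partition the boundary", {
  # 4 nodes at quadrant centers of the unit square: each cell area 1/4
  g4 <- venation_graph(
    nodes = data.frame(x = c(0.25, 0.75, 0.25, 0.75),
                       y = c(0.25, 0.25, 0.75, 0.75), area = NA),
    edges = data.frame(tail = c(1, 2, 3), head = c(2, 4, 4),
                       length = 1, width = 1),
    source = 1, validate = FALSE
  )
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  g4 <- drainage_areas(g4, boundary = sq)
  expect_equal(node_areas(g4), rep(0.25, 4), tolerance = 1e-6)

  # any configuration: areas sum to the polygon area
  g <- generate_leaf_lattice(leaf_shape(length = 1.6, width = 0.9,
                                        spacing = 0.1, seed = 5))
  bnd <- leaf_boundary(leaf_shape(length = 1.6, width = 0.9))
  expect_equal(sum(node_areas(g)),
               abs(venanet:::polygon_area_signed(bnd[, 1], bnd[, 2])),
               tolerance = 1e-6)
})

test_that("Voronoi areas agree with a Monte-Carlo nearest-node oracle", {
  res <- with_seed(42, {
    th <- runif(300, 0, 2 * pi)
    r <- sqrt(runif(300))
    x <- 2 * r * cos(th)
    y <- r * sin(th)
    keep <- !duplicated(cbind(x, y))
    x <- x[keep][1:50]
    y <- y[keep][1:50]
    g <- venation_graph(
      nodes = data.frame(x = x, y = y, area = NA),
      edges = data.frame(tail = 1:49, head = 2:50, length = 1, width = 1),
      source = 1, validate = FALSE
    )
    th_b <- seq(0, 2 * pi, length.out = 257)[-257]
    bnd <- cbind(2 * cos(th_b), sin(th_b))
    g <- drainage_areas(g, boundary = bnd)
    # MC oracle: uniform points in the polygon, assigned to nearest node
    counts <- numeric(50)
    n_in <- 0
    W <- spatstat.geom::owin(poly = list(x = bnd[, 1], y = bnd[, 2]))
    for (chunk in 1:100) {
      px <- runif(1e5, -2, 2)
      py <- runif(1e5, -1, 1)
      ok <- spatstat.geom::inside.owin(px, py, W)
      px <- px[ok]
      py <- py[ok]
      nn <- max.col(-outer(px, x, "-")^2 - outer(py, y, "-")^2)
      counts <- counts + tabulate(nn, 50)
      n_in <- n_in + length(px)
    }
    poly_area <- abs(venanet:::polygon_area_signed(bnd[, 1], bnd[, 2]))
    list(a = node_areas(g), amc = counts / n_in * poly_area)
  })
  expect_lt(max(abs(res$a - res$amc) / res$amc), 0.01)
})

test_that("automatic alpha shapes hug the node cloud", {
  g <- generate_leaf_lattice(leaf_shape(seed = 0))
  poly <- alpha_shape(cbind(g$nodes$x, g$nodes$y))
  a_alpha <- abs(venanet:::polygon_area_signed(poly[, 1], poly[, 2]))
  hull <- venanet:::convex_boundary(g$nodes$x, g$nodes$y)
  a_hull <- abs(venanet:::polygon_area_signed(hull[, 1], hull[, 2]))
  expect_lte(a_alpha, a_hull * (1 + 1e-9))
  expect_gt(a_alpha, 0.5 * a_hull)
  ga <- drainage_areas(g, boundary = "alpha")
  expect_equal(sum(node_areas(ga)), a_alpha, tolerance = 1e-6)
})

test_that("degenerate geometry is rejected", {
  gc <- venation_graph(
    nodes = data.frame(x = c(0, 1), y = c(0, 0), area = NA),
    edges = data.frame(tail = 1, head = 2, length = 1, width = 1),
    source = 1
  )
  expect_error(drainage_areas(gc), "3 nodes")
})
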