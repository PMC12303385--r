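test_that("graph validation reports the violated invariants", {
  g <- two_node_graph()
  expect_true(validate_graph(g)$valid)

  bad_len <- g
  bad_len$edges$length <- 0
  rep <- validate_graph(bad_len)
  expect_false(rep$valid)
  expect_match(rep$violations, "non-positive length", all = FALSE)

  # positive-width subgraph disconnected
  g3 <- venation_graph(
    nodes = data.frame(x = c(0, 1, 2), y = 0, area = 1),
    edges = data.frame(tail = c(1, 2), head = c(2, 3), length = 1,
                       width = c(1, 0)),
    source = 1, validate = FALSE
  )
  expect_match(validate_graph(g3)$violations, "disconnected", all = FALSE)

  loop <- g
  loop$edges$head <- 1L
  expect_match(validate_graph(loop)$violations, "self-loop", all = FALSE)

  bad_src <- g
  bad_src$source <- 5L
  expect_match(validate_graph(bad_src)$violations, "source", all = FALSE)

  expect_error(venation_graph(data.frame(x = 0:1, y = 0),
                              data.frame(tail = 1, head = 2,
                                         length = -1, width = 1)),
               "non-positive length")
})

test_that("incidence matrix has the tail-positive convention and rank n-1", {
  g <- two_node_graph()
  B <- incidence_matrix(g)
  expect_equal(dim(B), c(2L, 1L))
  expect_equal(as.vector(B), c(1, -1))

  # triangle: rank of B C B^T is n_n - 1
  tri <- venation_graph(
    nodes = data.frame(x = c(0, 1, 0.5), y = c(0, 0, 1), area = 1),
    edges = data.frame(tail = c(1, 2, 3), head = c(2, 3, 1),
                       length = 1, width = 1),
    source = 1
  )
  Bt <- as.matrix(incidence_matrix(tri))
  A <- Bt %*% t(Bt)  # unit conductances
  expect_equal(qr(A)$rank, 2L)

  # column sums vanish, for a path too
  p4 <- path_graph(4)
  expect_equal(max(abs(Matrix::colSums(incidence_matrix(p4)))), 0)
})

test_that("Laplacian rank is n-1 for random small connected graphs", {
  for (seed in 1:5) {
    n <- 5 + seed * 3
    g <- with_seed(seed, {
      extra <- cbind(sample(n, n, TRUE), sample(n, n, TRUE))
      extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
      venation_graph(
        nodes = data.frame(x = runif(n), y = runif(n), area = 1),
        edges = unique(data.frame(
          tail = c(seq_len(n - 1), extra[, 1]),
          head = c(2:n, extra[, 2]), length = 1, width = 1
        )),
        source = 1
      )
    })
    B <- as.matrix(incidence_matrix(g))
    expect_equal(qr(B %*% t(B), tol = 1e-10)$rank, n_nodes(g) - 1L)
  }
})

test_that("file round trips preserve the graph in all three formats", {
  g <- with_seed(7, {
    n <- 10
    venation_graph(
      nodes = data.frame(x = runif(n), y = runif(n), area = runif(n)),
      edges = data.frame(tail = seq_len(n - 1), head = 2:n,
                         length = runif(n - 1, 0.5, 2),
                         width = runif(n - 1, 0.1, 3)),
      source = 3,
      node_ids = paste0("n", sample(100, n))
    )
  })
  for (fmt in c("csv", "json", "graphml")) {
    path <- file.path(tempdir(), paste0("rt_", fmt,
                                        switch(fmt, csv = "", json = ".json",
                                               graphml = ".graphml")))
    write_venation(g, path, format = fmt)
    g2 <- read_venation(path, format = fmt)
    expect_equal(g2$nodes, g$nodes, tolerance = 1e-12)
    expect_equal(g2$edges[c("tail", "head")], g$edges[c("tail", "head")])
    expect_equal(g2$edges$length, g$edges$length, tolerance = 1e-12)
    expect_equal(g2$edges$width, g$edges$width, tolerance = 1e-12)
    expect_equal(g2$source, g$source)
    expect_equal(g2$node_ids, g$node_ids)
  }
})

test_that("malformed files give informative errors", {
  d <- file.path(tempdir(), "badcsv")
  dir.create(d, showWarnings = FALSE)
  utils::write.csv(data.frame(id = 1:2, x = 0:1, y = 0,
                              is_source = c(TRUE, FALSE)),
                   file.path(d, "nodes.csv"), row.names = FALSE)
  # edges.csv missing the width column
  utils::write.csv(data.frame(id = 1, tail = 1, head = 2, length = 1),
                   file.path(d, "edges.csv"), row.names = FALSE)
  expect_error(read_venation(d), "width")

  jf <- file.path(tempdir(), "dupnode.json")
  writeLines(jsonlite::toJSON(list(
    nodes = data.frame(id = c("a", "a"), x = 0:1, y = 0),
    edges = data.frame(id = "e1", tail = "a", head = "a",
                       length = 1, width = 1),
    source = "a"
  ), auto_unbox = TRUE), jf)
  expect_error(read_venation(jf), "duplicate node id")

  expect_error(read_venation(tempfile(fileext = ".xyz")), "format")
})

test_that("cycle rank counts independent loops of edge subsets", {
  d <- diamond_graph()
  expect_equal(cycle_rank(d), 1L)
  expect_equal(cycle_rank(d, edges = c(1, 2, 3)), 0L)
  expect_equal(cycle_rank(path_graph(6)), 0L)
  g <- grid_graph(3, 4)
  expect_equal(cycle_rank(g), n_edges(g) - n_nodes(g) + 1L)
})
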