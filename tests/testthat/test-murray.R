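# hand-built leak-free Y junction: parent width chosen so that
# w_p^3 = w_d1^3 + w_d2^3, with consistent flows (sinks only at the leaves)
leakfree_y <- function(wd = c(1, 1.5)) {
  wp <- sum(wd^3)^(1 / 3)
  venation_graph(
    nodes = data.frame(x = c(-1, 0, 1, 1), y = c(0, 0, 1, -1),
                       area = c(1, 1e-9, wd[1]^3, wd[2]^3)),
    edges = data.frame(tail = c(1, 2, 2), head = c(2, 3, 4), length = 1,
                       width = c(wp, wd)),
    source = 1, validate = FALSE
  )
}

test_that("a leak-free Y junction satisfies Murray's law at alpha = 3", {
  g <- leakfree_y()
  ens <- sink_ensemble(g, 0)
  tab <- murray_sums(g, edge_widths(g), ens, 3)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$R_in, tab$R_out, tolerance = 1e-6)
  expect_lt(murray_loss(g, edge_widths(g), ens, 3), 1e-12)
  # and the fitted exponent is exactly 3, invariant under width rescaling
  fa <- fit_alpha(g, edge_widths(g), ens)
  expect_equal(fa$alpha_star, 3, tolerance = 1e-3)
  fa2 <- fit_alpha(g, 10 * edge_widths(g), ens)
  expect_equal(fa2$alpha_star, fa$alpha_star, tolerance = 1e-3)
})

test_that("Murray sums are homogeneous of degree alpha in the widths", {
  g <- acc_lattice()
  fit <- acc_fit0()
  ens <- sink_ensemble(g, 0)
  for (a in c(2.5, 3, 3.5)) {
    t1 <- murray_sums(g, fit$widths_model, ens, a)
    t2 <- murray_sums(g, 2 * fit$widths_model, ens, a)
    expect_equal(t2$R_in, 2^a * t1$R_in, tolerance = 1e-9)
    expect_equal(t2$R_out, 2^a * t1$R_out, tolerance = 1e-9)
  }
})

test_that("widths versus radii shift both sums by 2^alpha and keep alpha*", {
  g <- acc_lattice()
  fit <- acc_fit0()
  ens <- sink_ensemble(g, 0)
  tr <- murray_sums(g, fit$widths_model, ens, 3, scale = "radius")
  tw <- murray_sums(g, fit$widths_model, ens, 3, scale = "width")
  expect_equal(tw$R_in, 2^3 * tr$R_in, tolerance = 1e-9)
  expect_equal(tw$R_out, 2^3 * tr$R_out, tolerance = 1e-9)
  aw <- fit_alpha(g, fit$widths_model, ens, scale = "width")
  expect_equal(aw$alpha_star, acc_alpha0()$alpha_star, tolerance = 1e-2)
})

test_that("loop edges flip in/out classification with the sink position", {
  # source -> two-path loop to a far node: the edge between the two loop
  # arms changes direction depending on which side the moving sink sits
  g <- venation_graph(
    nodes = data.frame(x = c(0, 1, 1, 2), y = c(0, 0.7, -0.7, 0), area = 1),
    edges = data.frame(tail = c(1, 1, 2, 3, 2), head = c(2, 3, 4, 4, 3),
                       length = c(1, 1, 1, 1, 1.4), width = 1),
    source = 1
  )
  ens <- sink_ensemble(g, 1)
  ind <- direction_indicators(g, edge_widths(g), ens, b = 2)
  # at least one incident edge is "in" for some member and "out" for another
  flips <- apply(ind, 2, function(col) {
    any(col == "in", na.rm = TRUE) && any(col == "out", na.rm = TRUE)
  })
  expect_true(any(flips))
  # and the number of outgoing terms differs between members
  n_out <- apply(ind, 1, function(row) sum(row == "out", na.rm = TRUE))
  expect_gt(length(unique(n_out)), 1L)
})

test_that("direction classification is constant across members on a tree at sigma 0", {
  g <- path_graph(7)
  # make an internal branch: attach two leaves to node 4
  g <- venation_graph(
    nodes = rbind(g$nodes, data.frame(x = c(4, 4), y = c(1, -1), area = 1)),
    edges = rbind(g$edges, data.frame(tail = c(4, 4), head = c(8, 9),
                                      length = 1, width = 1,
                                      conductivity = NA_real_)),
    source = 1
  )
  ens <- sink_ensemble(g, 0)
  ind <- direction_indicators(g, edge_widths(g), ens, b = 4)
  expect_true(all(apply(ind, 2, function(col) length(unique(col)) == 1L)))
})

test_that("sigma 0 tree residuals are negative and sink-area correctable", {
  g <- acc_lattice()
  fit <- acc_fit0()
  ens <- sink_ensemble(g, 0)
  tab <- murray_sums(g, fit$widths_model, ens, 3)
  expect_true(all(tab$residual < 0))
  sc <- sink_corrected_residuals(tab)
  expect_gt(sc$kappa, 0)
  # residual_b = -kappa * a_b exactly up to the optimizer tolerance
  expect_lt(max(abs(sc$table$corrected)) / mean(abs(tab$residual)), 1e-3)
})

test_that("sink fluctuation shifts residuals positively and widens them", {
  g <- acc_lattice()
  ens0 <- sink_ensemble(g, 0)
  ens1 <- sink_ensemble(g, 0.094)
  t0 <- murray_sums(g, acc_fit0()$widths_model, ens0, 3)
  t1 <- murray_sums(g, acc_fit094()$widths_model, ens1, 3)
  expect_gt(mean(t1$residual), mean(t0$residual))
  expect_gt(sd(t1$residual), sd(t0$residual))
})

test_that("the Murray loss is non-negative and smooth in alpha", {
  g <- acc_lattice()
  fit <- acc_fit0()
  ens <- sink_ensemble(g, 0)
  grid <- seq(2, 4, by = 0.05)
  L <- murray_loss(g, fit$widths_model, ens, grid)
  expect_true(all(L >= 0))
  # continuity: an infinitesimal step in alpha moves the loss infinitesimally
  for (a in c(2.3, 3, 3.7)) {
    L2 <- murray_loss(g, fit$widths_model, ens, c(a, a + 1e-7))
    expect_lt(abs(L2[2] - L2[1]), 1e-5 * max(L2[1], 1))
  }
})

test_that("residual profiles report kernel-weighted means and SDs", {
  g <- acc_lattice()
  fit <- acc_fit0()
  ens <- sink_ensemble(g, 0)
  tab <- murray_sums(g, fit$widths_model, ens, 3)
  # parent vein width: widest positive-width incident edge
  w <- fit$widths_model
  pw <- vapply(tab$node, function(b) {
    max(w[(g$edges$tail == b | g$edges$head == b) & w > 0])
  }, numeric(1))
  prof <- murray_residual_profile(tab, pw)
  expect_equal(nrow(prof), 50L)
  expect_true(all(prof$sd >= 0))
  expect_true(all(prof$mean < 0))  # negative bias across all widths
})
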