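# Small fixture graphs used across test files, plus memoized expensive
# model runs shared between test blocks.

two_node_graph <- function(ceff = 1, length = 1) {
  venation_graph(
    nodes = data.frame(x = c(0, 1), y = c(0, 0), area = c(1, 1)),
    edges = data.frame(tail = 1, head = 2, length = length,
                       width = 1, conductivity = ceff * length),
    source = 1
  )
}

path_graph <- function(n, areas = 1) {
  venation_graph(
    nodes = data.frame(x = seq_len(n), y = 0, area = areas),
    edges = data.frame(tail = seq_len(n - 1), head = 2:n, length = 1, width = 1),
    source = 1
  )
}

star_graph <- function(n_leaves = 3, areas = 1) {
  th <- seq_len(n_leaves) * 2 * pi / n_leaves
  venation_graph(
    nodes = data.frame(x = c(0, cos(th)), y = c(0, sin(th)), area = areas),
    edges = data.frame(tail = 1, head = 1 + seq_len(n_leaves),
                       length = 1, width = 1),
    source = 1
  )
}

# source feeding two parallel two-edge paths that rejoin (single loop)
diamond_graph <- function(widths = c(1.01, 1, 1, 0.99)) {
  venation_graph(
    nodes = data.frame(x = c(0, 1, 1, 2), y = c(0, 0.5, -0.5, 0), area = 1),
    edges = data.frame(tail = c(1, 1, 2, 3), head = c(2, 3, 4, 4),
                       length = 1, width = widths),
    source = 1
  )
}

# nr x nc rectangular grid with unit areas, source at corner
grid_graph <- function(nr, nc, seed = NULL) {
  idx <- function(r, c) (c - 1L) * nr + r
  tails <- heads <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r < nr) { tails <- c(tails, idx(r, c)); heads <- c(heads, idx(r + 1, c)) }
    if (c < nc) { tails <- c(tails, idx(r, c)); heads <- c(heads, idx(r, c + 1)) }
  }
  w <- if (is.null(seed)) rep(1, length(tails)) else
    with_seed(seed, stats::runif(length(tails), 0.5, 1.5))
  venation_graph(
    nodes = data.frame(x = rep(seq_len(nc), each = nr),
                       y = rep(seq_len(nr), nc), area = 1),
    edges = data.frame(tail = tails, head = heads, length = 1, width = w),
    source = 1
  )
}

with_seed <- venanet:::with_seed

# --- memoized expensive runs (shared across acceptance blocks) ----------

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# the study lattice for the Murray/topology experiments (~500 nodes)
acc_shape <- function() leaf_shape(spacing = 0.06, seed = 0)

acc_lattice <- function() memo("lattice", generate_leaf_lattice(acc_shape()))

acc_fit0 <- function() memo("fit0", {
  optimize_conductivities(acc_lattice(), optimizer_config(sigma = 0))
})

acc_fit094 <- function() memo("fit094", {
  optimize_conductivities(acc_lattice(), optimizer_config(sigma = 0.094))
})

acc_alpha0 <- function() memo("alpha0", {
  fit_alpha(acc_lattice(), acc_fit0()$widths_model,
            sink_ensemble(acc_lattice(), 0))
})

# parameter-recovery fixtures (~280-node lattice)
rec_shape <- function() leaf_shape(seed = 0)

rec_pseudo03 <- function() memo("pseudo03", {
  make_pseudo_data(rec_shape(), sigma_true = 0.3, noise_sd = 0.1, seed = 1)
})

rec_fit03 <- function() memo("recfit03", {
  suppressWarnings(fit_sigma(rec_pseudo03(), optimizer_config()))
})
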