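#' Partition a venation graph into spatial subsystems
#'
#' Divides the nodes into `K` clusters by k-means on the node coordinates.
#' For each subsystem with node set `Q` the partition records the interior
#' edges (both endpoints in `Q`), the crossing edges (exactly one endpoint
#' in `Q`), and the translation matrices that map full-system loads to
#' subsystem loads: `J` (`n_n x n_e`, the incidence entries `B_jk` for
#' `j` in `Q` and `k` crossing, zero elsewhere), `M` (`n_Q x n_n`, the row
#' selector for `Q`), so that `s_tilde = M (I - J G) s = Z s` adds to each
#' border node the net flow entering through its crossing edges.
#'
#' @param graph a `venation_graph`.
#' @param K number of subsystems (default 10).
#' @param seed seed for the k-means initialization.
#' @return an object of class `subsystem_partition`: list with `K`, `labels`
#'   (cluster per node) and `subsystems`, a list of per-cluster records
#'   `(nodes, interior, crossing, J, M)`.
#' @export
partition_subsystems <- function(graph, K = 10L, seed = 1L) {
  nn <- n_nodes(graph)
  stopifnot(K >= 1, K <= nn)
  xy <- cbind(graph$nodes$x, graph$nodes$y)
  labels <- NULL
  if (K == 1L) {
    labels <- rep(1L, nn)
  } else {
    for (try in 0:9) {
      km <- with_seed(seed + try, tryCatch(
        stats::kmeans(xy, centers = K, nstart = 5L, iter.max = 100L),
        error = function(e) NULL, warning = function(w) NULL
      ))
      if (!is.null(km) && length(unique(km$cluster)) == K) {
        labels <- as.integer(km$cluster)
        break
      }
    }
    if (is.null(labels)) stop("k-means failed to produce ", K, " non-empty clusters")
  }
  B <- incidence_matrix(graph)
  tl <- graph$edges$tail
  hd <- graph$edges$head
  ne <- n_edges(graph)
  subsystems <- lapply(seq_len(K), function(q) {
    inQ <- labels == q
    Q <- which(inQ)
    interior <- which(inQ[tl] & inQ[hd])
    crossing <- which(xor(inQ[tl], inQ[hd]))
    # J: incidence entries restricted to (node in Q) x (crossing edge)
    ji <- c(tl[crossing][inQ[tl[crossing]]], hd[crossing][inQ[hd[crossing]]])
    jj <- c(crossing[inQ[tl[crossing]]], crossing[inQ[hd[crossing]]])
    jx <- c(rep(1, sum(inQ[tl[crossing]])), rep(-1, sum(inQ[hd[crossing]])))
    J <- Matrix::sparseMatrix(i = ji, j = jj, x = jx, dims = c(nn, ne))
    M <- Matrix::sparseMatrix(i = seq_along(Q), j = Q, x = 1, dims = c(length(Q), nn))
    list(nodes = Q, interior = interior, crossing = crossing, J = J, M = M)
  })
  structure(list(K = as.integer(K), labels = labels, subsystems = subsystems),
            class = "subsystem_partition")
}

#' @export
print.subsystem_partition <- function(x, ...) {
  sizes <- vapply(x$subsystems, function(s) length(s$nodes), integer(1))
  cat(sprintf("<subsystem_partition> K = %d, node counts: %s\n",
              x$K, paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Translate full-system loads to subsystem loads
#'
#' Applies `Z = M (I - J G)` to each column of `S`: the subsystem load of a
#' border node is its own source/sink term plus the net flow entering
#' through its crossing edges, computed from the full-system fluxes
#' `F = G S`. Because the fluxes are evaluated at fixed (initial)
#' conductivities, `Z` need only be computed once per subsystem. Every
#' translated load is balanced on each connected component of the
#' subsystem's interior-edge subgraph.
#'
#' @param graph a `venation_graph`.
#' @param partition a [partition_subsystems()] result.
#' @param q subsystem index.
#' @param S full-system load matrix (`n_n x m`), e.g. [ensemble_matrix()].
#' @param conductivity conductivities at which the full-system fluxes are
#'   evaluated (default `width^4`).
#' @param F_full optional precomputed full-system flux matrix (`n_e x m`).
#' @return subsystem load matrix (`n_Q x m`).
#' @export
subsystem_loads <- function(graph, partition, q, S,
                            conductivity = NULL, F_full = NULL) {
  sub <- partition$subsystems[[q]]
  if (is.null(F_full)) {
    cond <- edge_conductances(graph, conductivity)
    ceff <- pmax(cond$ceff, .ceff_floor_rel * max(cond$ceff))
    B <- incidence_matrix(graph)
    st <- laplacian_solver(B, ceff, graph$source)
    F_full <- solve_grounded(st, S, graph$source,
                             graph$edges$tail, graph$edges$head, st$ceff)$f
  }
  as.matrix(sub$M %*% (S - sub$J %*% F_full))
}

# internal: incidence restricted to a subsystem (rows = nodes of Q in order,
# columns = interior edges), plus one grounded node per connected component
# of the interior subgraph.
subsystem_structure <- function(graph, sub) {
  Q <- sub$nodes
  interior <- sub$interior
  tl <- match(graph$edges$tail[interior], Q)
  hd <- match(graph$edges$head[interior], Q)
  nq <- length(Q)
  B <- Matrix::sparseMatrix(
    i = c(tl, hd), j = c(seq_along(interior), seq_along(interior)),
    x = c(rep(1, length(interior)), rep(-1, length(interior))),
    dims = c(nq, length(interior))
  )
  ig <- igraph::graph_from_edgelist(cbind(tl, hd), directed = FALSE)
  if (igraph::vcount(ig) < nq) ig <- igraph::add_vertices(ig, nq - igraph::vcount(ig))
  comp <- igraph::components(ig)$membership
  # ground the source if it lies in this subsystem, plus the first node of
  # every other component (matches the monolithic choice when K = 1)
  ground <- integer(0)
  src_local <- match(graph$source, Q)
  for (cmp in seq_len(max(comp))) {
    members <- which(comp == cmp)
    g0 <- if (!is.na(src_local) && src_local %in% members) src_local else members[1]
    ground <- c(ground, g0)
  }
  list(B = B, tl = tl, hd = hd, ground = ground,
       lengths = graph$edges$length[interior])
}

#' Subsystem flux solve
#'
#' Computes `f_tilde = G_tilde s_tilde` on the interior edges of subsystem
#' `q`: the Kirchhoff solve restricted to the subsystem's nodes and interior
#' edges, loaded with the translated vectors `Z s`. With unmodified
#' conductivities this reproduces the full-system fluxes on the interior
#' edges exactly.
#'
#' @inheritParams subsystem_loads
#' @return flux matrix (`n_interior_edges x m`); rows are indexed by
#'   `partition$subsystems[[q]]$interior`.
#' @export
subsystem_flux <- function(graph, partition, q, S,
                           conductivity = NULL, F_full = NULL) {
  sub <- partition$subsystems[[q]]
  St <- subsystem_loads(graph, partition, q, S, conductivity, F_full)
  cond <- edge_conductances(graph, conductivity)
  ceff_all <- pmax(cond$ceff, .ceff_floor_rel * max(cond$ceff))
  str <- subsystem_structure(graph, sub)
  ceff <- ceff_all[sub$interior]
  st <- laplacian_solver(str$B, ceff, str$ground)
  solve_grounded(st, St, str$ground, str$tl, str$hd, st$ceff)$f
}

#' Optimize a full leaf by subsystem decomposition
#'
#' Conductivity optimization for large networks: the nodes are split into
#' `config$subsystems` k-means clusters, the full-system ensemble fluxes and
#' the load-translation operators `Z` are computed once from the
#' data-initialized conductivities, and each subsystem's interior
#' conductivities are then optimized by the same fixed-point iteration as
#' [optimize_conductivities()] under its translated loads, with all
#' conductivities outside the subsystem held fixed. Crossing edges belong to
#' no subsystem interior and keep their data-initialized conductivities.
#' Final widths are normalized over the whole leaf. With
#' `config$subsystems = 1` this reproduces [optimize_conductivities()]
#' exactly.
#'
#' @param graph a `venation_graph` with positive widths and drainage areas.
#' @param config an [optimizer_config()].
#' @param partition optional precomputed [partition_subsystems()].
#' @return a `venation_fit` (see [optimize_conductivities()]) with extra
#'   elements `partition` and `subsystem_iterations`.
#' @export
optimize_full_leaf <- function(graph, config = optimizer_config(),
                               partition = NULL) {
  w0 <- edge_widths(graph)
  if (anyNA(w0) || any(w0 <= 0)) {
    stop("initial widths must all be positive (data initialization)")
  }
  c0 <- width_to_conductivity(w0)
  ens <- sink_ensemble(graph, config$sigma)
  S <- ensemble_matrix(ens, ensemble_distinct(ens))
  if (is.null(partition)) {
    partition <- partition_subsystems(graph, config$subsystems, config$seed)
  }
  # full-system fluxes at the initial conductivities, computed once
  ceff0 <- pmax(c0, .ceff_floor_rel * max(c0)) / edge_lengths(graph)
  B <- incidence_matrix(graph)
  st <- laplacian_solver(B, ceff0, graph$source)
  F_full <- solve_grounded(st, S, graph$source,
                           graph$edges$tail, graph$edges$head, st$ceff)$f
  cc <- c0
  f2 <- rowMeans(F_full^2)
  iters <- integer(partition$K)
  conv <- logical(partition$K)
  traces <- vector("list", partition$K)
  for (sweep in seq_len(config$sweeps)) {
    for (q in seq_len(partition$K)) {
      sub <- partition$subsystems[[q]]
      if (length(sub$interior) == 0L) {
        conv[q] <- TRUE
        next
      }
      St <- as.matrix(sub$M %*% (S - sub$J %*% F_full))
      str <- subsystem_structure(graph, sub)
      res <- iterate_conductivities(
        str$B, str$tl, str$hd, str$lengths, str$ground, St,
        cc[sub$interior], config$gamma, config$tol, config$max_iter,
        live_rel = config$zero_width_rel
      )
      c_new <- res$c
      if (partition$K > 1L) {
        # the fixed point lands in flux units while frozen crossing edges
        # stay in data units; conductivity scale within a subsystem is
        # arbitrary (flows are invariant), so rescale the interior back to
        # its initial material budget to keep all edges commensurate
        budget0 <- sum(str$lengths * cc[sub$interior]^config$gamma)
        budget1 <- sum(str$lengths * c_new^config$gamma)
        if (budget1 > 0) c_new <- c_new * (budget0 / budget1)^(1 / config$gamma)
      }
      cc[sub$interior] <- c_new
      f2[sub$interior] <- res$f2
      iters[q] <- iters[q] + res$iterations
      conv[q] <- res$converged
      traces[[q]] <- res$trace
    }
  }
  if (!all(conv)) {
    warning("subsystem(s) ", paste(which(!conv), collapse = ", "),
            " did not converge in ", config$max_iter, " iterations")
  }
  res_all <- list(c = cc, f2 = f2, converged = all(conv),
                  iterations = sum(iters),
                  trace = if (partition$K == 1L) traces[[1]] else
                    do.call(rbind, c(traces[!vapply(traces, is.null, TRUE)],
                                     make.row.names = FALSE)))
  finish_fit(graph, config, res_all,
             extra = list(partition = partition, subsystem_iterations = iters))
}
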