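#' Edge conductivities and conductances
#'
#' Laminar (Hagen-Poiseuille) flow through a cylindrical vein of width `w`
#' has conductivity proportional to `w^4`; the proportionality constant is
#' taken as 1 since all downstream quantities are normalized. The
#' conductance of an edge is its conductivity divided by its length,
#' `c_eff = c / l`.
#'
#' @param w vector of edge widths.
#' @return `width_to_conductivity()` returns `w^4`.
#' @export
width_to_conductivity <- function(w) w^4

#' @rdname width_to_conductivity
#' @param graph a `venation_graph`.
#' @param conductivity optional per-edge conductivities; default is the
#'   graph's `conductivity` column, falling back to `width^4`.
#' @return `edge_conductances()` returns a list with `c` (conductivities)
#'   and `ceff` (conductances `c/l`).
#' @export
edge_conductances <- function(graph, conductivity = NULL) {
  if (is.null(conductivity)) {
    conductivity <- graph$edges$conductivity
    if (anyNA(conductivity)) conductivity <- width_to_conductivity(graph$edges$width)
  }
  stopifnot(length(conductivity) == n_edges(graph), all(conductivity >= 0))
  list(c = conductivity, ceff = conductivity / graph$edges$length)
}

# Relative floor applied to conductivities when assembling the Laplacian, so
# that the grounded system stays non-singular while conductivities decay to
# zero during optimization. Exact-zero treatment applies only to reporting.
# The floor must sit far below the zero-width classification scale: a floor
# of eps * max(c) corresponds to widths of eps^(1/4) * w_max, so 1e-20
# keeps floor-limited edges two decades below the 1e-3 width cutoff.
.ceff_floor_rel <- 1e-20

#' Generalized moving-sink ensemble
#'
#' Builds the family of source-sink load vectors `s(k)`, one per sink node
#' `k`, that mixes a constant area-proportional background drainage with a
#' moving concentrated sink of relative amplitude `sigma`:
#' `s_source = 1` and, for every sink `j`,
#' `s_j(k) = -a_j (s_avg + delta_jk * sigma) * C(k)` with
#' `s_avg = (1 - sigma) / (n_n - 1)` and normalization
#' `C(k) = (sigma * a_k + s_avg * sum_j a_j)^-1`, which guarantees that each
#' member sums to zero exactly. At `sigma = 0` drainage is purely
#' area-proportional (all members coincide); at `sigma = 1` the moving sink
#' carries the whole load: `s_k = -1` and all other sink entries vanish.
#'
#' @param graph a `venation_graph` with positive drainage areas.
#' @param sigma sink fluctuation amplitude in `[0, 1]`.
#' @param areas optional drainage areas overriding the graph's.
#' @return an object of class `sink_ensemble`.
#' @export
sink_ensemble <- function(graph, sigma, areas = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0 || sigma > 1) {
    stop("sigma must be a single value in [0, 1]")
  }
  if (is.null(areas)) areas <- graph$nodes$area
  if (anyNA(areas) || any(areas <= 0)) {
    stop("all drainage areas must be positive; run drainage_areas() first")
  }
  nn <- n_nodes(graph)
  if (nn < 2L) stop("need at least one sink node")
  sinks <- setdiff(seq_len(nn), graph$source)
  s_avg <- (1 - sigma) / (nn - 1)
  area_sum <- sum(areas[sinks])
  C <- 1 / (sigma * areas[sinks] + s_avg * area_sum)  # indexed like `sinks`
  structure(
    list(sigma = sigma, source = graph$source, sinks = sinks,
         areas = areas, s_avg = s_avg, C = C, n_nodes = nn),
    class = "sink_ensemble"
  )
}

#' @export
print.sink_ensemble <- function(x, ...) {
  cat(sprintf("<sink_ensemble> sigma = %g, %d members (sink nodes), source %d\n",
              x$sigma, length(x$sinks), x$source))
  invisible(x)
}

#' Single member of the sink ensemble
#'
#' @param ensemble a [sink_ensemble()].
#' @param k sink node index (must not be the source).
#' @return the load vector `s(k)` of length `n_nodes`; sums to zero.
#' @export
sink_vector <- function(ensemble, k) {
  if (length(k) != 1L || !(k %in% ensemble$sinks)) {
    stop("k must be a single sink node (not the source)")
  }
  s <- numeric(ensemble$n_nodes)
  ck <- ensemble$C[match(k, ensemble$sinks)]
  s[ensemble$sinks] <- -ensemble$areas[ensemble$sinks] * ensemble$s_avg * ck
  s[k] <- s[k] - ensemble$areas[k] * ensemble$sigma * ck
  s[ensemble$source] <- 1
  s
}

#' All ensemble members as a matrix
#'
#' @param ensemble a [sink_ensemble()].
#' @param members optional subset of sink nodes.
#' @return dense `n_nodes x n_members` matrix, one load vector per column.
#' @export
ensemble_matrix <- function(ensemble, members = NULL) {
  if (is.null(members)) members <- ensemble$sinks
  stopifnot(all(members %in% ensemble$sinks))
  nn <- ensemble$n_nodes
  ck <- ensemble$C[match(members, ensemble$sinks)]
  base <- -ensemble$areas[ensemble$sinks] * ensemble$s_avg
  S <- matrix(0, nn, length(members))
  S[ensemble$sinks, ] <- outer(base, ck)
  S[cbind(members, seq_along(members))] <-
    S[cbind(members, seq_along(members))] -
    ensemble$areas[members] * ensemble$sigma * ck
  S[ensemble$source, ] <- 1
  S
}

# internal: members needed to evaluate the ensemble average. At sigma = 0
# every member is identical, so one representative suffices.
ensemble_distinct <- function(ensemble) {
  if (ensemble$sigma == 0) ensemble$sinks[1L] else ensemble$sinks
}

# internal: grounded sparse Cholesky solver for the weighted Laplacian.
# Returns pressures (gauge: p[ground] = 0) and fluxes for a matrix of
# balanced load vectors. One step of iterative refinement keeps the
# conservation residual near machine precision even for badly scaled
# conductances.
laplacian_solver <- function(B, ceff, ground, chol = NULL) {
  # When whole neighborhoods decay to the conductance floor, rounding can
  # push a pivot of the (analytically SPD) grounded Laplacian nonpositive;
  # retry with a progressively higher floor for this solve only. The
  # stored conductivities are untouched.
  for (floor_rel in c(0, 1e-16, 1e-13, 1e-10)) {
    cf <- if (floor_rel == 0) ceff else pmax(ceff, floor_rel * max(ceff))
    A <- Matrix::forceSymmetric(B %*% Matrix::Diagonal(x = cf) %*% Matrix::t(B))
    Ar <- A[-ground, -ground, drop = FALSE]
    ch <- tryCatch({
      if (is.null(chol)) Matrix::Cholesky(Ar, LDL = FALSE)
      else Matrix::update(chol, Ar)
    }, error = function(e) NULL)
    if (is.null(ch) && !is.null(chol)) {
      ch <- tryCatch(Matrix::Cholesky(Ar, LDL = FALSE),
                     error = function(e) NULL)
    }
    if (!is.null(ch)) return(list(chol = ch, Ar = Ar, ceff = cf))
  }
  stop("grounded Laplacian factorization failed: graph disconnected at ",
       "positive conductances?")
}

solve_grounded <- function(state, S, ground, tl, hd, ceff) {
  nn <- nrow(S)
  Sr <- S[-ground, , drop = FALSE]
  P <- Matrix::solve(state$chol, Sr)
  # one refinement step
  R <- Sr - state$Ar %*% P
  P <- P + Matrix::solve(state$chol, R)
  p <- matrix(0, nn, ncol(S))
  p[seq_len(nn)[-ground], ] <- as.matrix(P)
  f <- ceff * (p[tl, , drop = FALSE] - p[hd, , drop = FALSE])
  list(p = p, f = f)
}

#' Solve Kirchhoff flow for one load vector
#'
#' Solves `A p = s` with `A = B C_eff B^T` the weighted graph Laplacian
#' (pseudo-inverse semantics: the pressure gauge is fixed by grounding the
#' source node, which is immaterial since only pressure differences enter
#' the fluxes), then computes edge fluxes `f = C_eff B^T p`. Conservation
#' `B f = s` is verified to `1e-9 * max|s|` and violated only if the support
#' of `s` is disconnected from the source through positive conductances.
#'
#' @param graph a `venation_graph`.
#' @param s balanced load vector (`sum(s) = 0`).
#' @param conductivity optional conductivities (default `width^4`).
#' @return a list of class `flow_solution` with node pressures `p` and edge
#'   fluxes `f` (positive flux = tail-to-head flow).
#' @export
solve_flow <- function(graph, s, conductivity = NULL) {
  stopifnot(length(s) == n_nodes(graph))
  if (abs(sum(s)) > 1e-9 * max(abs(s))) {
    stop("load vector s is not balanced (sum != 0)")
  }
  cond <- edge_conductances(graph, conductivity)
  ceff <- pmax(cond$ceff, .ceff_floor_rel * max(cond$ceff))
  B <- incidence_matrix(graph)
  st <- laplacian_solver(B, ceff, graph$source)
  sol <- solve_grounded(st, matrix(s, ncol = 1), graph$source,
                        graph$edges$tail, graph$edges$head, st$ceff)
  f <- drop(sol$f)
  resid <- max(abs(as.vector(B %*% f) - s))
  if (!is.finite(resid) || resid > 1e-9 * max(abs(s))) {
    stop("flow solve failed (conservation residual ", format(resid),
         "); is the support of s connected to the source through positive ",
         "conductances?")
  }
  structure(list(p = drop(sol$p), f = f), class = "flow_solution")
}

#' Ensemble-averaged squared fluxes
#'
#' Computes `<f_i^2> = (1 / (n_n - 1)) * sum_k f_i^2(s(k))`, the uniform
#' average of the squared edge fluxes over all moving-sink positions `k`,
#' together with per-edge flow-direction fractions: the share of ensemble
#' members in which the flux runs tail-to-head (`frac_forward`) or
#' head-to-tail (`frac_backward`). Members with `|f| < 1e-12 * max|f|` on an
#' edge count to neither direction.
#'
#' @param graph a `venation_graph`.
#' @param ensemble a [sink_ensemble()].
#' @param conductivity optional conductivities (default `width^4`).
#' @return list with `f2`, `frac_forward`, `frac_backward`, `n_members`.
#' @export
ensemble_second_moment <- function(graph, ensemble, conductivity = NULL) {
  cond <- edge_conductances(graph, conductivity)
  ceff <- pmax(cond$ceff, .ceff_floor_rel * max(cond$ceff))
  B <- incidence_matrix(graph)
  st <- laplacian_solver(B, ceff, graph$source)
  S <- ensemble_matrix(ensemble)
  sol <- solve_grounded(st, S, graph$source,
                        graph$edges$tail, graph$edges$head, st$ceff)
  F <- sol$f
  tol <- 1e-12 * max(abs(F))
  list(
    f2 = rowMeans(F^2),
    frac_forward = rowMeans(F > tol),
    frac_backward = rowMeans(F < -tol),
    n_members = ncol(S)
  )
}

#' Dissipated power
#'
#' `P = sum_i f_i^2 / c_eff_i` over edges with positive conductance. Edges
#' with zero conductance carry no flux and contribute nothing; a non-zero
#' flux on such an edge is an inconsistency and raises an error.
#'
#' @param f per-edge fluxes.
#' @param ceff per-edge conductances (`c / l`).
#' @return scalar dissipation.
#' @export
dissipated_power <- function(f, ceff) {
  stopifnot(length(f) == length(ceff))
  zero <- ceff == 0
  if (any(zero) && any(abs(f[zero]) > 1e-12 * max(abs(f), 1e-300))) {
    stop("non-zero flux on a zero-conductance edge")
  }
  sum(f[!zero]^2 / ceff[!zero])
}
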