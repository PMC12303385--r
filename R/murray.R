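#' Murray's law for reticulate networks
#'
#' Classical Murray's law states that at a branch point the parent radius
#' obeys `r_p^alpha = sum_i r_d_i^alpha` with `alpha = 3` for leak-free
#' laminar flow, but it is only defined on trees. In a reticulate network
#' the in/out classification of the veins at a branch node depends on where
#' the moving sink sits, so the law is extended by averaging the
#' direction-resolved radius sums over the sink ensemble:
#' `R_b_in/out(alpha) = < sum_i I_b_i_in/out(k) * r_b_i^alpha >_k`,
#' the extended law being `R_b_in = R_b_out`, and the branching exponent is
#' fitted by minimizing `L(alpha) = <(R_b_out - R_b_in)^2>_b` over the
#' branch nodes (degree > 2 among positive-width edges).
#'
#' Because the radii do not depend on the sink position, the ensemble
#' average factorizes exactly into per-edge direction fractions:
#' `R_b_in(alpha) = sum_i p_in(b, i) * r_i^alpha` where `p_in(b, i)` is the
#' fraction of ensemble members in which edge `i` carries flow into `b`
#' (members with `|f| < 1e-12 * max|f|` on the edge count to neither
#' direction).
#'
#' @name murray
NULL

# internal: per-(branch node, incident positive-width edge) direction
# fractions under the sink ensemble, at conductivities w^4.
murray_incidences <- function(graph, widths, ensemble) {
  stopifnot(length(widths) == n_edges(graph))
  deg <- node_degrees(graph, widths > 0)
  # the source is excluded: it carries the net injection, so in/out radius
  # sums cannot balance there (a leaf's petiole is a single entering vein
  # and never a branch node in extracted data)
  branch <- setdiff(which(deg > 2L), graph$source)
  cond <- width_to_conductivity(widths)
  ceff <- pmax(cond, .ceff_floor_rel * max(cond)) / edge_lengths(graph)
  B <- incidence_matrix(graph)
  st <- laplacian_solver(B, ceff, graph$source)
  S <- ensemble_matrix(ensemble, ensemble_distinct(ensemble))
  F <- solve_grounded(st, S, graph$source,
                      graph$edges$tail, graph$edges$head, st$ceff)$f
  tol <- 1e-12 * max(abs(F))
  tl <- graph$edges$tail
  hd <- graph$edges$head
  rows <- lapply(branch, function(b) {
    inc <- which((tl == b | hd == b) & widths > 0)
    # flow into b: toward the head when b is the head, toward the tail when
    # the flux is negative and b is the tail
    sgn <- ifelse(hd[inc] == b, 1, -1)
    Fb <- F[inc, , drop = FALSE] * sgn
    data.frame(
      node = b,
      edge = inc,
      width = widths[inc],
      frac_in = rowMeans(Fb > tol),
      frac_out = rowMeans(Fb < -tol)
    )
  })
  list(branch = branch, incidences = do.call(rbind, rows),
       n_members = ncol(F), flux_tol = tol, F = F)
}

#' Per-member flow directions at one branch node
#'
#' For each ensemble member `k` and each positive-width edge incident to
#' branch node `b`, classifies the flow as `"in"` (toward `b`), `"out"`
#' (away from `b`) or `NA` (flux below `1e-12 * max|f|`, excluded from both
#' Murray sums). The number of in/out terms can change with the sink
#' position; that is precisely what the ensemble-averaged law accounts for.
#'
#' @param graph a `venation_graph`.
#' @param widths per-edge widths of the analysed network (model output).
#' @param ensemble a [sink_ensemble()].
#' @param b a branch node (degree > 2 among positive-width edges).
#' @return a character matrix (`n_members x n_incident_edges`, columns named
#'   by edge index) with entries `"in"`, `"out"` or `NA`.
#' @export
direction_indicators <- function(graph, widths, ensemble, b) {
  deg <- node_degrees(graph, widths > 0)
  if (deg[b] <= 2L) stop("node ", b, " is not a branch node (degree <= 2)")
  cond <- width_to_conductivity(widths)
  ceff <- pmax(cond, .ceff_floor_rel * max(cond)) / edge_lengths(graph)
  B <- incidence_matrix(graph)
  st <- laplacian_solver(B, ceff, graph$source)
  S <- ensemble_matrix(ensemble)
  F <- solve_grounded(st, S, graph$source,
                      graph$edges$tail, graph$edges$head, st$ceff)$f
  tol <- 1e-12 * max(abs(F))
  inc <- which((graph$edges$tail == b | graph$edges$head == b) & widths > 0)
  sgn <- ifelse(graph$edges$head[inc] == b, 1, -1)
  Fb <- t(F[inc, , drop = FALSE] * sgn)
  out <- matrix(NA_character_, nrow(Fb), ncol(Fb),
                dimnames = list(NULL, as.character(inc)))
  out[Fb > tol] <- "in"
  out[Fb < -tol] <- "out"
  out
}

#' Ensemble-averaged Murray sums per branch node
#'
#' @inheritParams direction_indicators
#' @param alpha branching exponent.
#' @param scale `"radius"` (default, `r = w/2`) or `"width"`; the choice
#'   rescales `R_in` and `R_out` by the same factor `2^alpha` and leaves the
#'   extended law and the fitted exponent unchanged.
#' @return a data.frame (one row per branch node) with columns `node`,
#'   `degree`, `R_in`, `R_out`, `residual` (`R_out - R_in`) and `area` (the
#'   node's drainage area, `NA` when absent).
#' @export
murray_sums <- function(graph, widths, ensemble, alpha = 3,
                        scale = c("radius", "width")) {
  scale <- match.arg(scale)
  mi <- murray_incidences(graph, widths, ensemble)
  if (length(mi$branch) == 0L) {
    warning("no branch nodes (degree > 2) in the positive-width subgraph")
    return(data.frame(node = integer(0), degree = integer(0),
                      R_in = numeric(0), R_out = numeric(0),
                      residual = numeric(0), area = numeric(0)))
  }
  inc <- mi$incidences
  r <- if (scale == "radius") inc$width / 2 else inc$width
  ra <- r^alpha
  f <- factor(inc$node, levels = mi$branch)
  R_in <- as.vector(rowsum(inc$frac_in * ra, f))
  R_out <- as.vector(rowsum(inc$frac_out * ra, f))
  data.frame(
    node = mi$branch,
    degree = as.vector(table(f)),
    R_in = R_in, R_out = R_out,
    residual = R_out - R_in,
    area = graph$nodes$area[mi$branch]
  )
}

#' Murray loss over branch nodes
#'
#' `L(alpha) = <(R_b_out(alpha) - R_b_in(alpha))^2>_b`, the mean squared
#' residual of the extended Murray's law over branch nodes.
#'
#' @inheritParams murray_sums
#' @param alpha vector of exponents (vectorized).
#' @return numeric vector `L(alpha)`.
#' @export
murray_loss <- function(graph, widths, ensemble, alpha,
                        scale = c("radius", "width")) {
  scale <- match.arg(scale)
  mi <- murray_incidences(graph, widths, ensemble)
  if (length(mi$branch) == 0L) stop("no branch nodes")
  inc <- mi$incidences
  r <- if (scale == "radius") inc$width / 2 else inc$width
  d <- inc$frac_out - inc$frac_in
  f <- factor(inc$node, levels = mi$branch)
  vapply(alpha, function(a) {
    res <- as.vector(rowsum(d * r^a, f))
    mean(res^2)
  }, numeric(1))
}

#' Fit the Murray branching exponent
#'
#' Evaluates `L(alpha)` on a grid and refines the argmin by parabolic
#' interpolation of the three bracketing points. A minimum on the grid
#' boundary is returned as-is with `bracketed = FALSE`.
#'
#' @inheritParams murray_sums
#' @param alpha_grid grid of exponents (default `seq(2, 4, by = 0.01)`).
#' @return an object of class `murray_fit`: list with `alpha` (grid),
#'   `loss`, `alpha_star`, `bracketed`, and the [murray_sums()] `table` at
#'   the fitted exponent.
#' @export
fit_alpha <- function(graph, widths, ensemble,
                      alpha_grid = seq(2, 4, by = 0.01),
                      scale = c("radius", "width")) {
  scale <- match.arg(scale)
  loss <- murray_loss(graph, widths, ensemble, alpha_grid, scale)
  ref <- refine_argmin(alpha_grid, loss)
  if (!ref$bracketed) {
    warning("bracket failure: Murray loss minimum on the grid boundary")
  }
  structure(
    list(alpha = alpha_grid, loss = loss, alpha_star = ref$x,
         bracketed = ref$bracketed,
         table = murray_sums(graph, widths, ensemble, ref$x, scale)),
    class = "murray_fit"
  )
}

#' @export
print.murray_fit <- function(x, ...) {
  cat(sprintf("<murray_fit> alpha* = %.4f (%s), %d branch nodes, L(alpha*) = %.4g\n",
              x$alpha_star,
              if (x$bracketed) "bracketed" else "grid boundary",
              nrow(x$table), min(x$loss)))
  invisible(x)
}

#' Sink-area correction of Murray residuals
#'
#' The model removes fluid at every node, so even a perfect tree violates
#' the leak-free law: at the fixed point `w^3` is proportional to `|f|` and
#' flux conservation leaves a deficit proportional to the node's own sink,
#' i.e. to its drainage area. The correction fits a single coefficient
#' `kappa = argmin sum_b (residual_b + kappa * a_b)^2` (closed form) and
#' returns the corrected residuals `residual_b + kappa * a_b`.
#'
#' @param table a [murray_sums()] table with `residual` and `area` columns.
#' @param areas optional drainage areas overriding `table$area`.
#' @return list with `kappa` and the `table` augmented with a `corrected`
#'   column.
#' @export
sink_corrected_residuals <- function(table, areas = NULL) {
  a <- if (is.null(areas)) table$area else areas[table$node]
  if (anyNA(a) || all(a == 0)) stop("drainage areas required for the sink correction")
  kappa <- -sum(table$residual * a) / sum(a^2)
  table$corrected <- table$residual + kappa * a
  list(kappa = kappa, table = table)
}

#' Smoothed residual profile versus vein width
#'
#' Gaussian-kernel weighted mean and standard deviation of the (optionally
#' corrected) Murray residuals as a function of the parent-vein width (the
#' widest vein incident to the branch node), on a log10-width axis.
#'
#' @param table a [murray_sums()] table (optionally with a `corrected`
#'   column from [sink_corrected_residuals()]).
#' @param parent_width per-branch-node parent vein widths.
#' @param value which residual column to profile.
#' @param bandwidth kernel bandwidth in log10-width units.
#' @param n number of evaluation points.
#' @return data.frame with `width`, `mean`, `sd`.
#' @export
murray_residual_profile <- function(table, parent_width,
                                    value = c("residual", "corrected"),
                                    bandwidth = 0.2, n = 50L) {
  value <- match.arg(value)
  stopifnot(length(parent_width) == nrow(table), all(parent_width > 0))
  lw <- log10(parent_width)
  y <- table[[value]]
  at <- seq(min(lw), max(lw), length.out = n)
  prof <- vapply(at, function(x0) {
    w <- exp(-0.5 * ((lw - x0) / bandwidth)^2)
    w <- w / sum(w)
    m <- sum(w * y)
    s <- sqrt(max(sum(w * (y - m)^2), 0))
    c(m, s)
  }, numeric(2))
  data.frame(width = 10^at, mean = prof[1, ], sd = prof[2, ])
}
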