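#' Optimizer configuration
#'
#' Parameters of the fixed-point conductivity optimization.
#'
#' @param sigma sink fluctuation amplitude in `[0, 1]`.
#' @param gamma material-cost exponent (> 0) in the budget `sum(l * c^gamma)`;
#'   the default `1/2` fixes the total vein volume (`sum(l * w^2)`).
#' @param tol convergence tolerance: iteration stops when the per-edge
#'   relative conductivity change `|c_new - c| / c_new` falls below `tol` on
#'   every surviving edge (edges above `1e-12` of the maximum conductivity;
#'   edges below that are decaying to zero and are already immaterial).
#' @param max_iter maximum number of fixed-point iterations.
#' @param zero_width_rel normalized widths below `zero_width_rel *
#'   mean(data widths)` are reported as exactly zero.
#' @param subsystems number of k-means subsystems used by
#'   [optimize_full_leaf()].
#' @param sweeps number of passes over the subsystems (default 1; the load
#'   translation is computed once from the initial conductivities).
#' @param seed seed for the k-means partition.
#' @return a list of class `optimizer_config`.
#' @export
optimizer_config <- function(sigma = 0, gamma = 0.5, tol = 1e-6,
                             max_iter = 5000L, zero_width_rel = 1e-3,
                             subsystems = 10L, sweeps = 1L, seed = 1L) {
  stopifnot(sigma >= 0, sigma <= 1, gamma > 0, tol > 0,
            max_iter >= 1, subsystems >= 1, sweeps >= 1)
  structure(
    list(sigma = sigma, gamma = gamma, tol = tol,
         max_iter = as.integer(max_iter), zero_width_rel = zero_width_rel,
         subsystems = as.integer(subsystems), sweeps = as.integer(sweeps),
         seed = as.integer(seed)),
    class = "optimizer_config"
  )
}

#' One fixed-point update of the conductivities
#'
#' Solves the flow for every ensemble member at the current conductivities
#' and applies the optimality scaling `c_i <- <f_i^2>^(1 / (1 + gamma))`,
#' the fixed point of which satisfies the Lagrange condition
#' `c_i ~ |f_i|^(2 / (1 + gamma))` for minimal dissipation at fixed material
#' cost. Conductivities are in arbitrary units; no per-step budget rescaling
#' is applied (the output scale is set by width normalization at the end).
#'
#' @param graph a `venation_graph`.
#' @param conductivity current per-edge conductivities.
#' @param ensemble a [sink_ensemble()].
#' @param gamma material-cost exponent.
#' @return updated conductivity vector.
#' @export
fixed_point_step <- function(graph, conductivity, ensemble, gamma = 0.5) {
  mom <- ensemble_second_moment(graph, ensemble, conductivity)
  mom$f2^(1 / (1 + gamma))
}

#' Normalize model widths to the data scale
#'
#' The optimization works in arbitrary conductivity units, so output widths
#' are rescaled to match the unweighted mean of the observed widths:
#' `w_hat = mean(w_data) / mean(w_model) * w_model`.
#'
#' @param w_model raw model widths.
#' @param w_data observed widths.
#' @return normalized widths with `mean(w_hat) == mean(w_data)`.
#' @export
normalize_widths <- function(w_model, w_data) {
  stopifnot(length(w_model) == length(w_data))
  m <- mean(w_model)
  if (!is.finite(m) || m <= 0) stop("mean model width must be positive")
  mean(w_data) / m * w_model
}

# internal fixed-point driver shared by the monolithic and the subsystem
# optimizer (identical arithmetic => K = 1 reproduces the monolithic result
# bit for bit).
#
# B: incidence (nn x ne); ground: one grounded node per connected component;
# S: load matrix (nn x m), one ensemble member per column; c0: initial
# conductivities. Returns the converged conductivities, the last <f^2>, and
# a per-iteration trace of the relative change and of the ensemble-averaged
# dissipation at fixed material budget (a Lyapunov function of the
# iteration).
iterate_conductivities <- function(B, tl, hd, lengths, ground, S, c0,
                                   gamma, tol, max_iter,
                                   live_rel = 1e-3) {
  cc <- c0
  ch <- NULL
  delta_tr <- power_tr <- numeric(0)
  converged <- FALSE
  iters <- 0L
  f2 <- NULL
  for (it in seq_len(max_iter)) {
    ceff <- pmax(cc, .ceff_floor_rel * max(cc)) / lengths
    st <- laplacian_solver(B, ceff, ground, chol = ch)
    ch <- st$chol
    sol <- solve_grounded(st, S, ground, tl, hd, st$ceff)
    f2 <- rowMeans(sol$f^2)
    # monitoring: dissipation rescaled to a unit material budget; uniform
    # conductivity rescaling leaves the flow pattern unchanged, so this is
    # the scale-free quantity that the fixed point minimizes.
    vol <- sum(lengths * cc^gamma)
    power_tr <- c(power_tr, sum(f2 / st$ceff) * vol^(1 / gamma))
    c_new <- f2^(1 / (1 + gamma))
    # per-edge relative change over surviving edges. "Surviving" uses the
    # same scale as the final zero-width classification (width below
    # live_rel of the mean width), so the iteration cannot stop while an
    # edge that will be reported nonzero is still decaying; edges below the
    # cutoff are dying double-exponentially and keep an O(1) relative
    # change all the way to the floor, hence are excluded.
    w_new <- c_new^(1 / 4)
    # one safety decade below the classification cutoff: decay through it
    # is double-exponential (2-3 iterations), and the margin absorbs the
    # small scale differences between a subsystem and the whole leaf
    live <- w_new >= 0.1 * live_rel * mean(w_new)
    delta <- max(abs(c_new[live] - cc[live]) / c_new[live])
    delta_tr <- c(delta_tr, delta)
    cc <- c_new
    iters <- it
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(c = cc, f2 = f2, converged = converged, iterations = iters,
       trace = data.frame(iteration = seq_len(iters), delta = delta_tr,
                          power = power_tr))
}

finish_fit <- function(graph, config, res, extra = list()) {
  w_data <- edge_widths(graph)
  w_raw <- res$c^(1 / 4)
  w_hat <- normalize_widths(w_raw, w_data)
  zero <- w_hat < config$zero_width_rel * mean(w_data)
  w_model <- ifelse(zero, 0, w_hat)
  out <- c(list(
    graph = graph, config = config,
    widths_model = w_model, widths_raw = w_raw,
    conductivity = res$c, f2 = res$f2,
    converged = res$converged, iterations = res$iterations,
    trace = res$trace
  ), extra)
  structure(out, class = "venation_fit")
}

#' Optimize edge conductivities by fixed-point iteration
#'
#' Starting from the observed widths (`c_i(0) = w_i_data^4`, which selects
#' the local optimum nearest the observed network in the highly non-convex
#' dissipation landscape), repeatedly solves the Kirchhoff flow for the
#' whole sink ensemble and updates `c_i <- <f_i^2>^(1/(1+gamma))` until the
#' relative change falls below `config$tol`. The converged widths
#' `w = c^(1/4)` are normalized to the mean data width (see
#' [normalize_widths()]); normalized widths below
#' `config$zero_width_rel * mean(w_data)` are reported as zero. With
#' `sigma = 0` the surviving positive-width edges form a spanning tree;
#' positive `sigma` retains loops.
#'
#' @param graph a `venation_graph` with positive widths and drainage areas.
#' @param config an [optimizer_config()].
#' @param init_widths optional initialization overriding the graph widths.
#' @return an object of class `venation_fit` with elements `widths_model`
#'   (normalized, with exact zeros), `widths_raw`, `conductivity`, `f2`,
#'   `converged`, `iterations` and a per-iteration `trace`.
#' @export
optimize_conductivities <- function(graph, config = optimizer_config(),
                                    init_widths = NULL) {
  w0 <- if (is.null(init_widths)) edge_widths(graph) else init_widths
  if (anyNA(w0) || any(w0 <= 0)) {
    stop("initial widths must all be positive (data initialization)")
  }
  ens <- sink_ensemble(graph, config$sigma)
  S <- ensemble_matrix(ens, ensemble_distinct(ens))
  B <- incidence_matrix(graph)
  res <- iterate_conductivities(
    B, graph$edges$tail, graph$edges$head, edge_lengths(graph),
    graph$source, S, width_to_conductivity(w0),
    config$gamma, config$tol, config$max_iter,
    live_rel = config$zero_width_rel
  )
  if (!res$converged) {
    warning("fixed-point iteration did not converge in ", config$max_iter,
            " iterations (last relative change ",
            format(res$trace$delta[res$iterations]), ")")
  }
  finish_fit(graph, config, res)
}

#' @export
print.venation_fit <- function(x, ...) {
  cat(sprintf(
    "<venation_fit> sigma = %g, gamma = %g: %s after %d iterations\n",
    x$config$sigma, x$config$gamma,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  nz <- sum(x$widths_model > 0)
  cat(sprintf("  %d of %d edges with positive model width (cycle rank %d)\n",
              nz, length(x$widths_model),
              cycle_rank(x$graph, x$widths_model > 0)))
  invisible(x)
}

#' Graph carrying the fitted model widths
#'
#' @param fit a `venation_fit`.
#' @return the input graph with the model widths in the `width` column and
#'   the converged conductivities in the `conductivity` column.
#' @export
fitted_graph <- function(fit) {
  g <- fit$graph
  g$edges$width <- fit$widths_model
  g$edges$conductivity <- fit$conductivity
  g
}
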