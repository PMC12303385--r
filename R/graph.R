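#' Construct a venation graph
#'
#' A `venation_graph` is a directed planar graph describing a leaf venation
#' network: nodes carry coordinates and (optionally) drainage areas, edges
#' carry a length, a width and (optionally) a conductivity. A single node,
#' the petiole, acts as the fluid source; every other node is a sink.
#'
#' Edge direction is a bookkeeping convention only: a positive flux on an
#' edge means flow from `tail` to `head`, and all physical quantities used
#' downstream depend on `|f|` or on the sign of `f` relative to a node.
#'
#' @param nodes data.frame with numeric columns `x`, `y` and optionally
#'   `area` (drainage area of the node's boundary-clipped Voronoi cell).
#' @param edges data.frame with integer columns `tail`, `head` (1-based node
#'   indices), numeric `length` (> 0), `width` (>= 0) and optionally
#'   `conductivity`.
#' @param source index of the source (petiole) node.
#' @param node_ids,edge_ids optional character ids preserved through file
#'   I/O; defaults are the decimal indices.
#' @param validate if `TRUE` (default), stop on an invalid graph.
#' @return an object of class `venation_graph`.
#' @seealso [validate_graph()], [incidence_matrix()], [read_venation()]
#' @export
venation_graph <- function(nodes, edges, source = 1L,
                           node_ids = NULL, edge_ids = NULL,
                           validate = TRUE) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("x", "y") %in% names(nodes)))
  stopifnot(all(c("tail", "head") %in% names(edges)))
  if (is.null(nodes$area)) nodes$area <- NA_real_
  if (is.null(edges$length)) edges$length <- NA_real_
  if (is.null(edges$width)) edges$width <- NA_real_
  if (is.null(edges$conductivity)) edges$conductivity <- NA_real_
  nodes <- nodes[, c("x", "y", "area")]
  edges <- edges[, c("tail", "head", "length", "width", "conductivity")]
  edges$tail <- as.integer(edges$tail)
  edges$head <- as.integer(edges$head)
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  g <- structure(
    list(
      nodes = nodes,
      edges = edges,
      source = as.integer(source),
      node_ids = if (is.null(node_ids)) as.character(seq_len(nrow(nodes))) else as.character(node_ids),
      edge_ids = if (is.null(edge_ids)) as.character(seq_len(nrow(edges))) else as.character(edge_ids)
    ),
    class = "venation_graph"
  )
  if (validate) {
    rep <- validate_graph(g)
    if (!rep$valid) {
      stop("invalid venation graph: ", paste(rep$violations, collapse = "; "))
    }
  }
  g
}

#' Validate a venation graph
#'
#' Checks the structural invariants of a [venation_graph()]: edge endpoints
#' reference existing nodes, no self-loops, strictly positive lengths,
#' non-negative widths, exactly one source node inside the node range, unique
#' external ids, and connectivity of the positive-width subgraph (input data
#' contain no zero-width edges, so this is the graph that must be connected).
#'
#' @param graph a `venation_graph` (or a bare list with the same slots).
#' @return a list with elements `valid` (logical) and `violations`
#'   (character vector, empty when valid). The graph is not modified.
#' @export
validate_graph <- function(graph) {
  v <- character(0)
  nn <- nrow(graph$nodes)
  ne <- nrow(graph$edges)
  if (nn < 1L) v <- c(v, "no nodes")
  if (length(graph$source) != 1L || is.na(graph$source) ||
      graph$source < 1L || graph$source > nn) {
    v <- c(v, "source index out of range")
  }
  if (anyDuplicated(graph$node_ids)) v <- c(v, "duplicate node id")
  if (anyDuplicated(graph$edge_ids)) v <- c(v, "duplicate edge id")
  if (!all(is.finite(graph$nodes$x)) || !all(is.finite(graph$nodes$y))) {
    v <- c(v, "non-finite node coordinate")
  }
  if (ne > 0L) {
    tl <- graph$edges$tail
    hd <- graph$edges$head
    if (anyNA(tl) || anyNA(hd) || any(tl < 1L | tl > nn) || any(hd < 1L | hd > nn)) {
      v <- c(v, "edge endpoint references missing node")
    } else {
      if (any(tl == hd)) v <- c(v, "self-loop edge")
    }
    len <- graph$edges$length
    if (anyNA(len) || any(len <= 0)) v <- c(v, "non-positive length")
    w <- graph$edges$width
    if (anyNA(w) || any(w < 0)) v <- c(v, "negative or missing width")
    # connectivity of the positive-width subgraph
    if (!anyNA(tl) && !anyNA(hd) && all(tl >= 1L & tl <= nn & hd >= 1L & hd <= nn) &&
        !anyNA(w)) {
      keep <- w > 0
      if (nn > 1L) {
        ig <- igraph::graph_from_edgelist(
          cbind(tl[keep], hd[keep]),
          directed = FALSE
        )
        if (igraph::vcount(ig) < nn) {
          ig <- igraph::add_vertices(ig, nn - igraph::vcount(ig))
        }
        if (igraph::count_components(ig) > 1L) v <- c(v, "disconnected")
      }
    }
  } else if (nn > 1L) {
    v <- c(v, "disconnected")
  }
  list(valid = length(v) == 0L, violations = v)
}

#' Signed incidence matrix
#'
#' Builds the sparse `n_nodes x n_edges` incidence matrix `B` with `+1` at
#' each edge's tail row and `-1` at its head row, so that a flux `f_i > 0`
#' means flow from tail to head. Every column has exactly one `+1` and one
#' `-1`, hence column sums are zero, and the weighted graph Laplacian
#' `A = B C_eff B^T` of a connected graph has rank `n_nodes - 1`.
#'
#' @param graph a valid `venation_graph`.
#' @return a `Matrix::sparseMatrix` of dimension `n_nodes x n_edges`.
#' @export
incidence_matrix <- function(graph) {
  rep <- validate_graph(graph)
  if (!rep$valid) {
    stop("cannot build incidence matrix: ", paste(rep$violations, collapse = "; "))
  }
  ne <- nrow(graph$edges)
  Matrix::sparseMatrix(
    i = c(graph$edges$tail, graph$edges$head),
    j = c(seq_len(ne), seq_len(ne)),
    x = c(rep(1, ne), rep(-1, ne)),
    dims = c(nrow(graph$nodes), ne)
  )
}

#' @export
print.venation_graph <- function(x, ...) {
  cat(sprintf(
    "<venation_graph> %d nodes, %d edges, source node %d\n",
    n_nodes(x), n_edges(x), x$source
  ))
  w <- x$edges$width
  if (n_edges(x) > 0 && !anyNA(w)) {
    cat(sprintf(
      "  widths: mean %.4g, range [%.4g, %.4g], %d zero\n",
      mean(w), min(w), max(w), sum(w == 0)
    ))
  }
  if (!anyNA(x$nodes$area)) {
    cat(sprintf("  drainage areas: total %.6g\n", sum(x$nodes$area)))
  }
  invisible(x)
}

#' Basic accessors for venation graphs
#'
#' `n_nodes()`/`n_edges()` count nodes and edges; `edge_lengths()`,
#' `edge_widths()` and `node_areas()` return the per-edge/per-node
#' attributes; `source_node()` returns the petiole index; `node_degrees()`
#' counts incident edges (optionally restricted to a subset of edges);
#' `cycle_rank()` returns the number of independent loops `E - N + C` of the
#' (sub)graph.
#'
#' @param graph a `venation_graph`.
#' @name graph-accessors
NULL

#' @rdname graph-accessors
#' @export
n_nodes <- function(graph) nrow(graph$nodes)

#' @rdname graph-accessors
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' @rdname graph-accessors
#' @export
edge_lengths <- function(graph) graph$edges$length

#' @rdname graph-accessors
#' @export
edge_widths <- function(graph) graph$edges$width

#' @rdname graph-accessors
#' @export
node_areas <- function(graph) graph$nodes$area

#' @rdname graph-accessors
#' @export
source_node <- function(graph) graph$source

#' @rdname graph-accessors
#' @param edges optional integer/logical index of edges to count.
#' @export
node_degrees <- function(graph, edges = NULL) {
  e <- graph$edges
  if (!is.null(edges)) e <- e[edges, , drop = FALSE]
  tabulate(c(e$tail, e$head), nbins = n_nodes(graph))
}

#' @rdname graph-accessors
#' @export
cycle_rank <- function(graph, edges = NULL) {
  e <- graph$edges
  if (!is.null(edges)) e <- e[edges, , drop = FALSE]
  touched <- sort(unique(c(e$tail, e$head)))
  if (length(touched) == 0L) return(0L)
  idx <- match(c(e$tail, e$head), touched)
  m <- length(e$tail)
  ig <- igraph::graph_from_edgelist(cbind(idx[seq_len(m)], idx[m + seq_len(m)]),
                                    directed = FALSE)
  ncomp <- igraph::count_components(ig)
  as.integer(m - length(touched) + ncomp)
}

#' Convert to an igraph object
#'
#' Returns an undirected `igraph` graph with node attributes `x`, `y`,
#' `area` and edge attributes `length`, `width`, `conductivity`. Useful for
#' plotting and for standard graph algorithms.
#'
#' @param graph a `venation_graph`.
#' @return an `igraph` object.
#' @export
as_igraph <- function(graph) {
  ig <- igraph::graph_from_edgelist(
    cbind(graph$edges$tail, graph$edges$head),
    directed = FALSE
  )
  if (igraph::vcount(ig) < n_nodes(graph)) {
    ig <- igraph::add_vertices(ig, n_nodes(graph) - igraph::vcount(ig))
  }
  igraph::V(ig)$name <- graph$node_ids
  igraph::V(ig)$x <- graph$nodes$x
  igraph::V(ig)$y <- graph$nodes$y
  igraph::V(ig)$area <- graph$nodes$area
  igraph::E(ig)$length <- graph$edges$length
  igraph::E(ig)$width <- graph$edges$width
  igraph::E(ig)$conductivity <- graph$edges$conductivity
  ig
}

# internal: replace widths, keeping the rest of the graph
set_widths <- function(graph, w) {
  stopifnot(length(w) == n_edges(graph))
  graph$edges$width <- as.numeric(w)
  graph
}

# internal: euclidean edge lengths from node coordinates
geom_edge_lengths <- function(nodes, tail, head) {
  sqrt((nodes$x[tail] - nodes$x[head])^2 + (nodes$y[tail] - nodes$y[head])^2)
}
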