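#' Drainage areas by boundary-clipped Voronoi tessellation
#'
#' Assigns to each node the area of its Voronoi (Dirichlet) cell clipped to
#' the leaf boundary. The areas partition the lamina: they are non-negative
#' and sum to the boundary polygon's area. The boundary may be supplied as
#' a polygon, or derived from the node cloud (`"alpha"`: alpha shape with
#' automatic alpha, falling back to the convex hull; `"convex"`: convex
#' hull).
#'
#' @param graph a `venation_graph` with at least 3 non-collinear nodes.
#' @param boundary `"alpha"`, `"convex"`, or an `n x 2` matrix of polygon
#'   vertices (closed implicitly, either orientation).
#' @param alpha optional circumradius threshold passed to [alpha_shape()]
#'   when `boundary = "alpha"`.
#' @return the graph with the per-node `area` column filled.
#' @export
drainage_areas <- function(graph, boundary = "alpha", alpha = NULL) {
  x <- graph$nodes$x
  y <- graph$nodes$y
  if (n_nodes(graph) < 3L) stop("need at least 3 nodes")
  poly <- if (is.character(boundary)) {
    switch(match.arg(boundary, c("alpha", "convex")),
      alpha = tryCatch(alpha_shape(cbind(x, y), alpha = alpha),
                       error = function(e) convex_boundary(x, y)),
      convex = convex_boundary(x, y)
    )
  } else {
    as.matrix(boundary)
  }
  areas <- clipped_voronoi_areas(x, y, poly)
  graph$nodes$area <- areas
  graph
}

# convex hull polygon, inflated marginally about its centroid so that the
# hull vertices (which are nodes) lie strictly inside the window
convex_boundary <- function(x, y, inflate = 1e-9) {
  h <- grDevices::chull(x, y)  # clockwise
  px <- x[h]
  py <- y[h]
  cx <- mean(px)
  cy <- mean(py)
  cbind(cx + (px - cx) * (1 + inflate), cy + (py - cy) * (1 + inflate))
}

# internal: Dirichlet tessellation clipped to a polygon window
clipped_voronoi_areas <- function(x, y, poly) {
  poly <- poly[!duplicated(round(poly, 12)), , drop = FALSE]
  if (nrow(poly) < 3L) stop("degenerate boundary polygon")
  # owin requires anticlockwise vertex order
  if (polygon_area_signed(poly[, 1], poly[, 2]) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  # nodes on the boundary (e.g. hull vertices) are rescued by a marginal
  # inflation of the window about its centroid
  for (inflate in c(0, 1e-9, 1e-7)) {
    px <- mean(poly[, 1]) + (poly[, 1] - mean(poly[, 1])) * (1 + inflate)
    py <- mean(poly[, 2]) + (poly[, 2] - mean(poly[, 2])) * (1 + inflate)
    W <- spatstat.geom::owin(poly = list(x = px, y = py))
    inside <- suppressWarnings(spatstat.geom::inside.owin(x, y, W))
    if (all(inside)) break
  }
  if (!all(inside)) {
    stop(sum(!inside), " node(s) fall outside the boundary polygon")
  }
  if (anyDuplicated(cbind(x, y))) stop("duplicate node coordinates")
  X <- spatstat.geom::ppp(x, y, window = W)
  if (X$n == 1L) return(spatstat.geom::area.owin(W))
  dd <- spatstat.geom::dirichlet(X)
  areas <- spatstat.geom::tile.areas(dd)
  # dirichlet tiles are in point order but a tile can drop if degenerate
  if (length(areas) != length(x)) {
    idx <- as.integer(sub("Tile ", "", names(dd$tiles)))
    full <- numeric(length(x))
    full[idx] <- areas
    areas <- full
  }
  tot <- spatstat.geom::area.owin(W)
  if (abs(sum(areas) - tot) > 1e-6 * tot) {
    stop("Voronoi areas do not partition the boundary (sum ", sum(areas),
         " vs polygon area ", tot, ")")
  }
  unname(areas)
}

polygon_area_signed <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Alpha shape of a point cloud
#'
#' Concave boundary of a node set, built from the Delaunay triangulation:
#' triangles with circumradius at most `alpha` are kept and the boundary is
#' the set of edges belonging to exactly one kept triangle. When `alpha` is
#' `NULL` it is chosen automatically as the smallest circumradius threshold
#' for which the kept triangles form a single region whose boundary is one
#' simple closed polygon containing at least 99% of the points; if no such
#' threshold exists the convex hull is returned.
#'
#' @param xy an `n x 2` matrix of point coordinates.
#' @param alpha circumradius threshold (same length units as `xy`), or
#'   `NULL` for automatic selection.
#' @return a polygon as an `m x 2` matrix (anticlockwise, not closed).
#' @export
alpha_shape <- function(xy, alpha = NULL) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3)
  dt <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
  tri <- deldir::triMat(dt)
  cr <- circumradii(xy, tri)
  cand <- if (is.null(alpha)) sort(unique(cr)) else alpha
  for (r0 in cand) {
    keep <- which(cr <= r0)
    if (length(keep) == 0L) next
    res <- boundary_of_triangles(xy, tri[keep, , drop = FALSE])
    if (is.null(res)) next
    covered <- length(unique(as.vector(tri[keep, ]))) / nrow(xy)
    if (covered >= 0.99) return(res)
  }
  if (!is.null(alpha)) stop("no simple alpha-shape boundary at alpha = ", alpha)
  convex_boundary(xy[, 1], xy[, 2], inflate = 0)
}

circumradii <- function(xy, tri) {
  a <- xy[tri[, 1], , drop = FALSE]
  b <- xy[tri[, 2], , drop = FALSE]
  cc <- xy[tri[, 3], , drop = FALSE]
  la <- sqrt(rowSums((b - cc)^2))
  lb <- sqrt(rowSums((a - cc)^2))
  lc <- sqrt(rowSums((a - b)^2))
  ar <- abs((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
              (cc[, 1] - a[, 1]) * (b[, 2] - a[, 2])) / 2
  r <- la * lb * lc / (4 * pmax(ar, .Machine$double.xmin))
  r[ar == 0] <- Inf
  r
}

# boundary edges (in exactly one triangle) assembled into one simple closed
# polygon; NULL when the boundary is not a single simple cycle
boundary_of_triangles <- function(xy, tri) {
  if (nrow(tri) == 0L) return(NULL)
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1]
  if (length(bkey) < 3L) return(NULL)
  bed <- do.call(rbind, strsplit(bkey, " "))
  bed <- matrix(as.integer(bed), ncol = 2)
  verts <- sort(unique(as.vector(bed)))
  deg <- table(factor(as.vector(bed), levels = verts))
  if (any(deg != 2)) return(NULL)
  # follow the single cycle
  adj <- split(c(bed[, 2], bed[, 1]), factor(c(bed[, 1], bed[, 2]), levels = verts))
  path <- integer(length(verts))
  path[1] <- verts[1]
  prev <- 0L
  for (i in 2:length(verts)) {
    nb <- adj[[as.character(path[i - 1])]]
    nxt <- nb[nb != prev][1]
    if (is.na(nxt)) return(NULL)
    prev <- path[i - 1]
    path[i] <- nxt
  }
  nb <- adj[[as.character(path[length(verts)])]]
  if (!(path[1] %in% nb)) return(NULL)  # not a single closed cycle
  poly <- xy[path, , drop = FALSE]
  if (polygon_area_signed(poly[, 1], poly[, 2]) < 0) {
    poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  }
  poly
}
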