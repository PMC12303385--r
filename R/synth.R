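#' Leaf shape specification for the synthetic generator
#'
#' Parametric lamina used by [generate_leaf_lattice()]: an elliptic leaf of
#' total length `length` (x direction) and total width `width`
#' (y direction), with the petiole at the base `(-length/2, 0)`. The lattice
#' spacing `spacing` sets the node density; `jitter` (a fraction of the
#' spacing) perturbs node positions to emulate the non-uniform node
#' placement of image-extracted networks; `perturb` is the relative
#' amplitude of the multiplicative uniform perturbation of the initial edge
#' widths around `width0`.
#'
#' @param length,width total extent of the elliptic lamina [length units].
#' @param spacing triangular lattice spacing `h`.
#' @param jitter positional jitter amplitude as a fraction of `h`.
#' @param width0 mean initial edge width.
#' @param perturb relative width perturbation amplitude.
#' @param seed RNG seed; all generated output is a pure function of the
#'   shape parameters and this seed.
#' @return a list of class `leaf_shape`.
#' @export
leaf_shape <- function(length = 2, width = 1, spacing = 0.08,
                       jitter = 0.2, width0 = 1, perturb = 0.01, seed = 0L) {
  stopifnot(length > 0, width > 0, spacing > 0, jitter >= 0,
            width0 > 0, perturb >= 0)
  structure(list(length = length, width = width, spacing = spacing,
                 jitter = jitter, width0 = width0, perturb = perturb,
                 seed = as.integer(seed)),
            class = "leaf_shape")
}

#' Boundary polygon of a leaf shape
#'
#' @param shape a [leaf_shape()].
#' @param n number of polygon vertices.
#' @return an `n x 2` matrix (anticlockwise).
#' @export
leaf_boundary <- function(shape, n = 128L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(shape$length / 2 * cos(th), shape$width / 2 * sin(th))
}

#' Generate a synthetic leaf lattice
#'
#' Builds a jittered triangular lattice clipped to the leaf boundary — a
#' loopy planar graph that emulates image-extracted venation networks — and
#' appends a petiole source node at the leaf base, connected to its three
#' nearest lattice nodes. Edge lengths are Euclidean distances; initial
#' widths are `width0 * (1 + perturb * u)` with `u ~ Uniform(-1, 1)` (small
#' perturbations around a uniform width, from which the optimizer selects a
#' local optimum). Drainage areas are filled by [drainage_areas()] against
#' the known boundary. The output is byte-identical across runs with the
#' same shape (including its seed).
#'
#' @param shape a [leaf_shape()].
#' @return a `venation_graph`; the source node (petiole) is the last node.
#' @export
generate_leaf_lattice <- function(shape) {
  h <- shape$spacing
  L <- shape$length
  W <- shape$width
  boundary <- leaf_boundary(shape)
  Wowin <- spatstat.geom::owin(poly = list(x = boundary[, 1], y = boundary[, 2]))
  # triangular lattice covering the bounding box
  rows <- seq(floor(-W / 2 / (h * sqrt(3) / 2)) - 1L,
              ceiling(W / 2 / (h * sqrt(3) / 2)) + 1L)
  cols <- seq(floor(-L / 2 / h) - 1L, ceiling(L / 2 / h) + 1L)
  grid <- expand.grid(col = cols, row = rows)
  gx <- (grid$col + (grid$row %% 2) / 2) * h
  gy <- grid$row * h * sqrt(3) / 2
  with_seed(shape$seed, {
    # jitter, rejecting displacements that leave the lamina
    jx <- gx + stats::runif(length(gx), -shape$jitter * h, shape$jitter * h)
    jy <- gy + stats::runif(length(gy), -shape$jitter * h, shape$jitter * h)
    keep0 <- suppressWarnings(spatstat.geom::inside.owin(gx, gy, Wowin))
    jin <- suppressWarnings(spatstat.geom::inside.owin(jx, jy, Wowin))
    x <- ifelse(jin, jx, gx)
    y <- ifelse(jin, jy, gy)
    keep <- keep0 & suppressWarnings(spatstat.geom::inside.owin(x, y, Wowin))
    if (sum(keep) < 20L) stop("lattice spacing too coarse for this leaf shape")
    x <- x[keep]
    y <- y[keep]
    # lattice adjacency: same-row neighbor and the two lower-row neighbors
    key <- function(r, co) paste(r, co)
    pos <- new.env(hash = TRUE, size = length(gx))
    kk <- key(grid$row[keep], grid$col[keep])
    for (i in seq_along(kk)) assign(kk[i], i, envir = pos)
    lookup <- function(r, co) {
      v <- mget(key(r, co), envir = pos, ifnotfound = list(NA_integer_))
      unlist(v, use.names = FALSE)
    }
    r <- grid$row[keep]
    co <- grid$col[keep]
    nb_right <- lookup(r, co + 1L)
    nb_down1 <- lookup(r + 1L, co)
    nb_down2 <- lookup(r + 1L, co + ifelse(r %% 2 == 0, -1L, 1L))
    tail <- rep(seq_along(x), 3L)
    head <- c(nb_right, nb_down1, nb_down2)
    ok <- !is.na(head)
    tail <- tail[ok]
    head <- head[ok]
    # petiole appended at the base, pulled inside the lamina (offset chosen
    # off the lattice so it cannot coincide with a lattice node)
    px <- -L / 2 + 0.4 * h
    py <- 0
    d2 <- (x - px)^2 + (y - py)^2
    near <- order(d2)[1:3]
    x <- c(x, px)
    y <- c(y, py)
    pet <- length(x)
    tail <- c(tail, rep(pet, 3L))
    head <- c(head, near)
    nodes <- data.frame(x = x, y = y)
    lens <- geom_edge_lengths(nodes, tail, head)
    widths <- shape$width0 * (1 + shape$perturb * stats::runif(length(tail), -1, 1))
    # restrict to the connected component containing the petiole
    ig <- igraph::graph_from_edgelist(cbind(tail, head), directed = FALSE)
    comp <- igraph::components(ig)$membership
    keep_n <- comp == comp[pet]
    new_id <- cumsum(keep_n)
    keep_e <- keep_n[tail] & keep_n[head]
    g <- venation_graph(
      nodes = nodes[keep_n, , drop = FALSE],
      edges = data.frame(tail = new_id[tail[keep_e]], head = new_id[head[keep_e]],
                         length = lens[keep_e], width = widths[keep_e]),
      source = new_id[pet]
    )
    drainage_areas(g, boundary = boundary)
  })
}

#' Pseudo-data widths from a known generating amplitude
#'
#' Produces a synthetic "observed" leaf for parameter-recovery experiments:
#' the model itself is run at a known amplitude `sigma_true` (and exponent
#' `gamma`) from the lattice's perturbed-uniform widths, the normalized
#' output widths receive multiplicative lognormal noise of standard
#' deviation `noise_sd` (on the log scale), and widths are floored at
#' `1e-3` of the mean width so that — like real extracted networks — the
#' pseudo-data contain no zero-width edges.
#'
#' @param shape a [leaf_shape()].
#' @param sigma_true generating sink fluctuation amplitude.
#' @param gamma material-cost exponent.
#' @param noise_sd lognormal noise standard deviation (0 for none).
#' @param seed RNG seed for the noise.
#' @param config optional [optimizer_config()] for the generating run.
#' @return a `venation_graph` whose `width` column holds the pseudo-data
#'   widths; attribute `"sigma_true"` records the generating amplitude.
#' @export
make_pseudo_data <- function(shape, sigma_true, gamma = 0.5, noise_sd = 0,
                             seed = 1L, config = NULL) {
  g <- generate_leaf_lattice(shape)
  if (is.null(config)) config <- optimizer_config()
  config$sigma <- sigma_true
  config$gamma <- gamma
  fit <- optimize_conductivities(g, config)
  w <- fit$widths_model
  if (noise_sd > 0) {
    w <- with_seed(seed, w * exp(stats::rnorm(length(w), 0, noise_sd)))
  }
  w <- pmax(w, 1e-3 * mean(w))
  out <- set_widths(g, w)
  attr(out, "sigma_true") <- sigma_true
  out
}

#' Rasterize a venation graph to a binary mask
#'
#' Draws every positive-width edge as a stroke of its width (with round
#' caps) on a pixel grid, producing a mask suitable for the extraction
#' pipeline round trip. Pixel `(row, col)` maps to coordinates
#' `x = origin_x + (col - 0.5) / px_per_unit`,
#' `y = origin_y + (row - 0.5) / px_per_unit`; the mapping is stored in the
#' attributes `origin` and `px_per_unit`.
#'
#' @param graph a `venation_graph` with positive widths.
#' @param px_per_unit raster resolution [pixels per length unit].
#' @param pad margin around the drawing, in length units (default: half the
#'   largest width plus two pixels).
#' @return a logical matrix (rows = y, cols = x) with attributes `origin`
#'   and `px_per_unit`.
#' @export
render_mask <- function(graph, px_per_unit, pad = NULL) {
  w <- edge_widths(graph)
  if (all(w <= 0)) stop("no positive-width edges to render")
  if (any(w[w > 0] * px_per_unit < 2)) {
    warning("some strokes are thinner than 2 px at this resolution")
  }
  if (is.null(pad)) pad <- max(w) / 2 + 2 / px_per_unit
  x <- graph$nodes$x
  y <- graph$nodes$y
  x0 <- min(x) - pad
  y0 <- min(y) - pad
  ncol_px <- ceiling((max(x) + pad - x0) * px_per_unit)
  nrow_px <- ceiling((max(y) + pad - y0) * px_per_unit)
  mask <- matrix(FALSE, nrow_px, ncol_px)
  tl <- graph$edges$tail
  hd <- graph$edges$head
  for (i in seq_len(n_edges(graph))) {
    if (w[i] <= 0) next
    ax <- x[tl[i]]; ay <- y[tl[i]]
    bx <- x[hd[i]]; by <- y[hd[i]]
    r <- w[i] / 2
    cmin <- max(1L, floor((min(ax, bx) - r - x0) * px_per_unit))
    cmax <- min(ncol_px, ceiling((max(ax, bx) + r - x0) * px_per_unit) + 1L)
    rmin <- max(1L, floor((min(ay, by) - r - y0) * px_per_unit))
    rmax <- min(nrow_px, ceiling((max(ay, by) + r - y0) * px_per_unit) + 1L)
    if (cmin > cmax || rmin > rmax) next
    pc <- cmin:cmax
    pr <- rmin:rmax
    pxx <- x0 + (pc - 0.5) / px_per_unit
    pyy <- y0 + (pr - 0.5) / px_per_unit
    gx <- matrix(pxx, length(pr), length(pc), byrow = TRUE)
    gy <- matrix(pyy, length(pr), length(pc))
    # distance from pixel centers to the segment
    vx <- bx - ax; vy <- by - ay
    vv <- vx^2 + vy^2
    t <- if (vv == 0) 0 else pmin(pmax(((gx - ax) * vx + (gy - ay) * vy) / vv, 0), 1)
    d2 <- (gx - (ax + t * vx))^2 + (gy - (ay + t * vy))^2
    hit <- d2 <= r^2
    mask[pr, pc] <- mask[pr, pc] | hit
  }
  attr(mask, "origin") <- c(x0, y0)
  attr(mask, "px_per_unit") <- px_per_unit
  mask
}

#' Read or write a binary mask image
#'
#' Masks are stored as single-channel PNG or TIFF images with foreground
#' (vein) pixels at intensity 1. Reading thresholds at 0.5.
#'
#' @param path image path (`.png` or `.tif`/`.tiff`).
#' @return `read_mask()` returns a logical matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
    tiff::readTIFF(path)
  } else {
    stop("unsupported mask format: ", ext)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' @rdname read_mask
#' @param mask a logical/binary matrix.
#' @export
write_mask <- function(mask, path) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
    tiff::writeTIFF(img, path)
  } else {
    stop("unsupported mask format: ", ext)
  }
  invisible(path)
}
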