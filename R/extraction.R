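#' Skeletonize a binary vein mask with local widths
#'
#' Thins the mask to a one-pixel-wide, 8-connected centerline by iterative
#' Guo-Hall thinning (a topology-preserving approximation of the medial
#' axis) and records the local full vein width at every skeleton pixel from
#' the Euclidean distance transform: `width = 2 * d - 1` pixels, where `d`
#' is the distance to the nearest background pixel (the `-1` corrects for
#' the half-pixel offset of pixel centers, so an axis-aligned bar of
#' thickness `k` px reports width exactly `k`).
#'
#' @param mask a binary/logical matrix (rows = y, cols = x) with vein
#'   pixels `TRUE`; must have a non-empty foreground.
#' @return an object of class `skeleton_image`: list with `skeleton`
#'   (logical matrix) and `width` (numeric matrix, `NA` off the skeleton).
#' @export
skeletonize_mask <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop("mask foreground is empty")
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  d <- matrix(as.numeric(d), nrow(mask), ncol(mask))
  skel <- thin_guohall(mask)
  w <- matrix(NA_real_, nrow(mask), ncol(mask))
  w[skel] <- pmax(2 * d[skel] - 1, 1)
  structure(list(skeleton = skel, width = w), class = "skeleton_image")
}

#' @export
print.skeleton_image <- function(x, ...) {
  cat(sprintf("<skeleton_image> %d x %d px, %d skeleton pixels\n",
              nrow(x$skeleton), ncol(x$skeleton), sum(x$skeleton)))
  invisible(x)
}

# shifted copy of a matrix (dr, dc), zero-filled at the border
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

neighbor_stack <- function(img) {
  # P2..P9 clockwise from north (row - 1)
  list(
    shift_mat(img, -1, 0), shift_mat(img, -1, 1), shift_mat(img, 0, 1),
    shift_mat(img, 1, 1), shift_mat(img, 1, 0), shift_mat(img, 1, -1),
    shift_mat(img, 0, -1), shift_mat(img, -1, -1)
  )
}

# vectorized Guo-Hall thinning (two-subiteration); preserves topology and
# yields cleaner one-pixel skeletons on thick oblique strokes than
# Zhang-Suen, which leaves staircase branch artifacts there
thin_guohall <- function(img) {
  img <- img > 0
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P <- neighbor_stack(img)
      p2 <- P[[1]]; p3 <- P[[2]]; p4 <- P[[3]]; p5 <- P[[4]]
      p6 <- P[[5]]; p7 <- P[[6]]; p8 <- P[[7]]; p9 <- P[[8]]
      C <- ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
        ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      m <- if (sub == 1) (p6 | p7 | (!p9)) & p8 else (p2 | p3 | (!p5)) & p4
      cond <- img & C == 1 & N >= 2 & N <= 3 & !m
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

#' Detect endpoints and branch points of a skeleton
#'
#' Endpoints are skeleton pixels with exactly one 8-connected skeleton
#' neighbor; branch-point candidates have three or more. Adjacent branch
#' pixels (as arise at wide junctions) are merged into a single node at
#' their centroid.
#'
#' @param skel a [skeletonize_mask()] result.
#' @return list with `endpoints` (`m x 2` matrix of (row, col)),
#'   `branchpoints` (data.frame `row`, `col` centroids, `n_pixels`), and
#'   `node_map` (integer matrix: 0 off nodes, otherwise the node id;
#'   endpoint ids come first).
#' @export
detect_skeleton_nodes <- function(skel) {
  img <- skel$skeleton
  P <- neighbor_stack(img)
  nb <- Reduce(`+`, P)
  ends <- which(img & nb == 1, arr.ind = TRUE)
  branch_px <- which(img & nb >= 3, arr.ind = TRUE)
  node_map <- matrix(0L, nrow(img), ncol(img))
  nid <- 0L
  if (nrow(ends) > 0) {
    for (i in seq_len(nrow(ends))) {
      nid <- nid + 1L
      node_map[ends[i, 1], ends[i, 2]] <- nid
    }
  }
  centroids <- NULL
  if (nrow(branch_px) > 0) {
    # merge 8-adjacent branch pixels into one node
    lab <- label_clusters(branch_px)
    for (l in sort(unique(lab))) {
      px <- branch_px[lab == l, , drop = FALSE]
      nid <- nid + 1L
      node_map[px] <- nid
      centroids <- rbind(centroids, c(mean(px[, 1]), mean(px[, 2]), nrow(px)))
    }
  }
  bp <- if (is.null(centroids)) {
    data.frame(row = numeric(0), col = numeric(0), n_pixels = integer(0))
  } else {
    data.frame(row = centroids[, 1], col = centroids[, 2],
               n_pixels = as.integer(centroids[, 3]))
  }
  list(endpoints = unname(ends), branchpoints = bp, node_map = node_map)
}

# 8-connected clustering of pixel coordinates
label_clusters <- function(px) {
  n <- nrow(px)
  if (n == 1L) return(1L)
  adj <- which(abs(outer(px[, 1], px[, 1], "-")) <= 1 &
                 abs(outer(px[, 2], px[, 2], "-")) <= 1, arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  ig <- igraph::graph_from_edgelist(adj, directed = FALSE)
  if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  as.integer(igraph::components(ig)$membership)
}

# 8-neighborhood offsets, deterministic order
.nb_off <- cbind(
  dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

#' Trace a venation graph from a skeleton
#'
#' Walks the skeleton between node pixels: each maximal chain of non-node
#' skeleton pixels joining two nodes becomes one edge, with length the sum
#' of step costs (1 per axis step, `sqrt(2)` per diagonal step) and width
#' the mean of the width raster along the chain. Isolated cycles that touch
#' no node are anchored by two synthetic nodes (splitting the cycle into
#' two edges). Node coordinates use `x = col`, `y = row`.
#'
#' @param skel a [skeletonize_mask()] result.
#' @param nodes a [detect_skeleton_nodes()] result (computed if missing).
#' @return a `venation_graph` (not yet pruned; the source defaults to node
#'   1 and should be set from the petiole location after pruning).
#' @export
trace_graph <- function(skel, nodes = detect_skeleton_nodes(skel)) {
  img <- skel$skeleton
  wras <- skel$width
  node_map <- nodes$node_map
  nr <- nrow(img)
  nc <- ncol(img)
  n_end <- nrow(nodes$endpoints)
  n_nodes0 <- n_end + nrow(nodes$branchpoints)
  # node coordinates (row, col)
  coords <- rbind(
    nodes$endpoints,
    as.matrix(nodes$branchpoints[, c("row", "col")])
  )
  coords <- matrix(as.numeric(coords), ncol = 2)
  node_width <- numeric(n_nodes0)
  for (id in seq_len(n_nodes0)) {
    px <- which(node_map == id, arr.ind = TRUE)
    node_width[id] <- mean(wras[px])
  }
  visited <- matrix(FALSE, nr, nc)
  edges <- list()
  add_edge <- function(a, b, len, wd) {
    edges[[length(edges) + 1L]] <<- c(a, b, len, wd)
  }
  nbrs <- function(r, c) {
    rr <- r + .nb_off[, 1]
    cc <- c + .nb_off[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    cbind(rr[ok], cc[ok])
  }
  step_len <- function(r1, c1, r2, c2) ifelse(abs(r1 - r2) + abs(c1 - c2) == 2, sqrt(2), 1)
  walk_chain <- function(pr, pc, qr, qc, a) {
    # from node pixel (pr,pc) of node a into chain pixel (qr,qc); returns
    # the end node id, total length and the chain pixels
    len <- step_len(pr, pc, qr, qc)
    chain_r <- qr
    chain_c <- qc
    prev_r <- pr; prev_c <- pc
    cur_r <- qr; cur_c <- qc
    repeat {
      visited[cur_r, cur_c] <<- TRUE
      nb <- nbrs(cur_r, cur_c)
      on_sk <- img[nb]
      nb <- nb[on_sk, , drop = FALSE]
      not_prev <- !(nb[, 1] == prev_r & nb[, 2] == prev_c)
      nb <- nb[not_prev, , drop = FALSE]
      if (nrow(nb) == 0L) return(NULL)  # dangling chain (shouldn't happen)
      ids <- node_map[nb]
      cont <- which(ids == 0L & !visited[nb])
      node_nb <- which(ids > 0L)
      if (length(node_nb)) {
        k <- node_nb[ids[node_nb] != a]
        if (length(k) == 0L) {
          # only our own start node: a genuine return (petal loop) if we
          # have walked a real chain, otherwise a junction-cluster artifact
          if (length(chain_r) >= 2L || length(cont) == 0L) {
            k <- node_nb[1]
          } else {
            k <- integer(0)
          }
        } else {
          k <- k[1]
        }
        if (length(k) == 1L) {
          len <- len + step_len(cur_r, cur_c, nb[k, 1], nb[k, 2])
          return(list(end = ids[k], len = len, rows = chain_r, cols = chain_c))
        }
      }
      if (length(cont) == 0L) return(NULL)
      k <- cont[1]
      len <- len + step_len(cur_r, cur_c, nb[k, 1], nb[k, 2])
      prev_r <- cur_r; prev_c <- cur_c
      cur_r <- nb[k, 1]; cur_c <- nb[k, 2]
      chain_r <- c(chain_r, cur_r)
      chain_c <- c(chain_c, cur_c)
    }
  }
  node_px <- which(node_map > 0L, arr.ind = TRUE)
  ord <- order(node_px[, 2], node_px[, 1])
  node_px <- node_px[ord, , drop = FALSE]
  seen_pairs <- character(0)
  n_nodes_tot <- n_nodes0
  for (i in seq_len(nrow(node_px))) {
    pr <- node_px[i, 1]
    pc <- node_px[i, 2]
    a <- node_map[pr, pc]
    nb <- nbrs(pr, pc)
    nb <- nb[img[nb], , drop = FALSE]
    for (j in seq_len(nrow(nb))) {
      qr <- nb[j, 1]
      qc <- nb[j, 2]
      qid <- node_map[qr, qc]
      if (qid > 0L) {
        # direct node-node adjacency (one edge per node pair)
        if (qid != a) {
          key <- paste(min(a, qid), max(a, qid))
          if (!(key %in% seen_pairs)) {
            seen_pairs <- c(seen_pairs, key)
            add_edge(a, qid, step_len(pr, pc, qr, qc),
                     mean(c(wras[pr, pc], wras[qr, qc])))
          }
        }
        next
      }
      if (visited[qr, qc]) next
      res <- walk_chain(pr, pc, qr, qc, a)
      if (is.null(res)) next
      chain_w <- chain_width(wras, res$rows, res$cols)
      if (res$end == a) {
        # petal loop back to its own node: split with an anchor node so the
        # loop is representable without a self-loop edge
        if (length(res$rows) < 3L) next
        mid <- ceiling(length(res$rows) / 2)
        n_nodes_tot <- n_nodes_tot + 1L
        node_map[res$rows[mid], res$cols[mid]] <- n_nodes_tot
        coords <- rbind(coords, c(res$rows[mid], res$cols[mid]))
        node_width <- c(node_width, wras[res$rows[mid], res$cols[mid]])
        h1 <- seq_len(mid)
        h2 <- seq(mid, length(res$rows))
        add_edge(a, n_nodes_tot, path_length(res$rows[h1], res$cols[h1]) + 1,
                 mean(wras[cbind(res$rows[h1], res$cols[h1])]))
        add_edge(n_nodes_tot, a, path_length(res$rows[h2], res$cols[h2]) + 1,
                 mean(wras[cbind(res$rows[h2], res$cols[h2])]))
        next
      }
      add_edge(a, res$end, res$len, chain_w)
    }
  }
  # isolated cycles: skeleton pixels never visited and not node pixels
  repeat {
    left <- which(img & !visited & node_map == 0L, arr.ind = TRUE)
    if (nrow(left) > 0L && n_nodes0 > 0L) {
      # drop pixels adjacent to nodes (chain starts already consumed)
      touch <- vapply(seq_len(nrow(left)), function(i) {
        nb <- nbrs(left[i, 1], left[i, 2])
        any(node_map[nb] > 0L)
      }, logical(1))
      left <- left[!touch, , drop = FALSE]
    }
    if (nrow(left) == 0L) break
    # anchor the cycle at its first pixel
    ar <- left[1, 1]
    ac <- left[1, 2]
    n_nodes_tot <- n_nodes_tot + 1L
    anchor <- n_nodes_tot
    node_map[ar, ac] <- anchor
    coords <- rbind(coords, c(ar, ac))
    node_width <- c(node_width, wras[ar, ac])
    visited[ar, ac] <- TRUE
    nb <- nbrs(ar, ac)
    nb <- nb[img[nb] & node_map[nb] == 0L & !visited[nb], , drop = FALSE]
    if (nrow(nb) == 0L) next  # single-pixel speck
    res <- walk_chain(ar, ac, nb[1, 1], nb[1, 2], anchor)
    if (is.null(res)) next
    if (res$end == anchor && length(res$rows) >= 2L) {
      # split the cycle with a second anchor at the chain midpoint
      mid <- ceiling(length(res$rows) / 2)
      n_nodes_tot <- n_nodes_tot + 1L
      node_map[res$rows[mid], res$cols[mid]] <- n_nodes_tot
      coords <- rbind(coords, c(res$rows[mid], res$cols[mid]))
      node_width <- c(node_width, wras[res$rows[mid], res$cols[mid]])
      h1 <- seq_len(mid)
      h2 <- seq(mid, length(res$rows))
      l1 <- path_length(res$rows[h1], res$cols[h1]) + 1
      l2 <- path_length(res$rows[h2], res$cols[h2]) + 1
      add_edge(anchor, n_nodes_tot, l1, mean(wras[cbind(res$rows[h1], res$cols[h1])]))
      add_edge(n_nodes_tot, anchor, l2, mean(wras[cbind(res$rows[h2], res$cols[h2])]))
    } else if (res$end != anchor) {
      add_edge(anchor, res$end, res$len, mean(wras[cbind(res$rows, res$cols)]))
    }
  }
  if (length(edges) == 0L) stop("no edges traced from skeleton")
  em <- do.call(rbind, edges)
  venation_graph(
    nodes = data.frame(x = coords[, 2], y = coords[, 1]),
    edges = data.frame(tail = as.integer(em[, 1]), head = as.integer(em[, 2]),
                       length = em[, 3], width = em[, 4]),
    source = 1L, validate = FALSE
  )
}

path_length <- function(rows, cols) {
  if (length(rows) < 2L) return(0)
  sum(ifelse(abs(diff(rows)) + abs(diff(cols)) == 2, sqrt(2), 1))
}

# width along a chain: trim half a vein width of pixels at each end (where
# the distance transform is inflated by the adjoining junctions), then take
# a high quantile of the remaining per-pixel widths. On oblique strokes the
# thinned centerline wanders up to half a pixel off the true medial axis,
# which biases the per-pixel estimate low everywhere except where the
# skeleton crosses the axis; the upper quantile reads those crossings.
chain_width <- function(wras, rows, cols) {
  w <- wras[cbind(rows, cols)]
  n <- length(w)
  k <- ceiling(stats::median(w) / 2)
  if (n > 2L * k + 1L) {
    unname(stats::quantile(w[(k + 1L):(n - k)], 0.9, names = FALSE))
  } else {
    # chain shorter than the junction-inflated zones: the minimum is the
    # closest reading to the true width
    min(w)
  }
}

#' Prune a traced venation graph
#'
#' Three clean-up passes, iterated to a fixed point (pruning is
#' idempotent): (1) nodes closer than `merge_radius` are merged at their
#' mean position (edges collapsing onto a single node are dropped);
#' (2) degree-1 edges shorter than `spur_length` (thinning artifacts at
#' junctions) are removed; (3) every degree-2 node is removed by
#' concatenating its two edges, with length the sum and width the
#' length-weighted mean of the two. Parallel edges between two nodes are
#' legitimate (they are loops) and kept; a degree-2 node whose both edges
#' lead to the same neighbor is kept as the anchor of that loop.
#'
#' @param graph a traced `venation_graph`.
#' @param merge_radius node-merge radius (same units as coordinates).
#' @param merge_width_factor contract edges shorter than this multiple of
#'   their own width by merging their endpoints: thinning fragments a wide
#'   junction into several branch points joined by stubs on the scale of
#'   the stroke width, and no genuine vein segment is shorter than its own
#'   width. 0 disables stub contraction.
#' @param spur_length maximum length of removed degree-1 spurs (0 disables
#'   spur removal).
#' @param keep node indices exempt from degree-2 removal.
#' @return the pruned `venation_graph`.
#' @export
prune_graph <- function(graph, merge_radius = 3, merge_width_factor = 2,
                        spur_length = 0, keep = integer(0)) {
  nodes <- graph$nodes
  edges <- graph$edges
  keep_ids <- graph$node_ids[keep]
  node_ids <- graph$node_ids
  repeat {
    changed <- FALSE
    n <- nrow(nodes)
    # --- merge close nodes and contract junction stubs
    if ((merge_radius > 0 || merge_width_factor > 0) && n > 1L) {
      d <- as.matrix(stats::dist(nodes[, c("x", "y")]))
      close <- which(d < merge_radius & upper.tri(d), arr.ind = TRUE)
      if (merge_width_factor > 0 && nrow(edges) > 0L) {
        stub <- edges$length < merge_width_factor * edges$width &
          edges$tail != edges$head
        if (any(stub)) {
          close <- rbind(close, unname(cbind(edges$tail[stub], edges$head[stub])))
        }
      }
      if (nrow(close) > 0L) {
        ig <- igraph::graph_from_edgelist(close, directed = FALSE)
        if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
        grp <- igraph::components(ig)$membership
        nodes <- data.frame(
          x = as.vector(tapply(nodes$x, grp, mean)),
          y = as.vector(tapply(nodes$y, grp, mean)),
          area = as.vector(tapply(nodes$area, grp, mean))
        )
        node_ids <- as.character(tapply(node_ids, grp, function(s) s[1]))
        edges$tail <- grp[edges$tail]
        edges$head <- grp[edges$head]
        drop <- edges$tail == edges$head
        if (any(drop)) edges <- edges[!drop, , drop = FALSE]
        changed <- changed || any(duplicated(grp)) || any(drop)
      }
    }
    # --- remove short spurs
    if (spur_length > 0 && nrow(edges) > 1L) {
      deg <- tabulate(c(edges$tail, edges$head), nbins = nrow(nodes))
      spur <- (deg[edges$tail] == 1L | deg[edges$head] == 1L) &
        edges$length < spur_length
      if (any(spur)) {
        edges <- edges[!spur, , drop = FALSE]
        changed <- TRUE
      }
    }
    # --- contract degree-2 nodes
    repeat {
      deg <- tabulate(c(edges$tail, edges$head), nbins = nrow(nodes))
      protected <- node_ids %in% keep_ids
      cand <- which(deg == 2L & !protected)
      done <- TRUE
      for (v in cand) {
        inc <- which(edges$tail == v | edges$head == v)
        if (length(inc) != 2L) next
        e1 <- edges[inc[1], ]
        e2 <- edges[inc[2], ]
        u1 <- if (e1$tail == v) e1$head else e1$tail
        u2 <- if (e2$tail == v) e2$head else e2$tail
        if (u1 == u2) next  # petal loop: keep v as its anchor
        len <- e1$length + e2$length
        wd <- (e1$length * e1$width + e2$length * e2$width) / len
        edges <- edges[-inc, , drop = FALSE]
        edges <- rbind(edges, data.frame(tail = u1, head = u2, length = len,
                                         width = wd, conductivity = NA_real_))
        changed <- TRUE
        done <- FALSE
        break
      }
      if (done) break
    }
    if (!changed) break
  }
  # drop isolated nodes
  deg <- tabulate(c(edges$tail, edges$head), nbins = nrow(nodes))
  live <- deg > 0L
  if (nrow(nodes) == 1L) live <- TRUE
  remap <- cumsum(live)
  nodes <- nodes[live, , drop = FALSE]
  node_ids <- node_ids[live]
  edges$tail <- remap[edges$tail]
  edges$head <- remap[edges$head]
  venation_graph(nodes, edges,
                 source = if (live[graph$source]) remap[graph$source] else 1L,
                 node_ids = node_ids, validate = FALSE)
}

#' Extract a venation graph from a binary mask
#'
#' Full pipeline: skeletonize with widths, detect endpoints and branch
#' points, trace edges, restrict to the connected component containing the
#' petiole (or the largest component), prune, designate the node nearest
#' the petiole coordinate as the source, and (optionally) fill drainage
#' areas.
#'
#' @param mask binary matrix (or a path readable by [read_mask()]).
#' @param petiole optional `c(x, y)` pixel coordinate of the petiole.
#' @param merge_radius node-merge radius in pixels (default 3).
#' @param merge_width_factor width-adaptive merge scale, see
#'   [prune_graph()].
#' @param spur_length degree-1 spurs shorter than this many pixels are
#'   removed (default 0: keep all endpoints).
#' @param boundary `NULL` (skip drainage areas), `"alpha"`, `"convex"`, or
#'   a polygon matrix, passed to [drainage_areas()].
#' @return a `venation_graph` in pixel units.
#' @export
extract_venation <- function(mask, petiole = NULL, merge_radius = 3,
                             merge_width_factor = 2, spur_length = 0,
                             boundary = NULL) {
  if (is.character(mask)) mask <- read_mask(mask)
  skel <- skeletonize_mask(mask)
  g <- trace_graph(skel)
  # component selection
  ig <- igraph::graph_from_edgelist(cbind(g$edges$tail, g$edges$head),
                                    directed = FALSE)
  if (igraph::vcount(ig) < n_nodes(g)) {
    ig <- igraph::add_vertices(ig, n_nodes(g) - igraph::vcount(ig))
  }
  comp <- igraph::components(ig)
  pick <- if (!is.null(petiole)) {
    d2 <- (g$nodes$x - petiole[1])^2 + (g$nodes$y - petiole[2])^2
    comp$membership[which.min(d2)]
  } else {
    which.max(comp$csize)
  }
  if (comp$no > 1L) {
    keep_n <- comp$membership == pick
    remap <- cumsum(keep_n)
    keep_e <- keep_n[g$edges$tail] & keep_n[g$edges$head]
    g <- venation_graph(
      g$nodes[keep_n, , drop = FALSE],
      data.frame(tail = remap[g$edges$tail[keep_e]],
                 head = remap[g$edges$head[keep_e]],
                 length = g$edges$length[keep_e],
                 width = g$edges$width[keep_e]),
      source = 1L, node_ids = g$node_ids[keep_n], validate = FALSE
    )
  }
  g <- prune_graph(g, merge_radius = merge_radius,
                   merge_width_factor = merge_width_factor,
                   spur_length = spur_length)
  if (!is.null(petiole)) {
    d2 <- (g$nodes$x - petiole[1])^2 + (g$nodes$y - petiole[2])^2
    g$source <- which.min(d2)
  }
  if (!is.null(boundary)) g <- drainage_areas(g, boundary)
  g
}
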