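#' Read and write venation graphs
#'
#' Three on-disk formats are supported:
#'
#' * `"csv"` — a directory holding `nodes.csv` (`id,x,y[,area][,is_source]`)
#'   and `edges.csv` (`id,tail,head,length,width[,conductivity]`), with
#'   `tail`/`head` referring to node `id`s;
#' * `"json"` — a single file with `nodes`, `edges` and `source` members
#'   carrying the same fields;
#' * `"graphml"` — GraphML with node/edge attributes as data keys (via
#'   igraph); the source is stored in the node attribute `is_source`.
#'
#' A save/load round trip reproduces node and edge tables (within decimal
#' text precision for `"csv"`) with stable edge ordering. External ids may
#' be arbitrary strings; internally nodes and edges are dense integer
#' indices.
#'
#' @param path file (json/graphml) or directory (csv) to read or write.
#' @param format one of `"auto"`, `"csv"`, `"json"`, `"graphml"`. `"auto"`
#'   picks by extension (directory => csv).
#' @param graph a `venation_graph`.
#' @return `read_venation()` returns a `venation_graph`; `write_venation()`
#'   returns `path` invisibly.
#' @export
read_venation <- function(path, format = "auto") {
  format <- resolve_format(path, format)
  switch(format,
    csv = read_venation_csv(path),
    json = read_venation_json(path),
    graphml = read_venation_graphml(path),
    stop("unknown format: ", format)
  )
}

#' @rdname read_venation
#' @export
write_venation <- function(graph, path, format = "auto") {
  format <- resolve_format(path, format)
  switch(format,
    csv = write_venation_csv(graph, path),
    json = write_venation_json(graph, path),
    graphml = write_venation_graphml(graph, path),
    stop("unknown format: ", format)
  )
  invisible(path)
}

resolve_format <- function(path, format) {
  format <- match.arg(format, c("auto", "csv", "json", "graphml"))
  if (format != "auto") return(format)
  if (dir.exists(path) || !grepl("\\.", basename(path))) return("csv")
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    json = "json",
    graphml = "graphml",
    csv = "csv",
    stop("cannot infer graph format from path: ", path)
  )
}

graph_from_tables <- function(nodes, edges, source_id, where) {
  need_n <- c("id", "x", "y")
  if (!all(need_n %in% names(nodes))) {
    stop(where, ": nodes table is missing column(s) ",
         paste(setdiff(need_n, names(nodes)), collapse = ", "))
  }
  need_e <- c("id", "tail", "head", "length", "width")
  if (!all(need_e %in% names(edges))) {
    stop(where, ": edges table is missing column(s) ",
         paste(setdiff(need_e, names(edges)), collapse = ", "))
  }
  node_ids <- as.character(nodes$id)
  if (anyDuplicated(node_ids)) {
    stop(where, ": duplicate node id '", node_ids[duplicated(node_ids)][1], "'")
  }
  edge_ids <- as.character(edges$id)
  tl <- match(as.character(edges$tail), node_ids)
  hd <- match(as.character(edges$head), node_ids)
  if (anyNA(tl) || anyNA(hd)) {
    bad <- which(is.na(tl) | is.na(hd))[1]
    stop(where, ": edge record ", bad, " references unknown node")
  }
  src <- match(as.character(source_id), node_ids)
  if (is.na(src)) stop(where, ": source id '", source_id, "' not among node ids")
  venation_graph(
    nodes = data.frame(x = as.numeric(nodes$x), y = as.numeric(nodes$y),
                       area = if (is.null(nodes$area)) NA_real_ else as.numeric(nodes$area)),
    edges = data.frame(tail = tl, head = hd,
                       length = as.numeric(edges$length),
                       width = as.numeric(edges$width),
                       conductivity = if (is.null(edges$conductivity)) NA_real_
                                      else as.numeric(edges$conductivity)),
    source = src, node_ids = node_ids, edge_ids = edge_ids
  )
}

node_table <- function(graph) {
  data.frame(
    id = graph$node_ids,
    x = graph$nodes$x, y = graph$nodes$y, area = graph$nodes$area,
    is_source = seq_len(n_nodes(graph)) == graph$source
  )
}

edge_table <- function(graph) {
  data.frame(
    id = graph$edge_ids,
    tail = graph$node_ids[graph$edges$tail],
    head = graph$node_ids[graph$edges$head],
    length = graph$edges$length,
    width = graph$edges$width,
    conductivity = graph$edges$conductivity
  )
}

read_venation_csv <- function(path) {
  nf <- file.path(path, "nodes.csv")
  ef <- file.path(path, "edges.csv")
  if (!file.exists(nf)) stop("missing ", nf)
  if (!file.exists(ef)) stop("missing ", ef)
  nodes <- utils::read.csv(nf, stringsAsFactors = FALSE)
  edges <- utils::read.csv(ef, stringsAsFactors = FALSE)
  if (is.null(nodes$is_source) || sum(nodes$is_source) != 1L) {
    stop("nodes.csv: exactly one node must have is_source = TRUE")
  }
  graph_from_tables(nodes, edges, nodes$id[as.logical(nodes$is_source)], "csv")
}

write_venation_csv <- function(graph, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(node_table(graph), file.path(path, "nodes.csv"), row.names = FALSE)
  utils::write.csv(edge_table(graph), file.path(path, "edges.csv"), row.names = FALSE)
}

read_venation_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("json parse error in ", path, ": ",
                                           conditionMessage(e)))
  for (m in c("nodes", "edges", "source")) {
    if (is.null(obj[[m]])) stop("json: missing member '", m, "'")
  }
  graph_from_tables(as.data.frame(obj$nodes), as.data.frame(obj$edges),
                    obj$source, "json")
}

write_venation_json <- function(graph, path) {
  nt <- node_table(graph)
  nt$is_source <- NULL
  obj <- list(nodes = nt, edges = edge_table(graph),
              source = graph$node_ids[graph$source])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
}

read_venation_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(ig)
  ea <- igraph::edge_attr(ig)
  el <- igraph::as_edgelist(ig, names = FALSE)
  nodes <- data.frame(id = va$name, x = va$x, y = va$y,
                      area = if (is.null(va$area)) NA_real_ else va$area)
  edges <- data.frame(id = if (is.null(ea$id)) as.character(seq_len(nrow(el))) else ea$id,
                      tail = va$name[el[, 1]], head = va$name[el[, 2]],
                      length = ea$length, width = ea$width,
                      conductivity = if (is.null(ea$conductivity)) NA_real_ else ea$conductivity)
  if (is.null(va$is_source) || sum(va$is_source) != 1) {
    stop("graphml: exactly one node must have is_source = 1")
  }
  graph_from_tables(nodes, edges, va$name[va$is_source > 0], "graphml")
}

write_venation_graphml <- function(graph, path) {
  ig <- as_igraph(graph)
  igraph::V(ig)$is_source <- as.integer(seq_len(n_nodes(graph)) == graph$source)
  igraph::E(ig)$id <- graph$edge_ids
  igraph::write_graph(ig, path, format = "graphml")
}
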