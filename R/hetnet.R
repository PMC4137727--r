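#' Typed heterogeneous graphs
#'
#' A `typed_graph` is an undirected simple graph whose nodes carry one of the
#' three entity types and whose edges partition into the six layers by
#' endpoint type. It is stored as two tibbles: `nodes` (`id`, `type`) and
#' `edges` (`a`, `b`, `layer`) with each pair in canonical order
#' (`a < b` lexicographically).
#'
#' @param nodes tibble with columns `id`, `type`.
#' @param edges tibble with columns `a`, `b` (node ids); the layer is derived
#'   from the endpoint types.
#' @return A `typed_graph` object.
#' @export
typed_graph <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  nodes <- tibble::tibble(id = normalize_id(nodes$id), type = nodes$type)
  if (anyDuplicated(nodes$id)) {
    dup <- unique(nodes$id[duplicated(nodes$id)])
    conflict <- vapply(dup, function(d) {
      length(unique(nodes$type[nodes$id == d])) > 1
    }, logical(1))
    if (any(conflict)) {
      stop("conflicting type assignment for node(s): ",
           paste(dup[conflict], collapse = ", "), call. = FALSE)
    }
    nodes <- dplyr::distinct(nodes)
  }
  bad <- setdiff(nodes$type, entity_types())
  if (length(bad)) stop("unknown entity type(s): ", paste(bad, collapse = ", "))
  a <- normalize_id(edges$a); b <- normalize_id(edges$b)
  if (any(a == b)) stop("self-loop edge(s) not allowed", call. = FALSE)
  lo <- pmin(a, b); hi <- pmax(a, b)
  missing <- setdiff(unique(c(lo, hi)), nodes$id)
  if (length(missing)) {
    stop("edge endpoint(s) missing from node table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ta <- nodes$type[match(lo, nodes$id)]
  tb <- nodes$type[match(hi, nodes$id)]
  e <- tibble::tibble(a = lo, b = hi, layer = layer_name(ta, tb))
  e <- dplyr::distinct(e) |> dplyr::arrange(.data$layer, .data$a, .data$b)
  nodes <- dplyr::arrange(nodes, .data$id)
  structure(list(nodes = nodes, edges = e), class = "typed_graph")
}

#' @export
print.typed_graph <- function(x, ...) {
  cat("<typed_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  cat("  nodes: ", paste(sprintf("%s=%d", names(table(x$nodes$type)),
                                 as.integer(table(x$nodes$type))), collapse = ", "), "\n", sep = "")
  tl <- table(factor(x$edges$layer, levels = layers()))
  tl <- tl[tl > 0]
  cat("  edges: ", paste(sprintf("%s=%d", names(tl), as.integer(tl)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build the integrated typed graph from an association table
#'
#' One edge per unique association; predicates, directionality and support
#' are discarded — the graph records only that an association between the two
#' entities exists. Nodes are the union of edge endpoints (so there are no
#' isolated nodes); an id appearing with two different types across layers
#' aborts with the offending ids.
#'
#' @param table an association table ([deduplicate()] and friends).
#' @return A [typed_graph].
#' @export
build_graph <- function(table) {
  stopifnot(inherits(table, "assoc_table"))
  nodes <- tibble::tibble(
    id = c(table$entity_a, table$entity_b),
    type = c(table$type_a, table$type_b)
  )
  typed_graph(nodes, tibble::tibble(a = table$entity_a, b = table$entity_b))
}

#' Layer-restricted subgraph
#'
#' Keeps only the edges of the named layers, and their endpoint nodes.
#' Restricting to, say, the disease-gene layer yields the bipartite
#' disease-gene association network analysed on its own.
#'
#' @param graph a [typed_graph].
#' @param keep character vector of layer names (non-empty).
#' @return A [typed_graph].
#' @export
subgraph_by_layers <- function(graph, keep) {
  stopifnot(inherits(graph, "typed_graph"))
  if (length(keep) == 0) stop("no layers requested", call. = FALSE)
  check_layers(keep)
  e <- graph$edges[graph$edges$layer %in% keep, , drop = FALSE]
  ids <- unique(c(e$a, e$b))
  structure(list(
    nodes = graph$nodes[graph$nodes$id %in% ids, , drop = FALSE],
    edges = e
  ), class = "typed_graph")
}

#' Induced subgraph on a node set
#'
#' @param graph a [typed_graph].
#' @param ids node ids to keep; edges survive when both endpoints are kept.
#' @return A [typed_graph] (nodes restricted to `ids` that exist in `graph`).
#' @export
induced_subgraph <- function(graph, ids) {
  stopifnot(inherits(graph, "typed_graph"))
  ids <- unique(normalize_id(ids))
  keep_e <- graph$edges$a %in% ids & graph$edges$b %in% ids
  structure(list(
    nodes = graph$nodes[graph$nodes$id %in% ids, , drop = FALSE],
    edges = graph$edges[keep_e, , drop = FALSE]
  ), class = "typed_graph")
}

#' Node degrees
#'
#' @param graph a [typed_graph].
#' @param node_type optional entity type to restrict the reported nodes.
#' @param layer optional layer name; when given only edges of that layer are
#'   counted.
#' @return A tibble `id`, `type`, `degree` covering every (possibly
#'   filtered) node of the graph.
#' @export
node_degrees <- function(graph, node_type = NULL, layer = NULL) {
  stopifnot(inherits(graph, "typed_graph"))
  e <- graph$edges
  if (!is.null(layer)) {
    check_layers(layer)
    e <- e[e$layer %in% layer, , drop = FALSE]
  }
  deg <- table(factor(c(e$a, e$b), levels = graph$nodes$id))
  out <- tibble::tibble(id = graph$nodes$id, type = graph$nodes$type,
                        degree = as.integer(deg[graph$nodes$id]))
  if (!is.null(node_type)) {
    stopifnot(node_type %in% entity_types())
    out <- out[out$type %in% node_type, , drop = FALSE]
  }
  out
}

#' Edge-list import/export
#'
#' TSV dialect `entity_a`, `type_a`, `entity_b`, `type_b`, `layer`;
#' round-trips exactly.
#'
#' @param graph a [typed_graph].
#' @param path file path.
#' @return `write_edgelist()` returns `path` invisibly; `read_edgelist()`
#'   the graph.
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "typed_graph"))
  ty <- function(id) graph$nodes$type[match(id, graph$nodes$id)]
  readr::write_tsv(tibble::tibble(
    entity_a = graph$edges$a, type_a = ty(graph$edges$a),
    entity_b = graph$edges$b, type_b = ty(graph$edges$b),
    layer = graph$edges$layer
  ), path)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  typed_graph(
    nodes = tibble::tibble(id = c(x$entity_a, x$entity_b),
                           type = c(x$type_a, x$type_b)),
    edges = tibble::tibble(a = x$entity_a, b = x$entity_b)
  )
}

#' Convert to igraph
#'
#' @param graph a [typed_graph].
#' @return An [igraph::graph] with vertex attributes `name`, `type` and edge
#'   attribute `layer`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "typed_graph"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = graph$edges$a, to = graph$edges$b,
                   layer = graph$edges$layer),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$id, type = graph$nodes$type)
  )
  g
}

# internal: node index lookup and sparse adjacency
graph_index <- function(graph) {
  stats::setNames(seq_len(nrow(graph$nodes)), graph$nodes$id)
}

graph_adjacency <- function(graph) {
  n <- nrow(graph$nodes)
  idx <- graph_index(graph)
  i <- unname(idx[graph$edges$a]); j <- unname(idx[graph$edges$b])
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
}

# adjacency list as integer indices, sorted
graph_adjlist <- function(graph) {
  n <- nrow(graph$nodes)
  idx <- graph_index(graph)
  i <- unname(idx[graph$edges$a]); j <- unname(idx[graph$edges$b])
  adj <- vector("list", n)
  ends <- split(c(j, i), c(i, j))
  for (k in names(ends)) adj[[as.integer(k)]] <- sort(ends[[k]])
  for (k in seq_len(n)) if (is.null(adj[[k]])) adj[[k]] <- integer(0)
  adj
}
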