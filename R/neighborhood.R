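#' Subnetwork spanned by one pattern's matches
#'
#' The induced subgraph on every node participating in any match of one
#' pattern — the view used to read a motif's aggregate structure (e.g. all
#' associations among the diseases and genes of the disease-disease-gene
#' triangle motif). Edges are induced: every association of the parent graph
#' among participating nodes is included, not only the edges inside matches.
#'
#' @param graph the parent [typed_graph].
#' @param matches match tibble rows for exactly one pattern.
#' @return A `pattern_subnetwork`: list with `pattern`, `graph` (induced
#'   [typed_graph]), `per_layer_edge_counts` (tibble `layer`, `edges`) and
#'   `node_counts` (tibble `type`, `nodes`).
#' @export
pattern_subnetwork <- function(graph, matches) {
  stopifnot(inherits(graph, "typed_graph"), is.data.frame(matches))
  pat <- unique(matches$pattern)
  if (length(pat) > 1) {
    stop("matches span several patterns: ", paste(pat, collapse = ", "), call. = FALSE)
  }
  if (nrow(matches) == 0) {
    warning("empty match list; returning empty subnetwork", call. = FALSE)
    pat <- NA_character_
  }
  ids <- unique(c(matches$node_a, matches$node_b, matches$node_c))
  sub <- induced_subgraph(graph, ids)
  structure(list(
    pattern = pat,
    graph = sub,
    per_layer_edge_counts = tibble::tibble(
      layer = layers(),
      edges = as.integer(table(factor(sub$edges$layer, levels = layers())))
    ),
    node_counts = tibble::tibble(
      type = entity_types(),
      nodes = as.integer(table(factor(sub$nodes$type, levels = entity_types())))
    )
  ), class = "pattern_subnetwork")
}

#' @export
print.pattern_subnetwork <- function(x, ...) {
  cat("<pattern_subnetwork> ", x$pattern, "\n", sep = "")
  nc <- x$node_counts[x$node_counts$nodes > 0, ]
  ec <- x$per_layer_edge_counts[x$per_layer_edge_counts$edges > 0, ]
  cat("  nodes: ", paste(sprintf("%s=%d", nc$type, nc$nodes), collapse = ", "), "\n", sep = "")
  cat("  edges: ", paste(sprintf("%s=%d", ec$layer, ec$edges), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Shared and exclusive neighbors of two anchors
#'
#' Partitions the type-filtered neighborhoods of two nodes into shared
#' neighbors and those exclusive to either anchor — e.g. the genes two
#' associated diseases have in common versus the genes seen with only one
#' of them (candidate disease genes for the other).
#'
#' @param graph a [typed_graph].
#' @param a,b two distinct node ids.
#' @param neighbor_type entity type of the neighbors considered.
#' @return A list with `anchor_a`, `anchor_b`, `neighbor_type`, and the
#'   disjoint sets `shared`, `only_a`, `only_b` (sorted character vectors).
#' @export
shared_neighbors <- function(graph, a, b, neighbor_type) {
  stopifnot(inherits(graph, "typed_graph"), neighbor_type %in% entity_types())
  a <- normalize_id(a); b <- normalize_id(b)
  if (a == b) stop("anchors must be distinct", call. = FALSE)
  for (id in c(a, b)) {
    if (!(id %in% graph$nodes$id)) stop("node not in graph: ", id, call. = FALSE)
  }
  na <- typed_neighbors(graph, a, neighbor_type)
  nb <- typed_neighbors(graph, b, neighbor_type)
  list(anchor_a = a, anchor_b = b, neighbor_type = neighbor_type,
       shared = sort(intersect(na, nb)),
       only_a = sort(setdiff(na, nb)),
       only_b = sort(setdiff(nb, na)))
}

typed_neighbors <- function(graph, id, type = NULL) {
  e <- graph$edges
  nb <- c(e$b[e$a == id], e$a[e$b == id])
  if (!is.null(type)) {
    nb_types <- graph$nodes$type[match(nb, graph$nodes$id)]
    nb <- nb[nb_types %in% type]
  }
  unique(nb)
}

#' Guilt-by-association candidate prioritization
#'
#' When two nodes (typically two diseases) share neighbors of some type,
#' the neighbors seen with only the source can be prioritized as candidates
#' for the target. Candidates are the source's `candidate_type` neighbors
#' not adjacent to the target, ranked by how many other shared neighbors
#' support them — the number of `target`-type nodes adjacent to both the
#' candidate and the target — with lexicographic tie-break. The ranking rule
#' is recorded in the `ranking_rule` attribute.
#'
#' @param graph a [typed_graph].
#' @param source,target two distinct node ids; they must share at least one
#'   `candidate_type` neighbor (the guilt-by-association premise).
#' @param candidate_type entity type of the candidates.
#' @return Tibble `id`, `support` ranked best-first (possibly empty, with a
#'   warning, when the premise is unmet).
#' @export
prioritize_candidates <- function(graph, source, target, candidate_type) {
  rep <- shared_neighbors(graph, source, target, candidate_type)
  if (length(rep$shared) == 0) {
    warning("source and target share no ", candidate_type,
            " neighbors; guilt-by-association premise unmet", call. = FALSE)
    out <- tibble::tibble(id = character(0), support = integer(0))
  } else {
    cands <- rep$only_a
    target_type <- graph$nodes$type[match(rep$anchor_b, graph$nodes$id)]
    tnb <- typed_neighbors(graph, rep$anchor_b, target_type)
    support <- vapply(cands, function(g) {
      length(intersect(typed_neighbors(graph, g, target_type), tnb))
    }, integer(1))
    ord <- order(-support, cands)
    out <- tibble::tibble(id = cands[ord], support = unname(support[ord]))
  }
  attr(out, "ranking_rule") <- paste0(
    "candidates = ", candidate_type, " neighbors of source not adjacent to target; ",
    "ranked by number of target-type nodes adjacent to both candidate and target, ",
    "then lexicographically")
  out
}

#' Ego subnetwork
#'
#' The induced subgraph on all nodes within a given number of hops of a
#' centre node (default: the centre and its first neighbors).
#'
#' @param graph a [typed_graph].
#' @param center node id.
#' @param radius hop limit (`>= 1`).
#' @return A [typed_graph].
#' @export
ego_subnetwork <- function(graph, center, radius = 1) {
  stopifnot(inherits(graph, "typed_graph"), radius >= 1)
  center <- normalize_id(center)
  if (!(center %in% graph$nodes$id)) stop("node not in graph: ", center, call. = FALSE)
  reached <- center
  frontier <- center
  for (r in seq_len(radius)) {
    nxt <- unique(unlist(lapply(frontier, typed_neighbors, graph = graph)))
    frontier <- setdiff(nxt, reached)
    if (length(frontier) == 0) break
    reached <- c(reached, frontier)
  }
  induced_subgraph(graph, reached)
}

#' Export a typed graph as GraphML
#'
#' For loading subnetworks into visualization tools.
#'
#' @param graph a [typed_graph].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}
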