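#' Aggregate significant-motif matches into the core network
#'
#' Overlapping matches of significant motifs cluster into a superstructure —
#' the backbone of the heterogeneous network. The core network is the union
#' of the induced edges of every match of every significant pattern, with
#' per-edge and per-node provenance recording which patterns contributed.
#'
#' @param graph the [typed_graph] the census was run on.
#' @param significance a `motif_significance` from [call_significance()].
#' @param matches match tibble (`pattern`, `node_a`, `node_b`, `node_c`),
#'   normally `census_match_table(census(graph, keep_matches = TRUE))`.
#' @return A `core_network`: list with `graph` (the core [typed_graph]),
#'   `edge_provenance` (tibble `a`, `b`, `layer`, `patterns` list column) and
#'   `node_provenance` (tibble `id`, `patterns` list column).
#' @export
aggregate_core <- function(graph, significance, matches) {
  stopifnot(inherits(graph, "typed_graph"),
            inherits(significance, "motif_significance"),
            is.data.frame(matches))
  sig_pat <- significance$pattern[significance$significant]
  missing <- setdiff(sig_pat, unique(matches$pattern))
  if (length(missing)) {
    stop("no stored matches for significant pattern(s) ",
         paste(missing, collapse = ", "),
         "; rerun census(graph, keep_matches = TRUE)", call. = FALSE)
  }
  m <- matches[matches$pattern %in% sig_pat, , drop = FALSE]
  if (nrow(m) == 0) {
    empty <- induced_subgraph(graph, character(0))
    return(structure(list(
      graph = empty,
      edge_provenance = tibble::tibble(a = character(0), b = character(0),
                                       layer = character(0), patterns = list()),
      node_provenance = tibble::tibble(id = character(0), patterns = list())
    ), class = "core_network"))
  }
  ekey <- edge_key(graph$edges$a, graph$edges$b)
  # induced edges of each match = graph edges among the 3 match nodes
  pair_rows <- dplyr::bind_rows(
    tibble::tibble(u = m$node_a, v = m$node_b, pattern = m$pattern),
    tibble::tibble(u = m$node_a, v = m$node_c, pattern = m$pattern),
    tibble::tibble(u = m$node_b, v = m$node_c, pattern = m$pattern)
  )
  pair_rows <- dplyr::mutate(pair_rows, a = pmin(.data$u, .data$v),
                             b = pmax(.data$u, .data$v))
  pair_rows <- pair_rows[edge_key(pair_rows$a, pair_rows$b) %in% ekey, , drop = FALSE]
  edge_prov <- pair_rows |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(patterns = list(sort(unique(.data$pattern))), .groups = "drop")
  lay <- graph$edges$layer[match(edge_key(edge_prov$a, edge_prov$b), ekey)]
  edge_prov <- dplyr::mutate(edge_prov, layer = lay)[, c("a", "b", "layer", "patterns")]
  node_prov <- dplyr::bind_rows(
    tibble::tibble(id = m$node_a, pattern = m$pattern),
    tibble::tibble(id = m$node_b, pattern = m$pattern),
    tibble::tibble(id = m$node_c, pattern = m$pattern)
  ) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(patterns = list(sort(unique(.data$pattern))), .groups = "drop")
  core_nodes <- graph$nodes[graph$nodes$id %in% node_prov$id, , drop = FALSE]
  core_graph <- structure(list(
    nodes = core_nodes,
    edges = dplyr::arrange(
      tibble::tibble(a = edge_prov$a, b = edge_prov$b, layer = edge_prov$layer),
      .data$layer, .data$a, .data$b)
  ), class = "typed_graph")
  structure(list(graph = core_graph, edge_provenance = edge_prov,
                 node_provenance = node_prov),
            class = "core_network")
}

#' @export
print.core_network <- function(x, ...) {
  cat("<core_network>\n")
  print(x$graph)
  invisible(x)
}

#' Degree distribution with power-law fit
#'
#' Degree histogram, complementary cumulative distribution (CCDF,
#' `P(K >= k)`) and a power-law exponent for the nodes of one type.
#' Degree distributions of literature-derived biomedical networks are
#' heavy-tailed: most entities have only a few links while a handful of
#' hubs dominate. The exponent is fitted by continuous maximum likelihood
#' with a Kolmogorov–Smirnov scan over the lower cutoff `xmin`
#' ([igraph::fit_power_law()], `plfit` implementation) rather than by
#' log-log regression, which is biased on binned tails.
#'
#' @param x a [typed_graph] or `core_network`.
#' @param node_type entity type whose degrees are analysed.
#' @param fit if `FALSE`, skip the power-law fit (histogram/CCDF only).
#' @return A `degree_dist` object: list with `node_type`, `degrees` (tibble
#'   `id`, `degree`), `histogram` (tibble `degree`, `n_nodes`), `ccdf`
#'   (tibble `degree`, `fraction`), `fitted_exponent`, `fit_xmin`,
#'   `fit_method`, `graph_label` (whether a core or full graph was used).
#' @export
degree_distribution <- function(x, node_type, fit = TRUE) {
  label <- if (inherits(x, "core_network")) "core" else "full"
  graph <- if (inherits(x, "core_network")) x$graph else x
  stopifnot(inherits(graph, "typed_graph"), node_type %in% entity_types())
  deg <- node_degrees(graph, node_type = node_type)
  if (nrow(deg) < 2) {
    stop("need at least 2 nodes of type '", node_type, "' (found ", nrow(deg), ")",
         call. = FALSE)
  }
  hist_tbl <- deg |> dplyr::count(.data$degree, name = "n_nodes") |>
    dplyr::arrange(.data$degree)
  ccdf <- tibble::tibble(
    degree = hist_tbl$degree,
    fraction = rev(cumsum(rev(hist_tbl$n_nodes))) / sum(hist_tbl$n_nodes)
  )
  exponent <- NA_real_; xmin <- NA_real_; method <- "none"
  if (fit) {
    pos <- deg$degree[deg$degree > 0]
    if (length(pos) >= 2) {
      fl <- igraph::fit_power_law(pos, implementation = "plfit")
      exponent <- fl$alpha; xmin <- fl$xmin
      method <- paste0(if (isTRUE(fl$continuous)) "continuous" else "discrete",
                       " MLE with KS xmin scan (plfit)")
    }
  }
  structure(list(node_type = node_type, degrees = deg[, c("id", "degree")],
                 histogram = hist_tbl, ccdf = ccdf,
                 fitted_exponent = exponent, fit_xmin = xmin,
                 fit_method = method, graph_label = label),
            class = "degree_dist")
}

#' @export
print.degree_dist <- function(x, ...) {
  cat("<degree_dist> type=", x$node_type, " (", x$graph_label, " graph), ",
      nrow(x$degrees), " nodes, max degree ", max(x$degrees$degree), "\n", sep = "")
  if (!is.na(x$fitted_exponent)) {
    cat("  power-law fit: exponent ", round(x$fitted_exponent, 3),
        ", xmin ", x$fit_xmin, " [", x$fit_method, "]\n", sep = "")
  }
  invisible(x)
}

#' Hub nodes of one entity type
#'
#' Returns the `top_k` highest-degree nodes of a type — the candidate focus
#' entities (e.g. hub drugs shared by many diseases suggest repositioning
#' leads). Ties are broken lexicographically by id so reports are
#' deterministic.
#'
#' @param x a [typed_graph] or `core_network`.
#' @param node_type entity type.
#' @param top_k number of hubs to report (`>= 1`).
#' @return A tibble `id`, `type`, `degree`, ranked, with attribute
#'   `selection_rule` describing the ranking.
#' @export
hubs <- function(x, node_type, top_k = 10) {
  graph <- if (inherits(x, "core_network")) x$graph else x
  stopifnot(inherits(graph, "typed_graph"), top_k >= 1)
  deg <- node_degrees(graph, node_type = node_type)
  if (nrow(deg) == 0) {
    warning("no nodes of type '", node_type, "' in graph", call. = FALSE)
  }
  out <- deg |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$id) |>
    utils::head(top_k)
  attr(out, "selection_rule") <-
    "top-k by degree, ties broken lexicographically by id"
  out
}
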