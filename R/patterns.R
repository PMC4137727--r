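#' The colored three-node pattern space
#'
#' Every connected three-node subgraph of a typed network falls into one of
#' 28 colored isomorphism classes: 18 paths (a centre node joined to two
#' leaves that are not adjacent to each other; 3 centre types x 6 unordered
#' leaf-type pairs) and 10 triangles (one per multiset of three endpoint
#' types). Patterns are named by canonical strings, e.g.
#' `"tri:disease,disease,gene"` (types sorted) and
#' `"path:center=gene;leaves=disease,disease"` (leaves sorted), which serve
#' as stable keys throughout the package.
#'
#' @return A tibble with one row per pattern, in a fixed canonical order:
#'   `pattern` (canonical string), `topology` (`"path"` or `"tri"`),
#'   `center` (centre type for paths, `NA` for triangles) and `types`
#'   (comma-joined sorted types of all three nodes).
#' @examples
#' pattern_space()
#' @export
pattern_space <- function() {
  tt <- entity_types()
  tri <- list()
  for (i in seq_along(tt)) {
    for (j in i:length(tt)) {
      for (k in j:length(tt)) {
        tri[[length(tri) + 1]] <- c(tt[i], tt[j], tt[k])
      }
    }
  }
  tri_tbl <- tibble::tibble(
    pattern  = vapply(tri, function(x) pattern_tri(x), character(1)),
    topology = "tri",
    center   = NA_character_,
    types    = vapply(tri, function(x) paste(x, collapse = ","), character(1))
  )
  paths <- list()
  for (c_type in tt) {
    for (i in seq_along(tt)) {
      for (j in i:length(tt)) {
        paths[[length(paths) + 1]] <- list(center = c_type, leaves = c(tt[i], tt[j]))
      }
    }
  }
  path_tbl <- tibble::tibble(
    pattern  = vapply(paths, function(x) pattern_path(x$center, x$leaves), character(1)),
    topology = "path",
    center   = vapply(paths, function(x) x$center, character(1)),
    types    = vapply(paths, function(x) paste(sort(c(x$center, x$leaves)), collapse = ","),
                      character(1))
  )
  dplyr::bind_rows(tri_tbl, path_tbl)
}

#' Canonical pattern names
#'
#' @param types three entity types (triangle) — order irrelevant.
#' @param center,leaves centre type and the two leaf types of a path.
#' @return The canonical pattern string.
#' @examples
#' pattern_tri(c("gene", "disease", "disease"))
#' pattern_path("gene", c("disease", "disease"))
#' @export
pattern_tri <- function(types) {
  stopifnot(length(types) == 3)
  bad <- setdiff(types, entity_types())
  if (length(bad)) stop("unknown entity type(s): ", paste(bad, collapse = ", "))
  paste0("tri:", paste(sort(types), collapse = ","))
}

#' @rdname pattern_tri
#' @export
pattern_path <- function(center, leaves) {
  stopifnot(length(center) == 1, length(leaves) == 2)
  bad <- setdiff(c(center, leaves), entity_types())
  if (length(bad)) stop("unknown entity type(s): ", paste(bad, collapse = ", "))
  paste0("path:center=", center, ";leaves=", paste(sort(leaves), collapse = ","))
}

#' Classify one node triple into its colored pattern
#'
#' Looks at the subgraph induced on three nodes: three induced edges make a
#' triangle, exactly two make a path whose centre is the degree-2 node, and
#' one or zero edges mean the triple is not connected.
#'
#' @param graph a [typed_graph].
#' @param ids character vector of exactly three distinct node ids.
#' @return The canonical pattern string, or `NA_character_` when the induced
#'   subgraph is not connected.
#' @export
classify_triple <- function(graph, ids) {
  stopifnot(inherits(graph, "typed_graph"))
  ids <- normalize_id(ids)
  if (length(ids) != 3 || anyDuplicated(ids)) {
    stop("classify_triple() needs exactly three distinct node ids", call. = FALSE)
  }
  missing <- setdiff(ids, graph$nodes$id)
  if (length(missing)) {
    stop("node(s) not in graph: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  types <- graph$nodes$type[match(ids, graph$nodes$id)]
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  key <- edge_key(graph$edges$a, graph$edges$b)
  has_edge <- vapply(seq_len(3), function(r) {
    u <- ids[pairs[r, 1]]; v <- ids[pairs[r, 2]]
    edge_key(min(u, v), max(u, v)) %in% key
  }, logical(1))
  n_edges <- sum(has_edge)
  if (n_edges == 3L) return(pattern_tri(types))
  if (n_edges == 2L) {
    # the centre is the node on both induced edges
    deg <- tabulate(as.vector(pairs[has_edge, , drop = FALSE]), nbins = 3)
    center <- which(deg == 2L)
    pattern_path(types[center], types[-center])
  } else {
    NA_character_
  }
}

edge_key <- function(a, b) paste(a, b, sep = "\r")
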