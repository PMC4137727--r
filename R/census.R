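#' Colored three-node motif census
#'
#' Counts every connected three-node induced subgraph of the network once and
#' classifies it into one of the 28 colored patterns ([pattern_space()]).
#' Overlapping occurrences all count (full enumeration, the convention of
#' standard motif tools): the census is the raw material for the null-model
#' significance test and, through stored matches, for core-network
#' aggregation.
#'
#' Counting is algebraic and never touches individual triples: with the
#' sparse adjacency matrix `A` and per-type index sets, colored triangle
#' counts come from products of type-blocks of `A`, and path counts from
#' per-node neighbor-type tallies (`A` times the type indicator matrix) with
#' the triangle overcount subtracted. Match enumeration (optional) walks
#' edges and open neighbor pairs with a total-order guard so no triple is
#' visited twice.
#'
#' @param graph a [typed_graph].
#' @param keep_matches if `TRUE`, also record the concrete node triple of
#'   every match (needed later by [aggregate_core()] and
#'   [pattern_subnetwork()]).
#' @return A `motif_census` object: a tibble with columns `pattern`,
#'   `topology`, `count` covering all 28 patterns in canonical order. When
#'   `keep_matches = TRUE` a tibble of matches (`pattern`, `node_a`,
#'   `node_b`, `node_c`, nodes sorted within each triple) is attached as the
#'   `matches` attribute.
#' @examples
#' g <- typed_graph(
#'   nodes = tibble::tibble(id = c("d1", "d2", "g1"),
#'                          type = c("disease", "disease", "gene")),
#'   edges = tibble::tibble(a = c("d1", "d1", "d2"), b = c("d2", "g1", "g1"))
#' )
#' census(g)
#' @export
census <- function(graph, keep_matches = FALSE) {
  stopifnot(inherits(graph, "typed_graph"))
  space <- pattern_space()
  counts <- census_counts(graph)
  out <- dplyr::mutate(space, count = unname(counts[space$pattern]))
  out$count[is.na(out$count)] <- 0
  out <- out[, c("pattern", "topology", "count")]
  class(out) <- c("motif_census", class(out))
  if (keep_matches) {
    attr(out, "matches") <- census_matches(graph)
  }
  out
}

#' @export
print.motif_census <- function(x, ...) {
  cat("<motif_census> ", sum(x$count), " connected triples over ",
      nrow(x), " patterns (", sum(x$count > 0), " non-zero)\n", sep = "")
  print(tibble::as_tibble(x)[x$count > 0, ], ...)
  invisible(x)
}

#' Matches stored with a census
#'
#' @param x a `motif_census` produced with `keep_matches = TRUE`.
#' @return The match tibble (`pattern`, `node_a`, `node_b`, `node_c`).
#' @export
census_match_table <- function(x) {
  m <- attr(x, "matches")
  if (is.null(m)) {
    stop("census was run without keep_matches = TRUE; rerun census(graph, keep_matches = TRUE)",
         call. = FALSE)
  }
  m
}

# named vector of counts for all patterns present (absent = 0)
census_counts <- function(graph) {
  n <- nrow(graph$nodes)
  tt <- entity_types()
  counts <- numeric(0)
  if (n < 3 || nrow(graph$edges) == 0) return(counts)
  A <- graph_adjacency(graph)
  type_idx <- lapply(tt, function(t) which(graph$nodes$type == t))
  names(type_idx) <- tt

  # triangles per sorted type multiset
  tri_counts <- list()
  for (i in seq_along(tt)) for (j in i:length(tt)) for (k in j:length(tt)) {
    s <- c(tt[i], tt[j], tt[k])
    i1 <- type_idx[[s[1]]]; i2 <- type_idx[[s[2]]]; i3 <- type_idx[[s[3]]]
    if (!length(i1) || !length(i2) || !length(i3)) {
      tri_counts[[pattern_tri(s)]] <- 0
      next
    }
    common3 <- A[i1, i3, drop = FALSE] %*% A[i3, i2, drop = FALSE]
    sub <- sum(common3 * A[i1, i2, drop = FALSE])
    div <- if (s[1] == s[3]) 6 else if (s[1] == s[2] || s[2] == s[3]) 2 else 1
    tri_counts[[pattern_tri(s)]] <- sub / div
  }
  counts <- unlist(tri_counts)

  # neighbor-type tallies: M[v, t] = number of type-t neighbors of v
  Tm <- Matrix::sparseMatrix(i = seq_len(n), j = match(graph$nodes$type, tt),
                             x = 1, dims = c(n, 3))
  M <- as.matrix(A %*% Tm)
  colnames(M) <- tt
  for (c_type in tt) {
    rows <- type_idx[[c_type]]
    for (i in seq_along(tt)) for (j in i:length(tt)) {
      a <- tt[i]; b <- tt[j]
      if (length(rows)) {
        p_all <- if (a == b) sum(choose(M[rows, a], 2)) else sum(M[rows, a] * M[rows, b])
      } else p_all <- 0
      mult <- sum(c(c_type, a, b) == c_type)
      tri_n <- counts[[pattern_tri(c(c_type, a, b))]]
      counts[[pattern_path(c_type, c(a, b))]] <- p_all - mult * tri_n
    }
  }
  counts
}

# enumerate concrete matches; each triple exactly once
census_matches <- function(graph) {
  n <- nrow(graph$nodes)
  empty <- tibble::tibble(pattern = character(0), node_a = character(0),
                          node_b = character(0), node_c = character(0))
  if (n < 3 || nrow(graph$edges) == 0) return(empty)
  adj <- graph_adjlist(graph)
  ids <- graph$nodes$id
  types <- graph$nodes$type
  pat <- character(0); ta <- character(0); tb <- character(0); tc <- character(0)
  buf_p <- vector("list", 2048); buf_t <- vector("list", 2048); nb <- 0L
  push <- function(p, trip) {
    nb <<- nb + 1L
    if (nb > length(buf_p)) { length(buf_p) <<- 2 * nb; length(buf_t) <<- 2 * nb }
    buf_p[[nb]] <<- p; buf_t[[nb]] <<- trip
  }
  # triangles: anchored at each edge (u,v), third vertex w > max(u,v)
  idx <- graph_index(graph)
  eu <- unname(idx[graph$edges$a]); ev <- unname(idx[graph$edges$b])
  for (e in seq_along(eu)) {
    u <- eu[e]; v <- ev[e]
    w <- intersect(adj[[u]], adj[[v]])
    w <- w[w > max(u, v)]
    for (x in w) push(pattern_tri(types[c(u, v, x)]), c(u, v, x))
  }
  # paths: for each centre, open pairs of neighbors (u < w, u-w not adjacent)
  for (v in seq_len(n)) {
    nb_v <- adj[[v]]
    k <- length(nb_v)
    if (k < 2) next
    for (ii in 1:(k - 1)) {
      u <- nb_v[ii]
      au <- adj[[u]]
      for (jj in (ii + 1):k) {
        w <- nb_v[jj]
        if (!(w %in% au)) {
          push(pattern_path(types[v], types[c(u, w)]), c(v, u, w))
        }
      }
    }
  }
  if (nb == 0L) return(empty)
  trips <- do.call(rbind, buf_t[seq_len(nb)])
  trips <- t(apply(trips, 1, sort))
  tibble::tibble(
    pattern = unlist(buf_p[seq_len(nb)]),
    node_a = ids[trips[, 1]], node_b = ids[trips[, 2]], node_c = ids[trips[, 3]]
  ) |> dplyr::arrange(.data$pattern, .data$node_a, .data$node_b, .data$node_c)
}
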