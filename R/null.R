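#' Type-preserving network randomization
#'
#' Produces a randomized network with exactly the original per-layer edge
#' counts and, in the default mode, every node's per-layer degree: edges are
#' rewired by double-edge swaps confined within each layer (a swap exchanges
#' the partners of two same-layer edges; swaps creating self-loops or
#' duplicate edges are rejected). This is the strictest reading of
#' "preserving the number of edges between types of nodes" that also holds
#' typed degree sequences fixed, so motif excess cannot be explained by
#' degree structure alone. A weaker null (`mode = "layer_count"`) preserves
#' only per-layer edge counts, resampling endpoints freely among nodes of
#' the right types; it is offered for sensitivity analysis.
#'
#' The swap loop is delegated per layer to [igraph::rewire()] with
#' [igraph::keeping_degseq()], which implements exactly this rejection
#' scheme; randomness flows from R's RNG, so results are reproducible under
#' `set.seed()`. Layers with fewer than two edges are left unchanged.
#'
#' @param graph a [typed_graph] (simple by construction).
#' @param swaps_per_edge attempted swaps per layer edge (default 100); the
#'   number of swap attempts in a layer with `m` edges is
#'   `round(swaps_per_edge * m)`.
#' @param mode `"layered_swap"` (default, degree-preserving) or
#'   `"layer_count"` (edge counts only).
#' @return A randomized [typed_graph] on the same node set and types.
#' @export
randomize_graph <- function(graph, swaps_per_edge = 100,
                            mode = c("layered_swap", "layer_count")) {
  stopifnot(inherits(graph, "typed_graph"), swaps_per_edge > 0)
  mode <- match.arg(mode)
  n <- nrow(graph$nodes)
  idx <- graph_index(graph)
  new_edges <- list()
  for (ly in unique(graph$edges$layer)) {
    e <- graph$edges[graph$edges$layer == ly, , drop = FALSE]
    m <- nrow(e)
    if (m < 2) { new_edges[[ly]] <- e; next }
    if (mode == "layered_swap") {
      tys <- layer_types(ly)[[1]]
      cross <- tys[1] != tys[2]
      if (cross) {
        # orient every edge from the first endpoint type to the second so a
        # directed degree-preserving rewire swaps partners without ever
        # pairing two same-type endpoints
        ta <- graph$nodes$type[unname(idx[e$a])]
        tail <- ifelse(ta == tys[1], e$a, e$b)
        head <- ifelse(ta == tys[1], e$b, e$a)
        el <- cbind(unname(idx[tail]), unname(idx[head]))
      } else {
        el <- cbind(unname(idx[e$a]), unname(idx[e$b]))
      }
      g <- igraph::graph_from_edgelist(el, directed = cross)
      if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
      g <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                    niter = round(swaps_per_edge * m)))
      el2 <- igraph::as_edgelist(g, names = FALSE)
      a <- graph$nodes$id[el2[, 1]]; b <- graph$nodes$id[el2[, 2]]
    } else {
      tys <- layer_types(ly)[[1]]
      pool_a <- graph$nodes$id[graph$nodes$type == tys[1]]
      pool_b <- graph$nodes$id[graph$nodes$type == tys[2]]
      seen <- character(0)
      a <- character(m); b <- character(m)
      for (k in seq_len(m)) {
        repeat {
          u <- sample(pool_a, 1); v <- sample(pool_b, 1)
          if (u == v) next
          key <- edge_key(min(u, v), max(u, v))
          if (!(key %in% seen)) { seen <- c(seen, key); break }
        }
        a[k] <- u; b[k] <- v
      }
    }
    lo <- pmin(a, b); hi <- pmax(a, b)
    new_edges[[ly]] <- tibble::tibble(a = lo, b = hi, layer = ly)
  }
  e <- dplyr::arrange(dplyr::bind_rows(new_edges), .data$layer, .data$a, .data$b)
  structure(list(nodes = graph$nodes, edges = e), class = "typed_graph")
}

#' Null-ensemble motif census
#'
#' Randomizes the network `n_networks` times ([randomize_graph()]) and runs
#' the colored census on every replicate, yielding the per-pattern null
#' count distributions that the significance test is based on. Fully
#' reproducible from `seed`: each replicate gets its own sub-seed drawn once
#' from the root seed.
#'
#' @param graph a [typed_graph].
#' @param n_networks number of randomized replicates (default 1000, the
#'   usual ensemble size for motif detection).
#' @param swaps_per_edge passed to [randomize_graph()].
#' @param seed integer root seed.
#' @param mode randomization mode, see [randomize_graph()].
#' @return A `motif_null` object: list with `counts` (pattern x replicate
#'   integer matrix), `stats` (tibble `pattern`, `null_mean`, `null_sd` —
#'   population sd across replicates), `n_networks`, `swaps_per_edge`,
#'   `seed`, `mode`.
#' @export
ensemble_census <- function(graph, n_networks = 1000, swaps_per_edge = 100,
                            seed = 1L, mode = "layered_swap") {
  stopifnot(inherits(graph, "typed_graph"), n_networks >= 1)
  space <- pattern_space()
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_networks)
  counts <- matrix(0, nrow = nrow(space), ncol = n_networks,
                   dimnames = list(space$pattern, NULL))
  for (r in seq_len(n_networks)) {
    set.seed(sub_seeds[r])
    g_r <- randomize_graph(graph, swaps_per_edge = swaps_per_edge, mode = mode)
    cts <- census_counts(g_r)
    if (length(cts)) counts[names(cts), r] <- cts
  }
  structure(list(
    counts = counts,
    stats = tibble::tibble(
      pattern = space$pattern,
      null_mean = unname(rowMeans(counts)),
      null_sd = unname(apply(counts, 1, sd_pop))
    ),
    n_networks = n_networks, swaps_per_edge = swaps_per_edge,
    seed = seed, mode = mode
  ), class = "motif_null")
}

#' @export
print.motif_null <- function(x, ...) {
  cat("<motif_null> ", x$n_networks, " randomized replicates (",
      x$mode, ", ", x$swaps_per_edge, " swaps/edge, seed ", x$seed, ")\n", sep = "")
  print(x$stats[x$stats$null_mean > 0 | x$stats$null_sd > 0, ], ...)
  invisible(x)
}

# population standard deviation (motif-tool convention)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Motif z-score
#'
#' `z = (n_real - null_mean) / null_sd`, where `n_real` is the pattern's
#' count in the real network and `null_mean`, `null_sd` are the mean and
#' (population) standard deviation of its counts across the randomized
#' ensemble. When the null distribution is degenerate (`null_sd == 0`) the
#' z-score is undefined and `NA` is returned.
#'
#' @param n_real real-network count.
#' @param null_mean,null_sd null ensemble mean and standard deviation
#'   (`null_sd >= 0`).
#' @return The z-score, or `NA_real_` when `null_sd` is zero.
#' @examples
#' zscore(10, 4, 2) # 3
#' @export
zscore <- function(n_real, null_mean, null_sd) {
  if (any(null_sd < 0)) stop("null_sd must be non-negative", call. = FALSE)
  ifelse(null_sd == 0, NA_real_, (n_real - null_mean) / null_sd)
}

#' Empirical motif p-value
#'
#' The fraction of randomized networks in which the pattern occurs at least
#' as often as in the real network (`"geq"`, the default and the convention
#' of standard motif tools: ties count against significance, which keeps the
#' test calibrated even when a pattern's null distribution is nearly
#' degenerate). `inequality = "greater"` counts strict exceedances only.
#'
#' @param n_real real-network count.
#' @param null_counts non-empty vector of per-replicate null counts.
#' @param inequality `"geq"` (default) or `"greater"` (strict exceedance).
#' @return p in `[0, 1]`.
#' @examples
#' empirical_p(10, c(12, 8, 10)) # 2/3
#' empirical_p(10, c(12, 8, 10), inequality = "greater") # 1/3
#' @export
empirical_p <- function(n_real, null_counts, inequality = c("geq", "greater")) {
  if (length(null_counts) == 0) stop("empty null_counts", call. = FALSE)
  inequality <- match.arg(inequality)
  if (inequality == "greater") mean(null_counts > n_real) else mean(null_counts >= n_real)
}

#' Call significant motifs
#'
#' A pattern is a network motif when it occurs at least `min_count` times in
#' the real network and its empirical p-value does not exceed `alpha`
#' (defaults 5 and 0.05, the standard motif-detection thresholds). z-scores
#' are reported for every pattern; results are sorted by z descending with
#' undefined z last. A degenerate null (sd 0) leaves z undefined but the
#' pattern can still be significant through p and the count floor.
#'
#' @param census a `motif_census` from [census()].
#' @param null a `motif_null` from [ensemble_census()] on the same graph.
#' @param min_count minimum real-network occurrences (default 5).
#' @param alpha significance level on the empirical p (default 0.05).
#' @param inequality p-value convention, see [empirical_p()].
#' @param bonferroni if `TRUE`, divide `alpha` by the number of patterns
#'   tested (off by default; the procedure traditionally tests each pattern
#'   at `alpha` unadjusted).
#' @return A `motif_significance` tibble: `pattern`, `n_real`, `null_mean`,
#'   `null_sd`, `z`, `p`, `significant`, `reasons`.
#' @export
call_significance <- function(census, null, min_count = 5, alpha = 0.05,
                              inequality = c("geq", "greater"),
                              bonferroni = FALSE) {
  stopifnot(inherits(census, "motif_census"), inherits(null, "motif_null"))
  inequality <- match.arg(inequality)
  if (!identical(sort(census$pattern), sort(rownames(null$counts)))) {
    stop("census and null ensemble cover different pattern spaces", call. = FALSE)
  }
  if (bonferroni) alpha <- alpha / nrow(census)
  n_real <- stats::setNames(census$count, census$pattern)
  pat <- census$pattern
  p <- vapply(pat, function(pp) empirical_p(n_real[[pp]], null$counts[pp, ], inequality),
              numeric(1))
  nm <- stats::setNames(null$stats$null_mean, null$stats$pattern)[pat]
  ns <- stats::setNames(null$stats$null_sd, null$stats$pattern)[pat]
  z <- zscore(n_real[pat], nm, ns)
  sig <- n_real[pat] >= min_count & p <= alpha
  reasons <- paste0(
    ifelse(n_real[pat] >= min_count, "count_ok", "count_below_min"), ";",
    ifelse(p <= alpha, "p_ok", "p_above_alpha")
  )
  out <- tibble::tibble(
    pattern = pat, n_real = unname(n_real[pat]),
    null_mean = unname(nm), null_sd = unname(ns),
    z = unname(z), p = unname(p), significant = unname(sig),
    reasons = reasons
  )
  out <- dplyr::arrange(out, dplyr::desc(!is.na(.data$z)), dplyr::desc(.data$z))
  structure(out, class = c("motif_significance", class(tibble::tibble())),
            min_count = min_count, alpha = alpha, inequality = inequality)
}

#' @export
print.motif_significance <- function(x, ...) {
  cat("<motif_significance> ", sum(x$significant), " significant motif(s) of ",
      nrow(x), " patterns (min_count=", attr(x, "min_count"),
      ", alpha=", attr(x, "alpha"), ")\n", sep = "")
  print(tibble::as_tibble(x)[, setdiff(names(x), "reasons")], ...)
  invisible(x)
}
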