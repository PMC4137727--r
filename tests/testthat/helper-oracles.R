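# Independent oracles: brute-force computations used to validate the
# package's algebraic/enumerative implementations. These deliberately avoid
# the package's counting code paths (census, classify_triple).

# random typed graph with n nodes and m edges
random_typed_graph <- function(n, m, seed = NULL, types = c("disease", "drug", "gene")) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  ty <- sample(types, n, replace = TRUE)
  pairs <- utils::combn(n, 2)
  m <- min(m, ncol(pairs))
  pick <- sample(ncol(pairs), m)
  typed_graph(
    nodes = tibble::tibble(id = ids, type = ty),
    edges = tibble::tibble(a = ids[pairs[1, pick]], b = ids[pairs[2, pick]])
  )
}

# brute-force colored census over all C(n,3) triples
oracle_census <- function(graph) {
  n <- nrow(graph$nodes)
  ids <- graph$nodes$id; types <- graph$nodes$type
  A <- matrix(FALSE, n, n)
  ai <- match(graph$edges$a, ids); bi <- match(graph$edges$b, ids)
  A[cbind(ai, bi)] <- TRUE; A[cbind(bi, ai)] <- TRUE
  counts <- list()
  if (n >= 3 && nrow(graph$edges) > 0) {
    trips <- utils::combn(n, 3)
    for (k in seq_len(ncol(trips))) {
      t3 <- trips[, k]
      e12 <- A[t3[1], t3[2]]; e13 <- A[t3[1], t3[3]]; e23 <- A[t3[2], t3[3]]
      ne <- e12 + e13 + e23
      if (ne < 2) next
      if (ne == 3) {
        key <- paste0("tri:", paste(sort(types[t3]), collapse = ","))
      } else {
        deg <- c(e12 + e13, e12 + e23, e13 + e23)
        key <- paste0("path:center=", types[t3[deg == 2]], ";leaves=",
                      paste(sort(types[t3[deg != 2]]), collapse = ","))
      }
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  unlist(counts)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# census tibble -> named count vector of the non-zero patterns
census_nonzero <- function(cen) {
  v <- stats::setNames(cen$count, cen$pattern)
  v[v > 0]
}

# exhaustive enumeration of colored connected 3-node graphs up to isomorphism
oracle_pattern_space_size <- function(types = c("disease", "drug", "gene")) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  canon <- character(0)
  for (e in 0:7) {
    edges <- as.logical(bitwAnd(e, c(1, 2, 4)))
    # connectivity of 3 nodes needs >= 2 edges (any 2 of 3 pairs connect all)
    if (sum(edges) < 2) next
    for (c1 in types) for (c2 in types) for (c3 in types) {
      cols <- c(c1, c2, c3)
      reps <- vapply(perms, function(p) {
        # relabel nodes by permutation p: new position j holds old node inv[j]
        inv <- order(p)
        eb <- vapply(seq_len(3), function(r) {
          u <- inv[pairs[r, 1]]; v <- inv[pairs[r, 2]]
          hit <- (pairs[, 1] == min(u, v)) & (pairs[, 2] == max(u, v))
          edges[which(hit)]
        }, logical(1))
        paste(c(cols[inv], as.integer(eb)), collapse = "|")
      }, character(1))
      canon <- c(canon, min(reps))
    }
  }
  length(unique(canon))
}

# small hand-built graph: two diseases, shared genes, unique genes
two_disease_fixture <- function(n_shared, n_only_a, n_only_b = 0) {
  genes <- sprintf("g%03d", seq_len(n_shared + n_only_a + n_only_b))
  shared <- genes[seq_len(n_shared)]
  only_a <- genes[n_shared + seq_len(n_only_a)]
  only_b <- if (n_only_b > 0) genes[n_shared + n_only_a + seq_len(n_only_b)] else character(0)
  edges <- tibble::tibble(
    a = c(rep("da", n_shared + n_only_a), rep("db", n_shared + n_only_b), "da"),
    b = c(shared, only_a, shared, only_b, "db")
  )
  typed_graph(
    nodes = tibble::tibble(id = c("da", "db", genes),
                           type = c("disease", "disease", rep("gene", length(genes)))),
    edges = edges
  )
}

# default-scale synthetic fixture with planted disease-disease-gene triangles
planted_fixture <- function(seed, n_planted = 30) {
  synthetic_config(
    planted = data.frame(pattern = pattern_tri(c("disease", "disease", "gene")),
                         count = n_planted),
    seed = seed
  )
}

# apply the package filter chain to a generated data set
filter_chain <- function(dat) {
  tab <- deduplicate(dat$records)
  tab <- filter_by_drug_whitelist(tab, dat$whitelist)
  tab <- restrict_to_derived_lists(tab)
  remove_stoplist_terms(tab, dat$stoplist)
}

# per-layer per-node degrees, aligned on the node table
layer_degree_sequences <- function(graph) {
  lapply(stats::setNames(layers(), layers()), function(ly) {
    e <- graph$edges[graph$edges$layer == ly, ]
    as.integer(table(factor(c(e$a, e$b), levels = graph$nodes$id)))
  })
}
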