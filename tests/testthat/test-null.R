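test_that("randomization preserves per-layer degrees and keeps graphs simple", {
  g <- random_typed_graph(60, 300, seed = 20)
  set.seed(1)
  r <- randomize_graph(g)
  expect_equal(r$nodes, g$nodes)
  expect_equal(layer_degree_sequences(r), layer_degree_sequences(g))
  expect_false(any(r$edges$a == r$edges$b))
  expect_false(anyDuplicated(paste(r$edges$a, r$edges$b)) > 0)
  expect_equal(table(factor(r$edges$layer, layers())), table(factor(g$edges$layer, layers())))
})

test_that("layers with fewer than two edges are returned unchanged", {
  g <- typed_graph(
    nodes = tibble::tibble(id = c("d1", "g1"), type = c("disease", "gene")),
    edges = tibble::tibble(a = "d1", b = "g1")
  )
  set.seed(1)
  expect_equal(randomize_graph(g)$edges, g$edges)
})

test_that("randomization is seed-deterministic", {
  g <- random_typed_graph(50, 200, seed = 21)
  set.seed(99); r1 <- randomize_graph(g)
  set.seed(99); r2 <- randomize_graph(g)
  expect_identical(r1$edges, r2$edges)
  set.seed(100); r3 <- randomize_graph(g)
  expect_false(identical(r3$edges, r1$edges))
})

test_that("the weaker null preserves only per-layer edge counts", {
  g <- random_typed_graph(50, 200, seed = 22)
  set.seed(7)
  r <- randomize_graph(g, mode = "layer_count")
  expect_equal(table(factor(r$edges$layer, layers())),
               table(factor(g$edges$layer, layers())))
  expect_false(any(r$edges$a == r$edges$b))
  expect_false(anyDuplicated(paste(r$edges$a, r$edges$b, r$edges$layer)) > 0)
})

test_that("z-scores follow the normalized-deviation definition", {
  expect_equal(zscore(10, 4, 2), 3.0)
  expect_equal(zscore(5, 5, 1), 0.0)
  expect_true(is.na(zscore(7, 2, 0)))
  expect_error(zscore(7, 2, -1), "non-negative")
})

test_that("empirical p counts exceedances under both tie conventions", {
  expect_equal(empirical_p(10, c(12, 8, 10)), 2 / 3)                          # ties count
  expect_equal(empirical_p(10, c(12, 8, 10), inequality = "greater"), 1 / 3)  # strict
  expect_equal(empirical_p(100, c(12, 8, 10)), 0)
  nulls <- c(0, 0, 3, 5, 1, 0, 2)
  expect_equal(empirical_p(0, nulls, inequality = "greater"), mean(nulls > 0))
  expect_error(empirical_p(1, integer(0)), "empty")
  # brute-force equivalence on arbitrary vectors
  set.seed(30)
  for (k in 1:20) {
    nc <- rpois(sample(3:50, 1), sample(1:20, 1))
    nr <- sample(0:25, 1)
    expect_equal(empirical_p(nr, nc, inequality = "greater"), sum(nc > nr) / length(nc))
    expect_equal(empirical_p(nr, nc), sum(nc >= nr) / length(nc))
  }
})

test_that("ensemble statistics are recomputable from the stored null counts", {
  g <- random_typed_graph(30, 100, seed = 23)
  null <- ensemble_census(g, n_networks = 10, seed = 5)
  expect_equal(ncol(null$counts), 10)
  expect_equal(null$stats$null_mean, unname(rowMeans(null$counts)))
  expect_equal(null$stats$null_sd,
               unname(apply(null$counts, 1, function(x) sqrt(mean((x - mean(x))^2)))))
  # reproducible from the seed
  null2 <- ensemble_census(g, n_networks = 10, seed = 5)
  expect_identical(null$counts, null2$counts)
})

test_that("significance needs both the count floor and the p threshold", {
  g <- random_typed_graph(30, 100, seed = 24)
  cen <- census(g)
  # hand-built null ensembles around the real counts
  fake_null <- function(counts_matrix) {
    structure(list(
      counts = counts_matrix,
      stats = tibble::tibble(pattern = rownames(counts_matrix),
                             null_mean = rowMeans(counts_matrix),
                             null_sd = apply(counts_matrix, 1, stats::sd)),
      n_networks = ncol(counts_matrix), swaps_per_edge = 100, seed = 1,
      mode = "layered_swap"), class = "motif_null")
  }
  pats <- cen$pattern
  m <- matrix(0L, nrow = length(pats), ncol = 20, dimnames = list(pats, NULL))
  sig <- call_significance(cen, fake_null(m))
  # with an all-zero null, exactly the patterns with n_real >= 5 are motifs
  expect_equal(sig$significant[match(cen$pattern, sig$pattern)], cen$count >= 5)
  expect_true(all(sig$p[sig$significant] == 0))
  # a null that always exceeds the real count kills significance
  m2 <- matrix(rep(cen$count + 1, 20), ncol = 20, dimnames = list(pats, NULL))
  sig2 <- call_significance(cen, fake_null(m2))
  expect_false(any(sig2$significant))
  expect_true(all(sig2$p == 1))
  # defined z-scores come before undefined ones
  mixed <- call_significance(cen, fake_null(
    matrix(c(rep(0L, 20), rpois(20 * (length(pats) - 1), 2)),
           nrow = length(pats), byrow = TRUE, dimnames = list(pats, NULL))))
  if (any(!is.na(mixed$z)) && any(is.na(mixed$z))) {
    expect_gt(min(which(is.na(mixed$z))), max(which(!is.na(mixed$z))))
  }
})

test_that("planted motifs stand out against the layered-swap null", {
  dat <- generate_predications(planted_fixture(seed = 77))
  g <- build_graph(filter_chain(dat))
  cen <- census(g)
  null <- ensemble_census(g, n_networks = 60, seed = 78)
  sig <- call_significance(cen, null)
  pat <- pattern_tri(c("disease", "disease", "gene"))
  row <- sig[sig$pattern == pat, ]
  expect_gte(row$n_real, 30)          # at least the planted matches
  expect_gt(row$n_real, row$null_mean)
  expect_true(row$significant)
})
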