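make_sig <- function(patterns, significant) {
  structure(tibble::tibble(
    pattern = patterns, n_real = ifelse(significant, 10, 0),
    null_mean = 0, null_sd = 1, z = 10, p = 0,
    significant = significant, reasons = ""
  ), class = c("motif_significance", class(tibble::tibble())),
  min_count = 5, alpha = 0.05, inequality = "greater")
}

test_that("the core is the union of significant-match edges with provenance", {
  g <- typed_graph(
    nodes = tibble::tibble(id = c("d1", "d2", "g1", "g2"),
                           type = c("disease", "disease", "gene", "gene")),
    edges = tibble::tibble(a = c("d1", "d1", "d2", "d1"),
                           b = c("d2", "g1", "g1", "g2"))
  )
  cen <- census(g, keep_matches = TRUE)
  m <- census_match_table(cen)
  tri_pat <- pattern_tri(c("disease", "disease", "gene"))
  sig <- make_sig(cen$pattern, cen$pattern == tri_pat)
  core <- aggregate_core(g, sig, m)
  expect_equal(nrow(core$graph$edges), 3)        # just the triangle
  expect_setequal(core$graph$nodes$id, c("d1", "d2", "g1"))
  expect_true(all(vapply(core$edge_provenance$patterns,
                         function(p) tri_pat %in% p, logical(1))))
  # no significant patterns -> empty core
  core0 <- aggregate_core(g, make_sig(cen$pattern, rep(FALSE, nrow(cen))), m)
  expect_equal(nrow(core0$graph$edges), 0)
  # significant pattern without stored matches -> instructive error
  sig2 <- make_sig("tri:drug,drug,drug", TRUE)
  expect_error(aggregate_core(g, sig2, m), "keep_matches")
})

test_that("core networks are sound subgraphs of their input", {
  dat <- generate_predications(planted_fixture(seed = 41, n_planted = 10))
  g <- build_graph(filter_chain(dat))
  cen <- census(g, keep_matches = TRUE)
  null <- ensemble_census(g, n_networks = 40, seed = 42)
  sig <- call_significance(cen, null)
  core <- aggregate_core(g, sig, census_match_table(cen))
  expect_true(all(core$graph$nodes$id %in% g$nodes$id))
  expect_true(all(paste(core$graph$edges$a, core$graph$edges$b) %in%
                    paste(g$edges$a, g$edges$b)))
  # independent membership re-scan: each core edge lies inside >= 1 match
  m <- census_match_table(cen)
  sig_m <- m[m$pattern %in% sig$pattern[sig$significant], ]
  covered <- logical(nrow(core$graph$edges))
  for (i in seq_len(nrow(sig_m))) {
    trip <- sort(c(sig_m$node_a[i], sig_m$node_b[i], sig_m$node_c[i]))
    covered <- covered | (core$graph$edges$a %in% trip & core$graph$edges$b %in% trip)
  }
  expect_true(all(covered))
  # dropping a pattern never adds edges
  fewer <- sig
  fewer$significant[which(fewer$significant)[1]] <- FALSE
  core2 <- aggregate_core(g, fewer, m)
  expect_lte(nrow(core2$graph$edges), nrow(core$graph$edges))
})

test_that("degree distributions report exact histograms and monotone CCDFs", {
  star <- typed_graph(
    nodes = tibble::tibble(id = c("hub", sprintf("d%02d", 1:6)),
                           type = c("gene", rep("disease", 6))),
    edges = tibble::tibble(a = "hub", b = sprintf("d%02d", 1:6))
  )
  dd <- degree_distribution(star, "disease", fit = FALSE)
  expect_equal(dd$histogram$n_nodes, 6)
  expect_equal(dd$histogram$degree, 1)
  expect_equal(dd$ccdf$fraction[1], 1.0)
  expect_error(degree_distribution(star, "gene"), "at least 2")
  expect_error(degree_distribution(star, "drug"), "at least 2")

  g <- random_typed_graph(60, 240, seed = 50)
  dd2 <- degree_distribution(g, "disease", fit = FALSE)
  expect_equal(sum(dd2$histogram$n_nodes), sum(g$nodes$type == "disease"))
  expect_true(all(diff(dd2$ccdf$fraction) <= 0))
})

test_that("power-law exponents are recovered from synthetic degree sequences", {
  degs <- powerlaw_degree_sequence(3000, 2.5, seed = 51)
  fit <- igraph::fit_power_law(degs[degs > 0], implementation = "plfit")
  expect_lt(abs(fit$alpha - 2.5), 0.25)
})

test_that("hub reports rank by degree with lexicographic ties", {
  g <- typed_graph(
    nodes = tibble::tibble(id = c("a", "b", "c", "g1", "g2", "g3", "g4", "g5"),
                           type = c(rep("drug", 3), rep("gene", 5))),
    edges = tibble::tibble(
      a = c(rep("a", 5), rep("b", 3), "c"),
      b = c(paste0("g", 1:5), paste0("g", 1:3), "g1")
    )
  )
  h <- hubs(g, "drug", top_k = 1)
  expect_equal(h$id, "a")
  # all-equal degrees: lexicographically first ids win
  eq <- typed_graph(
    nodes = tibble::tibble(id = c("z", "y", "x", "g1"),
                           type = c(rep("drug", 3), "gene")),
    edges = tibble::tibble(a = c("z", "y", "x"), b = "g1")
  )
  expect_equal(hubs(eq, "drug", top_k = 2)$id, c("x", "y"))
  expect_warning(hubs(eq, "disease", top_k = 1), "no nodes")
})

test_that("planted hub drugs dominate the drug hub report", {
  # two hub drugs surrounded by many diseases, plus low-degree background drugs
  n_dis <- 60
  dis <- sprintf("d%03d", seq_len(n_dis))
  edges <- tibble::tibble(
    a = c(rep("hub1", n_dis), rep("hub2", n_dis - 10), "weak1", "weak2"),
    b = c(dis, dis[1:(n_dis - 10)], dis[1], dis[2])
  )
  g <- typed_graph(
    nodes = tibble::tibble(id = c("hub1", "hub2", "weak1", "weak2", dis),
                           type = c(rep("drug", 4), rep("disease", n_dis))),
    edges = edges
  )
  expect_setequal(hubs(g, "drug", top_k = 2)$id, c("hub1", "hub2"))
})
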