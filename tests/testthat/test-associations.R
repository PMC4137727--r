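write_pred_file <- function(lines, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  hdr <- "subject_id\tsubject_type\tpredicate\tobject_id\tobject_type\tpmid"
  readr::write_lines(c(if (header) hdr, lines), path)
  path
}

test_that("predication parsing maps fields, skips headers and malformed rows", {
  path <- write_pred_file(c(
    "D001\tdisease\tASSOCIATED_WITH\tG007\tgene\t12345",
    "X1\tdrug\tTREATS\tD001\tdisease\t99",
    "broken\trow",
    "\tdisease\tASSOCIATED_WITH\tG007\tgene\t1"
  ))
  expect_warning(recs <- read_predications(path), "2 malformed")
  expect_equal(nrow(recs), 2)
  expect_equal(recs$subject_id[1], "d001")
  expect_equal(recs$object_type[1], "gene")
  expect_equal(attr(recs, "skipped"), 2L)
  expect_error(read_predications(path, strict = TRUE), "malformed")
})

test_that("empty files, unknown types and layer hints are handled", {
  empty <- write_pred_file(character(0))
  recs <- read_predications(empty)
  expect_equal(nrow(recs), 0)

  bad <- write_pred_file("D001\tplanet\tX\tG007\tgene\t1")
  expect_error(read_predications(bad), "planet")

  mixed <- write_pred_file(c(
    "d1\tdisease\tX\tg1\tgene\t1",
    "d1\tdisease\tX\td2\tdisease\t2"
  ))
  expect_warning(dg <- read_predications(mixed, layer_hint = "disease-gene"),
                 "1 malformed")
  expect_equal(nrow(dg), 1)
})

test_that("a generated fixture parses back with exact record counts", {
  dat <- generate_predications(synthetic_config(seed = 42))
  dir <- withr::local_tempdir()
  write_synthetic_data(dat, dir)
  recs <- read_predications(file.path(dir, "predications.tsv"))
  expect_equal(nrow(recs), nrow(dat$records))
  expect_equal(nrow(recs), dat$manifest$n_records)
})

test_that("deduplication collapses both argument orders and drops self-pairs", {
  recs <- tibble::tibble(
    subject_id = c("a", "b", "c"), subject_type = c("disease", "disease", "gene"),
    predicate = "X",
    object_id = c("b", "a", "c"), object_type = c("disease", "disease", "gene"),
    pmid = c("1", "2", "3")
  )
  tab <- deduplicate(recs)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$support, 2L)
  expect_equal(tab$pmids[[1]], c("1", "2"))
  expect_equal(tab$entity_a, "a")
  expect_equal(attr(tab, "dropped_self"), 1L)
})

test_that("deduplication conserves support and ignores record order", {
  dat <- generate_predications(synthetic_config(seed = 5))
  tab <- deduplicate(dat$records)
  n_self <- sum(dat$records$subject_id == dat$records$object_id)
  expect_equal(sum(tab$support), nrow(dat$records) - n_self)
  expect_equal(nrow(tab), dat$manifest$n_unique)

  shuffled <- dat$records[rev(seq_len(nrow(dat$records))), ]
  expect_equal(tibble::as_tibble(deduplicate(shuffled)), tibble::as_tibble(tab))

  # idempotence: expanding the table back into records and re-deduplicating
  expanded <- tibble::tibble(
    subject_id = rep(tab$entity_a, tab$support),
    subject_type = rep(tab$type_a, tab$support),
    predicate = "X",
    object_id = rep(tab$entity_b, tab$support),
    object_type = rep(tab$type_b, tab$support),
    pmid = unlist(lapply(seq_len(nrow(tab)), function(i) {
      p <- tab$pmids[[i]]
      p[1 + (seq_len(tab$support[i]) - 1) %% length(p)]
    }))
  )
  tab2 <- deduplicate(expanded)
  expect_equal(tab2$support, tab$support)
  expect_equal(tab2$entity_a, tab$entity_a)
  expect_equal(tab2$pmids, tab$pmids)
})

test_that("whitelist filtering requires every drug endpoint to be approved", {
  recs <- tibble::tibble(
    subject_id = c("x", "x", "d1"), subject_type = c("drug", "drug", "disease"),
    predicate = "X",
    object_id = c("g1", "y", "d2"), object_type = c("gene", "drug", "disease"),
    pmid = c("1", "2", "3")
  )
  tab <- deduplicate(recs)
  out <- filter_by_drug_whitelist(tab, "X")  # case-folded match
  expect_true(any(out$layer == "drug-gene"))       # x-g1 kept
  expect_false(any(out$layer == "drug-drug"))      # x-y dropped (y unlisted)
  expect_true(any(out$layer == "disease-disease")) # untouched layer
  expect_error(filter_by_drug_whitelist(tab, character(0)), "empty")
})

test_that("whitelist filtering matches a brute-force membership oracle", {
  dat <- generate_predications(synthetic_config(seed = 11))
  tab <- deduplicate(dat$records)
  out <- filter_by_drug_whitelist(tab, dat$whitelist)
  wl <- dat$whitelist
  keep <- vapply(seq_len(nrow(tab)), function(i) {
    ok_a <- tab$type_a[i] != "drug" || tab$entity_a[i] %in% wl
    ok_b <- tab$type_b[i] != "drug" || tab$entity_b[i] %in% wl
    ok_a && ok_b
  }, logical(1))
  expect_equal(nrow(out), sum(keep))
  expect_equal(out$entity_a, tab$entity_a[keep])
  # monotone: a subset per layer
  expect_true(all(table(factor(out$layer, layers())) <= table(factor(tab$layer, layers()))))
})

test_that("derived-list restriction keeps only drug-supported genes/diseases", {
  recs <- tibble::tibble(
    subject_id = c("x", "x", "g1", "g1", "d1"),
    subject_type = c("drug", "drug", "gene", "gene", "disease"),
    predicate = "X",
    object_id = c("g1", "d1", "g3", "d1", "d9"),
    object_type = c("gene", "disease", "gene", "disease", "disease"),
    pmid = as.character(1:5)
  )
  tab <- filter_by_drug_whitelist(deduplicate(recs), "x")
  out <- restrict_to_derived_lists(tab)
  expect_equal(attr(out, "derived_genes"), "g1")
  expect_equal(attr(out, "derived_diseases"), "d1")
  expect_false(any(out$entity_a == "g1" & out$entity_b == "g3"))  # g3 not derived
  expect_true(any(out$layer == "disease-gene"))                    # d1-g1 kept
  expect_false(any(out$entity_b == "d9"))                          # d9 not derived
})

test_that("derived-list restriction equals an independent two-pass oracle", {
  dat <- generate_predications(synthetic_config(seed = 21))
  tab <- filter_by_drug_whitelist(deduplicate(dat$records), dat$whitelist)
  out <- restrict_to_derived_lists(tab)
  ids <- c(tab$entity_a, tab$entity_b); tys <- c(tab$type_a, tab$type_b)
  lys <- c(tab$layer, tab$layer)
  genes <- unique(ids[lys == "drug-gene" & tys == "gene"])
  diseases <- unique(ids[lys == "disease-drug" & tys == "disease"])
  ok_end <- function(id, ty) (ty == "drug") | (ty == "gene" & id %in% genes) |
    (ty == "disease" & id %in% diseases)
  keep <- grepl("drug", tab$layer) |
    (ok_end(tab$entity_a, tab$type_a) & ok_end(tab$entity_b, tab$type_b))
  expect_equal(nrow(out), sum(keep))
})

test_that("stoplist removal is exact-token and case-insensitive", {
  recs <- tibble::tibble(
    subject_id = c("Protein", "proteinase"), subject_type = c("gene", "gene"),
    predicate = "X",
    object_id = c("g1", "g2"), object_type = c("gene", "gene"),
    pmid = c("1", "2")
  )
  tab <- deduplicate(recs)
  out <- remove_stoplist_terms(tab, "protein")
  expect_equal(nrow(out), 1)
  expect_equal(out$entity_b, "proteinase")  # substring must NOT match
  expect_equal(sum(attr(out, "removed_by_layer")), 1)
  expect_equal(nrow(remove_stoplist_terms(tab, character(0))), 2)  # identity
})

test_that("stoplist removal count equals a membership oracle on the fixture", {
  dat <- generate_predications(synthetic_config(seed = 31))
  tab <- restrict_to_derived_lists(
    filter_by_drug_whitelist(deduplicate(dat$records), dat$whitelist))
  out <- remove_stoplist_terms(tab, dat$stoplist)
  hit <- tab$entity_a %in% dat$stoplist | tab$entity_b %in% dat$stoplist
  expect_equal(nrow(out), nrow(tab) - sum(hit))
  expect_equal(nrow(out), dat$manifest$n_post_stoplist)
})

test_that("table stats count layers, entities and totals", {
  recs <- tibble::tibble(
    subject_id = c("d1", "d1"), subject_type = "disease", predicate = "X",
    object_id = c("g1", "g2"), object_type = "gene", pmid = c("1", "2")
  )
  st <- table_stats(deduplicate(recs))
  dg <- st[st$layer == "disease-gene", ]
  expect_equal(dg$unique_associations, 2)
  expect_equal(dg$unique_entities, 3)
  expect_equal(st$records[st$layer == "total"], 2)

  empty <- table_stats(deduplicate(recs[0, ]))
  expect_true(all(empty$unique_associations == 0))
})

test_that("association tables round-trip through TSV and export N-Triples", {
  dat <- generate_predications(synthetic_config(seed = 3))
  tab <- deduplicate(dat$records)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_associations(tab, path)
  back <- read_associations(path)
  expect_equal(tibble::as_tibble(back)[order(back$layer, back$entity_a, back$entity_b), ],
               tibble::as_tibble(tab)[, names(back)])
  nt <- withr::local_tempfile(fileext = ".nt")
  write_ntriples(tab, nt)
  lines <- readr::read_lines(nt)
  expect_length(lines, nrow(tab))
  expect_true(all(grepl("^<.*> <.*> <.*> \\.$", lines)))
})
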