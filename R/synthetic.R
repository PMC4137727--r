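#' Configuration for the synthetic predication generator
#'
#' Describes a literature-style association snapshot at desk scale: three
#' node populations, six association layers with heavy-tailed wiring,
#' redundant records (the same pair asserted many times under different
#' PMIDs and argument orders), contamination by generic terms, an
#' approved-drug whitelist covering part of the drug population, and
#' optionally planted motif matches on reserved nodes with known ground
#' truth.
#'
#' Defaults define the package's reference study conditions: 300 diseases,
#' 100 drugs and 300 genes; a ~2,000-edge background whose per-layer sizes
#' keep the relative proportions of a filtered literature snapshot
#' (disease-drug by far the largest layer, drug-drug the smallest);
#' mean redundancy 2.5 records per unique association; 40% of drugs
#' whitelisted; 25 generic contaminant terms; power-law weight exponent 2.5.
#'
#' @param nodes_per_type named integer vector over `disease`, `drug`, `gene`.
#' @param edges_per_layer named integer vector over the six [layers()]
#'   (background edges, before planting/contamination).
#' @param redundancy mean records per unique association (`>= 1`).
#' @param stoplist_contamination number of generic-term nodes wired into the
#'   stream.
#' @param planted `NULL`, or a data frame `pattern`, `count` of motif
#'   matches to plant on reserved nodes.
#' @param degree_model `"powerlaw"` (heavy-tailed endpoint sampling weights)
#'   or `"uniform"`.
#' @param pl_exponent exponent of the power-law weights (`> 1`).
#' @param whitelist_fraction fraction of background drugs whitelisted,
#'   in `(0, 1]`.
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(nodes_per_type = c(disease = 300, drug = 100, gene = 300),
                             edges_per_layer = c("disease-disease" = 40,
                                                 "disease-drug" = 1310,
                                                 "disease-gene" = 510,
                                                 "drug-drug" = 6,
                                                 "drug-gene" = 90,
                                                 "gene-gene" = 50),
                             redundancy = 2.5,
                             stoplist_contamination = 25,
                             planted = NULL,
                             degree_model = c("powerlaw", "uniform"),
                             pl_exponent = 2.5,
                             whitelist_fraction = 0.4,
                             seed = 1L) {
  degree_model <- match.arg(degree_model)
  stopifnot(all(entity_types() %in% names(nodes_per_type)),
            all(layers() %in% names(edges_per_layer)),
            redundancy >= 1, whitelist_fraction > 0, whitelist_fraction <= 1,
            pl_exponent > 1, stoplist_contamination >= 0)
  nodes_per_type <- nodes_per_type[entity_types()]
  edges_per_layer <- edges_per_layer[layers()]
  for (ly in layers()) {
    tys <- layer_types(ly)[[1]]
    max_m <- if (tys[1] == tys[2]) choose(nodes_per_type[[tys[1]]], 2) else
      nodes_per_type[[tys[1]]] * nodes_per_type[[tys[2]]]
    if (edges_per_layer[[ly]] > max_m) {
      stop("infeasible config: layer ", ly, " requests ", edges_per_layer[[ly]],
           " edges but at most ", max_m, " simple edges exist", call. = FALSE)
    }
  }
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted), all(c("pattern", "count") %in% names(planted)),
              all(planted$count >= 0))
    bad <- setdiff(planted$pattern, pattern_space()$pattern)
    if (length(bad)) stop("unknown planted pattern(s): ", paste(bad, collapse = ", "))
  }
  structure(list(nodes_per_type = nodes_per_type,
                 edges_per_layer = edges_per_layer,
                 redundancy = redundancy,
                 stoplist_contamination = stoplist_contamination,
                 planted = planted,
                 degree_model = degree_model,
                 pl_exponent = pl_exponent,
                 whitelist_fraction = whitelist_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Discrete power-law degree sequence
#'
#' Samples `n` degrees from the discrete power law (zeta distribution,
#' `P(K = k) proportional to k^-exponent`, lower cutoff 1) by
#' inverse-transform sampling of the exact probability table, truncated at
#' `n - 1` since no simple graph supports larger degrees. The total is
#' adjusted to an even sum so the sequence is realizable as a graph.
#'
#' @param n sequence length (`>= 10`).
#' @param exponent power-law exponent (`> 1`).
#' @param seed optional seed for reproducibility.
#' @return Integer vector of `n` degrees with even sum.
#' @export
powerlaw_degree_sequence <- function(n, exponent, seed = NULL) {
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  if (exponent <= 1) stop("exponent must exceed 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cdf <- cumsum(seq_len(n - 1)^(-exponent))
  cdf <- cdf / cdf[length(cdf)]
  x <- findInterval(stats::runif(n), cdf) + 1L
  if (sum(x) %% 2 == 1) {
    k <- sample.int(n, 1)
    x[k] <- x[k] + 1L
  }
  x
}

# endpoint-sampling weights for one node pool
sampling_weights <- function(n, model, exponent) {
  if (model == "uniform") rep(1, n) else {
    sample(seq_len(n))^(-1 / (exponent - 1))
  }
}

# sample m distinct simple edges between two pools (possibly the same)
sample_layer_edges <- function(pool_a, pool_b, m, w_a, w_b) {
  if (m == 0) return(tibble::tibble(a = character(0), b = character(0)))
  seen <- character(0)
  out_a <- character(0); out_b <- character(0)
  while (length(out_a) < m) {
    k <- max(2 * (m - length(out_a)), 16)
    u <- sample(pool_a, k, replace = TRUE, prob = w_a)
    v <- sample(pool_b, k, replace = TRUE, prob = w_b)
    ok <- u != v
    u <- u[ok]; v <- v[ok]
    a <- pmin(u, v); b <- pmax(u, v)
    key <- edge_key(a, b)
    fresh <- !duplicated(key) & !(key %in% seen)
    a <- a[fresh]; b <- b[fresh]
    take <- seq_len(min(length(a), m - length(out_a)))
    out_a <- c(out_a, a[take]); out_b <- c(out_b, b[take])
    seen <- c(seen, edge_key(a[take], b[take]))
  }
  tibble::tibble(a = out_a, b = out_b)
}

#' Generate a synthetic predication stream with ground truth
#'
#' Emits the full desk-scale input set for the pipeline — a predication
#' record stream, a drug whitelist and a generic-term stoplist — together
#' with a ground-truth manifest recording every quantity the pipeline
#' should reproduce (per-layer record and unique-association counts,
#' expected survivors after each filtering stage, planted match triples).
#' Planted matches are wired on reserved nodes untouched by background
#' wiring, and every reserved disease/gene is tethered to a whitelisted
#' background drug so planted structures survive the whitelist and
#' derived-list filters by construction; planted counts are therefore
#' guaranteed lower bounds on census counts.
#'
#' @param config a [synthetic_config()].
#' @return A list: `records` (predication tibble in stream order),
#'   `whitelist`, `stoplist` (character vectors), `manifest` (list, see
#'   details), `truth_edges` (the unique association tibble before
#'   redundancy expansion).
#' @export
generate_predications <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  npt <- config$nodes_per_type
  ids <- list(
    disease = sprintf("dis%04d", seq_len(npt[["disease"]])),
    drug    = sprintf("drug%04d", seq_len(npt[["drug"]])),
    gene    = sprintf("gene%04d", seq_len(npt[["gene"]]))
  )

  # --- planted motifs on reserved nodes -------------------------------------
  planted_edges <- tibble::tibble(a = character(0), b = character(0),
                                  ta = character(0), tb = character(0))
  planted_triples <- tibble::tibble(pattern = character(0), node_a = character(0),
                                    node_b = character(0), node_c = character(0))
  reserved_nonu <- character(0)  # reserved diseases/genes needing drug support
  reserved_drugs <- character(0)
  counter <- c(disease = 0L, drug = 0L, gene = 0L)
  if (!is.null(config$planted)) {
    space <- pattern_space()
    for (r in seq_len(nrow(config$planted))) {
      pat <- config$planted$pattern[r]
      row <- space[space$pattern == pat, ]
      for (inst in seq_len(config$planted$count[r])) {
        tys <- strsplit(row$types, ",", fixed = TRUE)[[1]]
        if (row$topology == "path") {
          center <- row$center
          # remove one instance of the centre type to recover the leaves
          leaves <- tys[-match(center, tys)]
          ord_types <- c(center, leaves)
        } else {
          ord_types <- tys
        }
        mint <- function(t) {
          counter[[t]] <<- counter[[t]] + 1L
          sprintf("p%s%04d", t, counter[[t]])
        }
        nd <- vapply(ord_types, mint, character(1))
        if (row$topology == "tri") {
          pe <- tibble::tibble(a = nd[c(1, 1, 2)], b = nd[c(2, 3, 3)],
                               ta = ord_types[c(1, 1, 2)], tb = ord_types[c(2, 3, 3)])
        } else {
          pe <- tibble::tibble(a = nd[c(1, 1)], b = nd[c(2, 3)],
                               ta = ord_types[c(1, 1)], tb = ord_types[c(2, 3)])
        }
        planted_edges <- dplyr::bind_rows(planted_edges, pe)
        trip <- sort(nd)
        planted_triples <- dplyr::bind_rows(planted_triples, tibble::tibble(
          pattern = pat, node_a = trip[1], node_b = trip[2], node_c = trip[3]))
        reserved_nonu <- c(reserved_nonu, nd[ord_types != "drug"])
        reserved_drugs <- c(reserved_drugs, nd[ord_types == "drug"])
      }
    }
  }

  # --- whitelist ------------------------------------------------------------
  n_wl <- max(1L, floor(config$whitelist_fraction * npt[["drug"]]))
  whitelist <- sort(c(sample(ids$drug, n_wl), reserved_drugs))

  # support tether: every reserved disease/gene to one whitelisted background drug
  wl_background <- setdiff(whitelist, reserved_drugs)
  support_edges <- tibble::tibble(a = character(0), b = character(0),
                                  ta = character(0), tb = character(0))
  if (length(reserved_nonu)) {
    sup_drug <- sample(wl_background, length(reserved_nonu), replace = TRUE)
    sup_type <- ifelse(grepl("^pdis", reserved_nonu), "disease", "gene")
    support_edges <- tibble::tibble(a = reserved_nonu, b = sup_drug,
                                    ta = sup_type, tb = "drug")
  }

  # --- background layers ----------------------------------------------------
  weights <- lapply(entity_types(), function(t) {
    sampling_weights(npt[[t]], config$degree_model, config$pl_exponent)
  })
  names(weights) <- entity_types()
  background <- list()
  for (ly in layers()) {
    tys <- layer_types(ly)[[1]]
    e <- sample_layer_edges(ids[[tys[1]]], ids[[tys[2]]],
                            config$edges_per_layer[[ly]],
                            weights[[tys[1]]], weights[[tys[2]]])
    ta <- ifelse(grepl("^dis", e$a), "disease", ifelse(grepl("^drug", e$a), "drug", "gene"))
    tb <- ifelse(grepl("^dis", e$b), "disease", ifelse(grepl("^drug", e$b), "drug", "gene"))
    background[[ly]] <- tibble::tibble(a = e$a, b = e$b, ta = ta, tb = tb)
  }
  background <- dplyr::bind_rows(background)

  # --- generic-term contamination -------------------------------------------
  stock <- c("gene", "protein", "homologous gene", "cells", "dna", "enzyme")
  n_stop <- config$stoplist_contamination
  stoplist <- character(0)
  stop_edges <- tibble::tibble(a = character(0), b = character(0),
                               ta = character(0), tb = character(0))
  if (n_stop > 0) {
    stoplist <- c(utils::head(stock, n_stop),
                  if (n_stop > length(stock)) sprintf("generic%03d", seq_len(n_stop - length(stock))))
    stop_type <- sample(entity_types(), n_stop, replace = TRUE)
    rows <- list()
    for (k in seq_len(n_stop)) {
      deg <- sample(1:3, 1)
      partner_type <- sample(entity_types(), deg, replace = TRUE)
      partners <- vapply(partner_type, function(t) sample(ids[[t]], 1), character(1))
      rows[[k]] <- tibble::tibble(a = stoplist[k], b = partners,
                                  ta = stop_type[k], tb = partner_type)
    }
    stop_edges <- dplyr::bind_rows(rows)
    stop_edges <- stop_edges[stop_edges$a != stop_edges$b, , drop = FALSE]
  }

  # --- assemble unique associations ----------------------------------------
  all_edges <- dplyr::bind_rows(planted_edges, support_edges, background, stop_edges)
  flip <- all_edges$a > all_edges$b
  tmp <- all_edges$a[flip]; all_edges$a[flip] <- all_edges$b[flip]; all_edges$b[flip] <- tmp
  tmp <- all_edges$ta[flip]; all_edges$ta[flip] <- all_edges$tb[flip]; all_edges$tb[flip] <- tmp
  all_edges$layer <- layer_name(all_edges$ta, all_edges$tb)
  all_edges <- dplyr::distinct(all_edges, .data$a, .data$b, .keep_all = TRUE)

  # --- redundancy expansion into records ------------------------------------
  n_assoc <- nrow(all_edges)
  reps <- 1L + stats::rpois(n_assoc, config$redundancy - 1)
  idx <- rep(seq_len(n_assoc), reps)
  swap <- stats::runif(length(idx)) < 0.5
  preds <- sample(c("ASSOCIATED_WITH", "TREATS", "INTERACTS_WITH", "COEXISTS_WITH"),
                  length(idx), replace = TRUE)
  records <- tibble::tibble(
    subject_id = ifelse(swap, all_edges$b[idx], all_edges$a[idx]),
    subject_type = ifelse(swap, all_edges$tb[idx], all_edges$ta[idx]),
    predicate = preds,
    object_id = ifelse(swap, all_edges$a[idx], all_edges$b[idx]),
    object_type = ifelse(swap, all_edges$ta[idx], all_edges$tb[idx]),
    pmid = as.character(10000000L + seq_along(idx))
  )
  records <- records[sample.int(nrow(records)), , drop = FALSE]

  manifest <- build_manifest(all_edges, records, whitelist, stoplist,
                             planted_triples, config)
  list(records = records, whitelist = whitelist, stoplist = stoplist,
       manifest = manifest, truth_edges = all_edges)
}

# ground-truth filter-chain bookkeeping, by plain set logic over the unique
# edge table (the oracle the pipeline's stage counts are audited against)
build_manifest <- function(edges, records, whitelist, stoplist, planted_triples,
                           config) {
  count_by_layer <- function(e) {
    as.list(table(factor(e$layer, levels = layers())))
  }
  rec_layer <- layer_name(records$subject_type, records$object_type)
  drug_ok <- function(e) {
    (e$ta != "drug" | e$a %in% whitelist) & (e$tb != "drug" | e$b %in% whitelist)
  }
  post_wl <- edges[drug_ok(edges), , drop = FALSE]
  genes <- unique(c(post_wl$a[post_wl$layer == "drug-gene" & post_wl$ta == "gene"],
                    post_wl$b[post_wl$layer == "drug-gene" & post_wl$tb == "gene"]))
  diseases <- unique(c(post_wl$a[post_wl$layer == "disease-drug" & post_wl$ta == "disease"],
                       post_wl$b[post_wl$layer == "disease-drug" & post_wl$tb == "disease"]))
  in_list <- function(id, ty) ifelse(ty == "gene", id %in% genes,
                                     ifelse(ty == "disease", id %in% diseases, TRUE))
  drug_ly <- c("disease-drug", "drug-drug", "drug-gene")
  post_dl <- post_wl[post_wl$layer %in% drug_ly |
                       (in_list(post_wl$a, post_wl$ta) & in_list(post_wl$b, post_wl$tb)), ,
                     drop = FALSE]
  post_sl <- post_dl[!(post_dl$a %in% stoplist | post_dl$b %in% stoplist), , drop = FALSE]
  list(
    seed = config$seed,
    n_records = nrow(records),
    records_per_layer = as.list(table(factor(rec_layer, levels = layers()))),
    unique_per_layer = count_by_layer(edges),
    n_unique = nrow(edges),
    post_whitelist_per_layer = count_by_layer(post_wl),
    n_post_whitelist = nrow(post_wl),
    derived_genes = sort(genes),
    derived_diseases = sort(diseases),
    post_derived_per_layer = count_by_layer(post_dl),
    n_post_derived = nrow(post_dl),
    post_stoplist_per_layer = count_by_layer(post_sl),
    n_post_stoplist = nrow(post_sl),
    n_entities = length(unique(c(edges$a, edges$b))),
    n_entities_final = length(unique(c(post_sl$a, post_sl$b))),
    whitelist = whitelist,
    stoplist = stoplist,
    planted = planted_triples
  )
}

#' Write a synthetic data set to disk
#'
#' Emits `predications.tsv` (header + one record per row in the dialect
#' read by [read_predications()]), `whitelist.txt`, `stoplist.txt` (one
#' token per line) and `manifest.yaml`.
#'
#' @param data result of [generate_predications()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_data <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(data$records, file.path(dir, "predications.tsv"))
  readr::write_lines(data$whitelist, file.path(dir, "whitelist.txt"))
  readr::write_lines(data$stoplist, file.path(dir, "stoplist.txt"))
  manifest <- data$manifest
  manifest$planted <- as.list(manifest$planted)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
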