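#' Run the full motif-analysis pipeline
#'
#' Orchestrates every stage — record ingest, deduplication, whitelist and
#' derived-list filtering, stoplist removal, graph construction, colored
#' motif census, null-ensemble significance, core-network aggregation and
#' per-type degree/hub reports — and returns a run report whose stage
#' counts form the audit trail of the filtering chain.
#'
#' All randomness flows from `seed`; reruns with the same inputs and seed
#' reproduce the significance table exactly.
#'
#' @param records a predication record tibble ([read_predications()] /
#'   [generate_predications()]`$records`), or a path to a predication TSV.
#' @param whitelist character vector of approved drug tokens, or a path to
#'   a one-token-per-line file.
#' @param stoplist character vector of generic terms (or file path); may be
#'   empty.
#' @param n_networks,swaps_per_edge null-ensemble settings
#'   ([ensemble_census()]).
#' @param min_count,alpha significance thresholds ([call_significance()]).
#' @param seed root seed for the null ensemble.
#' @param top_k_hubs hubs reported per entity type.
#' @param fit_degree if `TRUE` (default), fit power-law degree
#'   distributions per type on the core network when it is large enough.
#' @param out_dir optional directory; when given, intermediate artifacts
#'   (association tables, edge lists, significance and census TSVs) are
#'   written there.
#' @return A `hetmotif_run` list: `stage_counts` (tibble `stage`, `layer`,
#'   `n`), `stats` (final [table_stats()]), `graph`, `census`,
#'   `significance`, `core`, `degree` (list per type or NULL),
#'   `hubs` (list per type), `config` (echo of all settings), `version`.
#' @export
run_pipeline <- function(records, whitelist, stoplist = character(0),
                         n_networks = 1000, swaps_per_edge = 100,
                         min_count = 5, alpha = 0.05, seed = 1L,
                         top_k_hubs = 10, fit_degree = TRUE, out_dir = NULL) {
  if (is.character(records) && length(records) == 1) {
    records <- read_predications(records)
  }
  if (is.character(whitelist) && length(whitelist) == 1 && file.exists(whitelist)) {
    whitelist <- readr::read_lines(whitelist)
  }
  if (is.character(stoplist) && length(stoplist) == 1 && file.exists(stoplist)) {
    stoplist <- readr::read_lines(stoplist)
  }
  stage_count <- function(stage, table) {
    per <- table(factor(table$layer, levels = layers()))
    tibble::tibble(stage = stage,
                   layer = c(layers(), "total"),
                   n = c(as.integer(per), nrow(table)))
  }
  counts <- list()
  counts$records <- tibble::tibble(
    stage = "records",
    layer = c(layers(), "total"),
    n = c(as.integer(table(factor(layer_name(records$subject_type, records$object_type),
                                  levels = layers()))), nrow(records))
  )
  tab <- deduplicate(records)
  counts$unique <- stage_count("unique_associations", tab)
  tab_wl <- filter_by_drug_whitelist(tab, whitelist)
  counts$wl <- stage_count("post_whitelist", tab_wl)
  tab_dl <- restrict_to_derived_lists(tab_wl)
  counts$dl <- stage_count("post_derived_list", tab_dl)
  tab_sl <- remove_stoplist_terms(tab_dl, stoplist)
  counts$sl <- stage_count("post_stoplist", tab_sl)
  stage_counts <- dplyr::bind_rows(counts)

  graph <- build_graph(tab_sl)
  cen <- census(graph, keep_matches = TRUE)
  null <- ensemble_census(graph, n_networks = n_networks,
                          swaps_per_edge = swaps_per_edge, seed = seed)
  sig <- call_significance(cen, null, min_count = min_count, alpha = alpha)
  core <- aggregate_core(graph, sig, census_match_table(cen))

  degree <- NULL
  hub_reports <- list()
  for (t in entity_types()) {
    n_t <- sum(core$graph$nodes$type == t)
    if (n_t >= 1) {
      hub_reports[[t]] <- hubs(core, t, top_k = top_k_hubs)
    }
    if (fit_degree && n_t >= 2) {
      degree[[t]] <- degree_distribution(core, t)
    }
  }

  run <- structure(list(
    stage_counts = stage_counts,
    stats = table_stats(tab_sl),
    graph = graph, census = cen, significance = sig, core = core,
    degree = degree, hubs = hub_reports,
    config = list(n_networks = n_networks, swaps_per_edge = swaps_per_edge,
                  min_count = min_count, alpha = alpha, seed = seed,
                  top_k_hubs = top_k_hubs),
    version = as.character(utils::packageVersion("hetmotif"))
  ), class = "hetmotif_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_associations(tab_sl, file.path(out_dir, "associations.tsv"))
    write_edgelist(graph, file.path(out_dir, "graph.tsv"))
    write_edgelist(core$graph, file.path(out_dir, "core.tsv"))
    readr::write_tsv(tibble::as_tibble(cen), file.path(out_dir, "census.tsv"))
    readr::write_tsv(tibble::as_tibble(sig), file.path(out_dir, "significance.tsv"))
    readr::write_tsv(stage_counts, file.path(out_dir, "stage_counts.tsv"))
  }
  run
}

#' @export
print.hetmotif_run <- function(x, ...) {
  cat("<hetmotif_run> hetmotif ", x$version, "\n", sep = "")
  tot <- x$stage_counts[x$stage_counts$layer == "total", ]
  cat("  stages: ", paste(sprintf("%s=%d", tot$stage, tot$n), collapse = " -> "), "\n", sep = "")
  cat("  graph: ", nrow(x$graph$nodes), " nodes / ", nrow(x$graph$edges), " edges; core: ",
      nrow(x$core$graph$nodes), " nodes / ", nrow(x$core$graph$edges), " edges\n", sep = "")
  cat("  significant motifs: ", sum(x$significance$significant), "\n", sep = "")
  invisible(x)
}

#' Compare motif calls across layer-restricted networks
#'
#' Runs census + null-ensemble significance independently on each
#' layer-restricted subgraph (e.g. the full network versus the disease-gene
#' network alone) and tabulates which patterns are significant where. A
#' pattern needing an edge layer absent from a restricted network can never
#' be significant there, so full-network motifs are generally not all
#' recoverable from two-type subnetworks.
#'
#' @param graph a [typed_graph].
#' @param layer_sets named list (length `>= 2`) of layer-name vectors; the
#'   names label the comparison columns.
#' @param n_networks,swaps_per_edge,min_count,alpha,seed significance
#'   settings as in [run_pipeline()].
#' @return A tibble with `pattern` plus one logical column per layer set.
#' @export
compare_layer_censuses <- function(graph, layer_sets, n_networks = 200,
                                   swaps_per_edge = 100, min_count = 5,
                                   alpha = 0.05, seed = 1L) {
  stopifnot(inherits(graph, "typed_graph"), length(layer_sets) >= 2)
  if (is.null(names(layer_sets)) || any(names(layer_sets) == "")) {
    names(layer_sets) <- paste0("network_", seq_along(layer_sets))
  }
  out <- tibble::tibble(pattern = pattern_space()$pattern)
  for (nm in names(layer_sets)) {
    sub <- subgraph_by_layers(graph, layer_sets[[nm]])
    cen <- census(sub)
    null <- ensemble_census(sub, n_networks = n_networks,
                            swaps_per_edge = swaps_per_edge, seed = seed)
    sig <- call_significance(cen, null, min_count = min_count, alpha = alpha)
    out[[nm]] <- sig$significant[match(out$pattern, sig$pattern)]
  }
  out
}
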