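#' Read literature predication records
#'
#' Parses a tab-separated predication export: one subject-predicate-object
#' assertion per row with its source PubMed id, in the column order
#' `subject_id`, `subject_type`, `predicate`, `object_id`, `object_type`,
#' `pmid` (a leading header row with these names is skipped). Entity ids are
#' case-folded and whitespace-trimmed, so identity is the normalised token.
#'
#' @param path path to a TSV predication file.
#' @param layer_hint optional layer name; when given, rows whose endpoint
#'   types do not match the layer are treated as malformed.
#' @param strict if `TRUE`, any malformed row aborts the read; by default
#'   malformed rows are skipped with a warning naming their line numbers.
#' @return A tibble of records: `subject_id`, `subject_type`, `predicate`,
#'   `object_id`, `object_type`, `pmid`, with a `skipped` attribute giving
#'   the number of malformed rows dropped.
#' @export
read_predications <- function(path, layer_hint = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cols <- c("subject_id", "subject_type", "predicate",
            "object_id", "object_type", "pmid")
  lines <- readr::read_lines(path)
  if (length(lines) && grepl("^subject_id\t", lines[[1]])) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- tibble::as_tibble(stats::setNames(rep(list(character(0)), 6), cols))
    attr(out, "skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf >= 6L
  recs <- NULL
  if (any(ok)) {
    m <- do.call(rbind, lapply(fields[ok], function(x) x[1:6]))
    recs <- tibble::as_tibble(stats::setNames(as.data.frame(m, stringsAsFactors = FALSE), cols))
    recs$subject_id <- normalize_id(recs$subject_id)
    recs$object_id <- normalize_id(recs$object_id)
    recs$subject_type <- normalize_id(recs$subject_type)
    recs$object_type <- normalize_id(recs$object_type)
    bad_type <- !(recs$subject_type %in% entity_types()) |
      !(recs$object_type %in% entity_types())
    if (any(bad_type)) {
      offenders <- setdiff(unique(c(recs$subject_type, recs$object_type)), entity_types())
      stop("unknown entity type(s) in ", path, ": ",
           paste(offenders, collapse = ", "), call. = FALSE)
    }
    bad_row <- recs$subject_id == "" | recs$object_id == "" | recs$pmid == ""
    if (!is.null(layer_hint)) {
      check_layers(layer_hint)
      bad_row <- bad_row |
        layer_name(recs$subject_type, recs$object_type) != layer_hint
    }
    ok[ok] <- !bad_row
    recs <- recs[!bad_row, , drop = FALSE]
  }
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    msg <- paste0(n_skip, " malformed row(s) in ", basename(path),
                  " at line(s) ", paste(utils::head(which(!ok), 10), collapse = ", "),
                  if (n_skip > 10) ", ...")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (is.null(recs)) {
    recs <- tibble::as_tibble(stats::setNames(rep(list(character(0)), 6), cols))
  }
  attr(recs, "skipped") <- n_skip
  recs
}

#' Collapse redundant records into unique undirected associations
#'
#' The same entity pair is typically asserted many times across the
#' literature (and in both argument orders). This collapses a record stream
#' into one row per unordered entity pair per layer, with the number of
#' contributing records as `support` and the set of distinct source PMIDs.
#' Records relating an entity to itself are dropped and counted.
#'
#' @param records a record tibble as returned by [read_predications()].
#' @return An association table: a tibble with columns `layer`, `entity_a`,
#'   `entity_b` (canonical order: `entity_a < entity_b` lexicographically),
#'   `type_a`, `type_b`, `support`, `pmids` (list column of character
#'   vectors), sorted by layer then pair. The number of dropped
#'   self-associations is in the `dropped_self` attribute.
#' @export
deduplicate <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(empty_assoc_table(dropped = 0L))
  records$subject_id <- normalize_id(records$subject_id)
  records$object_id <- normalize_id(records$object_id)
  records$subject_type <- normalize_id(records$subject_type)
  records$object_type <- normalize_id(records$object_type)
  self <- records$subject_id == records$object_id
  n_self <- sum(self)
  r <- records[!self, , drop = FALSE]
  if (nrow(r) == 0) return(empty_assoc_table(dropped = n_self))
  flip <- r$subject_id > r$object_id
  a <- ifelse(flip, r$object_id, r$subject_id)
  b <- ifelse(flip, r$subject_id, r$object_id)
  ta <- ifelse(flip, r$object_type, r$subject_type)
  tb <- ifelse(flip, r$subject_type, r$object_type)
  tab <- tibble::tibble(
    layer = layer_name(ta, tb),
    entity_a = a, entity_b = b, type_a = ta, type_b = tb, pmid = r$pmid
  ) |>
    dplyr::group_by(.data$layer, .data$entity_a, .data$entity_b,
                    .data$type_a, .data$type_b) |>
    dplyr::summarise(support = dplyr::n(),
                     pmids = list(sort(unique(.data$pmid))),
                     .groups = "drop") |>
    dplyr::arrange(.data$layer, .data$entity_a, .data$entity_b)
  as_assoc_table(tab, dropped = n_self)
}

empty_assoc_table <- function(dropped = 0L) {
  as_assoc_table(tibble::tibble(
    layer = character(0), entity_a = character(0), entity_b = character(0),
    type_a = character(0), type_b = character(0),
    support = integer(0), pmids = list()
  ), dropped = dropped)
}

as_assoc_table <- function(x, dropped = NULL) {
  if (!is.null(dropped)) attr(x, "dropped_self") <- dropped
  class(x) <- unique(c("assoc_table", class(x)))
  x
}

# carry attributes/class through a dplyr::filter on an assoc table
keep_assoc <- function(table, keep) {
  out <- table[keep, , drop = FALSE]
  attr(out, "dropped_self") <- attr(table, "dropped_self")
  as_assoc_table(out)
}

#' Restrict drug-containing layers to an approved-drug whitelist
#'
#' Keeps, within the drug-drug, drug-gene and drug-disease layers, only the
#' associations whose drug endpoint(s) all appear on the whitelist (both
#' endpoints for drug-drug). Emulates restricting literature associations to
#' FDA-approved drugs; the other three layers are untouched here.
#'
#' @param table an association table from [deduplicate()].
#' @param whitelist character vector of approved drug tokens (case-folded
#'   and trimmed before matching). Must be non-empty.
#' @return The filtered association table.
#' @export
filter_by_drug_whitelist <- function(table, whitelist) {
  stopifnot(inherits(table, "assoc_table"))
  whitelist <- unique(normalize_id(whitelist))
  whitelist <- whitelist[nzchar(whitelist)]
  if (length(whitelist) == 0) {
    stop("empty drug whitelist would silently empty three layers", call. = FALSE)
  }
  drug_ok <- function(id, type) type != "drug" | id %in% whitelist
  keep <- drug_ok(table$entity_a, table$type_a) &
    drug_ok(table$entity_b, table$type_b)
  keep_assoc(table, keep)
}

#' Restrict remaining layers to drug-derived gene and disease lists
#'
#' After whitelist filtering, the genes of interest are those appearing in
#' surviving drug-gene associations and the diseases those in surviving
#' drug-disease associations. Gene-gene, disease-disease and disease-gene
#' associations are kept only when every endpoint belongs to the
#' corresponding derived list.
#'
#' @param table an association table whose drug layers have already been
#'   whitelist-filtered.
#' @return The filtered table, with the derived lists attached as attributes
#'   `derived_genes` and `derived_diseases`.
#' @export
restrict_to_derived_lists <- function(table) {
  stopifnot(inherits(table, "assoc_table"))
  ids <- c(table$entity_a, table$entity_b)
  tys <- c(table$type_a, table$type_b)
  lys <- c(table$layer, table$layer)
  genes <- unique(ids[lys == "drug-gene" & tys == "gene"])
  diseases <- unique(ids[lys == "disease-drug" & tys == "disease"])
  in_list <- function(id, type) {
    ifelse(type == "gene", id %in% genes,
           ifelse(type == "disease", id %in% diseases, TRUE))
  }
  drug_layers <- c("disease-drug", "drug-drug", "drug-gene")
  keep <- table$layer %in% drug_layers |
    (in_list(table$entity_a, table$type_a) & in_list(table$entity_b, table$type_b))
  out <- keep_assoc(table, keep)
  attr(out, "derived_genes") <- sort(genes)
  attr(out, "derived_diseases") <- sort(diseases)
  out
}

#' Remove associations touching generic stoplist terms
#'
#' Literature-mined tables contain generic, nonsensical entities ("gene",
#' "protein", "homologous gene", ...). Any association with a stoplisted
#' endpoint is removed. Matching is exact-token and case-insensitive — never
#' substring, so "proteinase" survives a "protein" stoplist.
#'
#' @param table an association table.
#' @param stoplist character vector of generic terms (may be empty).
#' @return The filtered table; per-layer removal counts are attached as the
#'   `removed_by_layer` attribute.
#' @export
remove_stoplist_terms <- function(table, stoplist) {
  stopifnot(inherits(table, "assoc_table"))
  stoplist <- unique(normalize_id(stoplist))
  stoplist <- stoplist[nzchar(stoplist)]
  hit <- table$entity_a %in% stoplist | table$entity_b %in% stoplist
  removed <- table$layer[hit]
  out <- keep_assoc(table, !hit)
  attr(out, "removed_by_layer") <- table(factor(removed, levels = layers()))
  out
}

#' Per-layer association statistics
#'
#' Summarises an association table the way the source snapshots are usually
#' reported: per layer, the number of raw records (sum of supports), unique
#' associations and unique entities, plus a `total` row in which entities
#' shared between layers are counted once.
#'
#' @param table an association table.
#' @return A tibble with columns `layer`, `records`, `unique_associations`,
#'   `unique_entities`; the final row has `layer == "total"`.
#' @export
table_stats <- function(table) {
  stopifnot(inherits(table, "assoc_table"))
  per <- lapply(layers(), function(ly) {
    rows <- table$layer == ly
    tibble::tibble(
      layer = ly,
      records = sum(table$support[rows]),
      unique_associations = sum(rows),
      unique_entities = length(unique(c(table$entity_a[rows], table$entity_b[rows])))
    )
  })
  per <- dplyr::bind_rows(per)
  dplyr::bind_rows(per, tibble::tibble(
    layer = "total",
    records = sum(table$support),
    unique_associations = nrow(table),
    unique_entities = length(unique(c(table$entity_a, table$entity_b)))
  ))
}

#' Write or read unique-association tables
#'
#' The on-disk dialect is TSV with columns `layer`, `entity_a`, `entity_b`,
#' `type_a`, `type_b`, `support`, `pmid_list` (PMIDs joined by `|`);
#' round-trips exactly.
#'
#' @param table an association table.
#' @param path output/input file path.
#' @return `write_associations()` returns `path` invisibly;
#'   `read_associations()` returns the association table.
#' @export
write_associations <- function(table, path) {
  stopifnot(inherits(table, "assoc_table"))
  flat <- dplyr::mutate(tibble::as_tibble(table),
                        pmid_list = vapply(.data$pmids, paste, character(1), collapse = "|"),
                        pmids = NULL)
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_associations
#' @export
read_associations <- function(path) {
  flat <- readr::read_tsv(path, col_types = readr::cols(
    layer = "c", entity_a = "c", entity_b = "c", type_a = "c", type_b = "c",
    support = "i", pmid_list = "c"
  ))
  flat$pmids <- strsplit(ifelse(is.na(flat$pmid_list), "", flat$pmid_list), "|", fixed = TRUE)
  flat$pmid_list <- NULL
  as_assoc_table(flat, dropped = 0L)
}

#' Export unique associations as N-Triples
#'
#' A minimal linked-data view: one triple per unique association, with
#' subject/object URIs minted from the entity tokens and the predicate URI
#' from the layer name.
#'
#' @param table an association table.
#' @param path output file path.
#' @param base URI prefix for minted entity and predicate URIs.
#' @return `path`, invisibly.
#' @export
write_ntriples <- function(table, path,
                           base = "http://example.org/hetmotif/") {
  stopifnot(inherits(table, "assoc_table"))
  uri <- function(x) paste0("<", base, "entity/", utils::URLencode(x, reserved = TRUE), ">")
  pred <- paste0("<", base, "assoc/", table$layer, ">")
  lines <- paste(uri(table$entity_a), pred, uri(table$entity_b), ".")
  readr::write_lines(lines, path)
  invisible(path)
}
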