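#' Entity types and association layers
#'
#' The network has exactly three node types — `disease`, `drug`, `gene` —
#' and its edges partition into six layers, one per unordered pair of
#' endpoint types.
#'
#' @return `entity_types()` returns the three type names; `layers()` the six
#'   canonical layer names (endpoint types joined by `-` in alphabetical
#'   order, e.g. `"disease-gene"`).
#' @examples
#' entity_types()
#' layers()
#' @export
entity_types <- function() c("disease", "drug", "gene")

#' @rdname entity_types
#' @export
layers <- function() {
  tt <- entity_types()
  out <- character(0)
  for (i in seq_along(tt)) {
    for (j in i:length(tt)) out <- c(out, paste(tt[i], tt[j], sep = "-"))
  }
  out
}

# canonical layer name for a pair of entity types
layer_name <- function(type_a, type_b) {
  bad <- !(type_a %in% entity_types()) | !(type_b %in% entity_types())
  if (any(bad)) {
    offending <- unique(c(type_a, type_b)[c(bad, bad)])
    offending <- setdiff(offending, entity_types())
    stop("unknown entity type(s): ", paste(offending, collapse = ", "),
         call. = FALSE)
  }
  lo <- pmin(type_a, type_b)
  hi <- pmax(type_a, type_b)
  paste(lo, hi, sep = "-")
}

# endpoint types of a layer name, sorted
layer_types <- function(layer) {
  check_layers(layer)
  strsplit(layer, "-", fixed = TRUE)
}

check_layers <- function(layer) {
  bad <- setdiff(layer, layers())
  if (length(bad) > 0) {
    stop("unknown layer(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(layer)
}

# id normalisation: entity identity is the case-folded, whitespace-trimmed token
normalize_id <- function(x) tolower(trimws(x))
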