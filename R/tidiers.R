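#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a motif significance table
#'
#' @param x a `motif_significance` from [call_significance()].
#' @param ... unused.
#' @return A plain tibble with one row per pattern: `pattern`, `n_real`,
#'   `null_mean`, `null_sd`, `z`, `p`, `significant`.
#' @method tidy motif_significance
#' @export
tidy.motif_significance <- function(x, ...) {
  tibble::as_tibble(x)[, c("pattern", "n_real", "null_mean", "null_sd",
                           "z", "p", "significant")]
}

#' @rdname tidy.motif_significance
#' @return `glance()` returns a one-row summary: number of patterns tested,
#'   number significant, thresholds, and the largest defined z.
#' @method glance motif_significance
#' @export
glance.motif_significance <- function(x, ...) {
  tibble::tibble(
    n_patterns = nrow(x),
    n_significant = sum(x$significant),
    min_count = attr(x, "min_count"),
    alpha = attr(x, "alpha"),
    max_z = if (all(is.na(x$z))) NA_real_ else max(x$z, na.rm = TRUE)
  )
}

#' Tidy a motif census
#'
#' @param x a `motif_census`.
#' @param ... unused.
#' @return Tibble `pattern`, `topology`, `count`.
#' @method tidy motif_census
#' @export
tidy.motif_census <- function(x, ...) tibble::as_tibble(x)

#' Tidy a degree distribution
#'
#' @param x a `degree_dist` from [degree_distribution()].
#' @param ... unused.
#' @return The CCDF tibble (`degree`, `fraction`) with the node type as a
#'   column.
#' @method tidy degree_dist
#' @export
tidy.degree_dist <- function(x, ...) {
  dplyr::mutate(x$ccdf, node_type = x$node_type)
}

#' @rdname tidy.degree_dist
#' @method glance degree_dist
#' @export
glance.degree_dist <- function(x, ...) {
  tibble::tibble(node_type = x$node_type, n_nodes = nrow(x$degrees),
                 max_degree = max(x$degrees$degree),
                 fitted_exponent = x$fitted_exponent, fit_xmin = x$fit_xmin,
                 graph = x$graph_label)
}

#' Plot methods
#'
#' `autoplot.motif_significance()` draws the per-pattern z-scores with the
#' significant motifs highlighted; `autoplot.degree_dist()` draws the
#' log-log degree CCDF (a straight descending line indicates power-law
#' behaviour).
#'
#' @param object the result object.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot motif_significance
#' @export
autoplot.motif_significance <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$z), ]
  d$pattern <- factor(d$pattern, levels = d$pattern[order(d$z)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$pattern,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "z-score vs randomized ensemble", y = NULL,
                  fill = "significant") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.motif_significance
#' @method autoplot degree_dist
#' @export
autoplot.degree_dist <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$degree > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$degree, y = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(K >= k)",
                  title = paste0(object$node_type, " degree CCDF (",
                                 object$graph_label, " graph)")) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"
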