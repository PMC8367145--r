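#' @import ggplot2
NULL

#' Silhouette sweep across candidate cluster counts
#'
#' Line plot of the silhouette index against k, with the selected k marked.
#'
#' @param x A `select_k_result` from [select_k()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_silhouette_sweep <- function(x, ...) {
  stopifnot(inherits(x, "select_k_result"))
  ggplot(x$sweep, aes(x = .data$k, y = .data$silhouette)) +
    geom_line(color = "grey40") +
    geom_point() +
    geom_vline(xintercept = x$k_star, linetype = "dashed", color = "firebrick") +
    scale_x_continuous(breaks = x$sweep$k) +
    labs(x = "number of clusters k", y = "silhouette index",
         title = sprintf("Silhouette-selected k* = %d (%s distance)",
                         x$k_star, x$distance)) +
    theme_minimal()
}

#' @export
autoplot.select_k_result <- function(object, ...) plot_silhouette_sweep(object, ...)

#' Neighbor similarity chart for one or more query concepts
#'
#' Horizontal bars of cosine similarity for the top neighbors, faceted by
#' query, colored by feature category.
#'
#' @param neighbors Output of [top_k_neighbors()] or [neighbor_report()].
#' @return A ggplot object.
#' @export
plot_neighbor_similarities <- function(neighbors) {
  if (!"query" %in% names(neighbors)) neighbors$query <- "query"
  ggplot(neighbors,
         aes(x = .data$similarity,
             y = stats::reorder(.data$token, .data$similarity),
             fill = .data$category)) +
    geom_col() +
    facet_wrap(~query, scales = "free_y") +
    labs(x = "cosine similarity", y = NULL, fill = "category") +
    theme_minimal()
}

#' Scheme comparison chart
#'
#' Dot plot of the internal validity indices per representation scheme,
#' mirroring the scheme-comparison table of [compare_schemes()].
#'
#' @param comparison Tibble from [compare_schemes()].
#' @return A ggplot object.
#' @export
plot_scheme_comparison <- function(comparison) {
  long <- tidyr::pivot_longer(
    comparison,
    cols = dplyr::any_of(c("hopkins", "silhouette", "dbi")),
    names_to = "index", values_to = "value"
  )
  long$label <- paste(long$scheme, long$corpus, sep = " / ")
  ggplot(long, aes(x = .data$value, y = .data$label)) +
    geom_point(size = 2) +
    facet_wrap(~index, scales = "free_x") +
    labs(x = NULL, y = NULL,
         title = "Cluster validity by representation scheme") +
    theme_minimal()
}
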