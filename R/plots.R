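#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Degree-distribution plot of a regulatory network
#'
#' In- and out-degree distributions split by node kind, on a log10 count
#' scale.
#'
#' @param object A `regnet`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regnet
#' @export
autoplot.regnet <- function(object, ...) {
  e <- object$edges
  deg <- dplyr::bind_rows(
    dplyr::count(e, id = .data$source_id, name = "degree") |>
      dplyr::mutate(direction = "out"),
    dplyr::count(e, id = .data$target_id, name = "degree") |>
      dplyr::mutate(direction = "in")) |>
    dplyr::left_join(object$nodes, by = "id")
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$degree,
                                    fill = .data$kind)) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "degree", y = "nodes",
                  title = "Degree distribution by node kind") +
    ggplot2::theme_minimal()
}

#' Null-distribution plot of a motif enrichment test
#'
#' Histogram of the motif counts in the rewired null networks with the
#' observed count marked.
#'
#' @param object A `motif_enrichment` object from [enrichment_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motif_enrichment
#' @export
autoplot.motif_enrichment <- function(object, ...) {
  df <- tibble::tibble(count = object$random_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = paste(object$motif_type, "count in rewired networks"),
      y = "networks",
      title = sprintf("%s enrichment (%s null): observed %d, p = %.3g",
                      object$motif_type, object$mode, object$observed,
                      object$p)) +
    ggplot2::theme_minimal()
}

#' Conservation histogram across tissues
#'
#' Distribution of per-entity conservation percentages, the tissue-level
#' summary of how consistently a motif recurs where a TF has data.
#'
#' @param conservation A tibble from [motif_conservation()].
#' @return A ggplot object.
#' @export
plot_conservation <- function(conservation) {
  ggplot2::ggplot(conservation, ggplot2::aes(x = .data$percent)) +
    ggplot2::geom_histogram(breaks = seq(0, 100, by = 10),
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "% of data tissues containing the motif",
                  y = "entities",
                  title = unique(conservation$level)) +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise tissue-network similarity
#'
#' @param jaccard A tissue x tissue matrix from [pairwise_jaccard()].
#' @return A ggplot object.
#' @export
plot_jaccard <- function(jaccard) {
  df <- tibble::as_tibble(as.table(jaccard), .name_repair = "minimal")
  names(df) <- c("tissue_1", "tissue_2", "jaccard")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue_1, y = .data$tissue_2,
                                   fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
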