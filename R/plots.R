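# ggplot2 views of the main result types.

#' Plot motif positional densities around cleavage sites
#'
#' @param density Tibble from [motif_positional_density()].
#' @return A ggplot: density (global mode = 1) vs offset, one line per
#'   motif, with the cleavage site at 0.
#' @export
plot_motif_density <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(x = .data$offset, y = .data$density,
                                        color = .data$motif)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "offset from cleavage site (nt)",
                  y = "density (mode = 1)", color = "motif") +
    ggplot2::theme_minimal()
}

#' Plot the resolution sweep
#'
#' @param sweep Tibble from [resolution_sweep()].
#' @return A ggplot of mean absolute relative quantification error vs
#'   cleavage-site distance, faceted by truncation length.
#' @export
plot_resolution_sweep <- function(sweep) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data$cs_distance,
                               y = .data$mean_abs_rel_error,
                               color = .data$isoform,
                               group = interaction(.data$isoform,
                                                   .data$proximal_count,
                                                   .data$distal_count))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~truncation_length) +
    ggplot2::labs(x = "cleavage-site distance (nt)",
                  y = "mean |relative error|") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a bootstrap differential-usage test
#'
#' @param object A `utr_boot_test`.
#' @param dwui_threshold,q_threshold Significance rule used for
#'   coloring (defaults 0.10 / 0.05).
#' @param ... Ignored.
#' @return A ggplot of -log10(q) vs the observed usage difference.
#' @method autoplot utr_boot_test
#' @export
autoplot.utr_boot_test <- function(object, dwui_threshold = 0.10,
                                   q_threshold = 0.05, ...) {
  d <- as_tibble(unclass_tbl(object)) |>
    mutate(significant = abs(.data$observed) > dwui_threshold &
             !is.na(.data$q) & .data$q < q_threshold)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed,
                                  y = -log10(.data$q),
                                  color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-dwui_threshold, dwui_threshold),
                        linetype = "dashed", color = "grey60") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = paste0("observed ", object$statistic[1],
                             " difference"),
                  y = "-log10 q") +
    ggplot2::theme_minimal()
}

#' Heatmap of a clustered effect matrix
#'
#' @param object A `utr_clusters` object.
#' @param ... Ignored.
#' @return A ggplot tile heatmap of the retained z-scaled effects with
#'   rows and columns ordered by cluster.
#' @method autoplot utr_clusters
#' @export
autoplot.utr_clusters <- function(object, ...) {
  po <- object$perturbation_clusters |> arrange(.data$cluster)
  go <- object$gene_clusters |> arrange(.data$cluster)
  d <- as_tibble(as.data.frame.table(object$z, responseName = "z",
                                     stringsAsFactors = FALSE)) |>
    rlang::set_names(c("perturbation", "gene_id", "z")) |>
    mutate(perturbation = factor(.data$perturbation, levels = po$id),
           gene_id = factor(.data$gene_id, levels = go$id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene_id, y = .data$perturbation,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "response gene", y = "perturbation", fill = "zdWUI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
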