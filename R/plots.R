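# ggplot2 displays for the main result types.

#' @import ggplot2
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Clone-size distribution plot
#'
#' Bar chart of clonotype sizes in decreasing order, the usual display for an
#' oligoclonal repertoire (a long singleton tail with a few expanded clones).
#'
#' @param sizes A [clonal_size_distribution()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clonal_sizes <- function(sizes, ...) {
  df <- as_tibble(sizes) |> mutate(rank = row_number())
  ggplot(df, aes(x = .data$rank, y = .data$size)) +
    geom_col(fill = "grey30") +
    labs(x = "clonotype rank", y = "cells per clonotype",
         title = "Clonal size distribution") +
    theme_minimal()
}

#' Positional residue enrichment heatmap
#'
#' Tile map of CDR3 position x residue enrichment (pool frequency over
#' background), faceted by pool.
#'
#' @param enrichment A [positional_residue_enrichment()] result.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot(enrichment,
         aes(x = factor(.data$position), y = .data$residue,
             fill = log2(.data$enrichment))) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    facet_wrap(~pool) +
    labs(x = "CDR3 position (1 = conserved Cys)", y = NULL,
         fill = "log2 enrichment") +
    theme_minimal()
}

#' Paired log fold-change scatter
#'
#' Scatter of per-gene log2 fold-changes from two comparisons with the
#' identity line, the display used to show transcriptional concordance of two
#' cell pools against a common reference.
#'
#' @param de_a,de_b `tr1_de` results.
#' @param only_significant Restrict to genes significant in either comparison.
#' @return A ggplot object.
#' @export
plot_logfc_concordance <- function(de_a, de_b, only_significant = TRUE) {
  paired <- inner_join(
    as_tibble(de_a) |> select("gene", lfc_a = "log_fc", sig_a = "significant"),
    as_tibble(de_b) |> select("gene", lfc_b = "log_fc", sig_b = "significant"),
    by = "gene"
  )
  if (only_significant) paired <- filter(paired, .data$sig_a | .data$sig_b)
  ggplot(paired, aes(x = .data$lfc_a, y = .data$lfc_b)) +
    geom_point(alpha = 0.5) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    labs(x = "log2 fold-change (comparison A)",
         y = "log2 fold-change (comparison B)") +
    theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param de A `tr1_de` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tr1_de <- function(de, ...) {
  df <- as_tibble(de)
  ggplot(df, aes(x = .data$log_fc, y = -log10(pmax(.data$p_adj, 1e-300)),
                 colour = .data$significant)) +
    geom_point(alpha = 0.6) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    geom_vline(xintercept = c(-1, 1) * attr(de, "lfc_threshold"), linetype = 3) +
    labs(x = "log2 fold-change", y = "-log10 adjusted p") +
    theme_minimal()
}

#' Clonotype-by-cluster composition plot
#'
#' Stacked bars of each repeated clonotype's cells across expression clusters,
#' the display used to show that the same clonotypes populate the TFH-like
#' and TR1-like clusters.
#'
#' @param table A [clonotype_cluster_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clonotype_cluster_table <- function(table, ...) {
  long <- as_tibble(table) |>
    tidyr::pivot_longer(starts_with("cluster_"), names_to = "cluster",
                        names_prefix = "cluster_", values_to = "n") |>
    mutate(group_id = factor(.data$group_id,
                             levels = rev(unique(table$group_id))))
  ggplot(long, aes(x = .data$n, y = .data$group_id, fill = .data$cluster)) +
    geom_col() +
    labs(x = "cells", y = "repeated clonotype", fill = "cluster") +
    theme_minimal()
}
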