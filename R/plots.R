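#' Forest plot of per-category odds ratios
#'
#' Odds ratio and corrected confidence interval per functional category on
#' a log scale, with the no-association line at 1. Skipped (zero-cell)
#' categories are shown without an estimate.
#'
#' @param object A `fusenet_enrichment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fusenet_enrichment <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(
    d[!d$skipped, ],
    ggplot2::aes(x = .data$or, y = .data$category,
                 colour = .data$significant)
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#B2182B", `FALSE` = "grey55")) +
    ggplot2::labs(
      x = sprintf("odds ratio (CI at z = %.2f)", object$z),
      y = "functional category",
      colour = "CI excludes 1",
      title = "Composite-gene enrichment, eukaryotes vs prokaryotes"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of a remodelling census
#'
#' @param census_tbl Tibble from [census()].
#' @return A ggplot object.
#' @export
plot_census <- function(census_tbl) {
  d <- census_tbl |>
    pivot_longer(
      c("n_nested", "n_strict_composite", "n_strict_component",
        "n_non_remodelled"),
      names_to = "gene_class", values_to = "n"
    ) |>
    mutate(gene_class = sub("^n_", "", .data$gene_class))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$n,
                                  fill = .data$gene_class)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "share of genes", fill = "class",
                  title = "Remodelling classes per group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Replicate dot plot for the resampling experiment
#'
#' One dot per replicate, class and remodelling category, mirroring how
#' equal-size resampling runs are conventionally summarised.
#'
#' @param replicates Tibble from [run_resampling()].
#' @return A ggplot object.
#' @export
plot_resampling <- function(replicates) {
  ggplot2::ggplot(
    replicates,
    ggplot2::aes(x = .data$domain_class, y = .data$n,
                 colour = .data$domain_class)
  ) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_class),
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = "genes per replicate",
                  title = "Equal-size resampling replicates") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
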