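#' Boxplots of alpha-diversity indices by group
#'
#' @param alpha An [alpha_diversity()] tibble.
#' @param grouping Factor of group labels, one per sample in `alpha` order.
#' @param indices Which index columns to show.
#' @return A ggplot (facetted boxplots).
#' @export
plot_alpha_diversity <- function(alpha, grouping,
                                 indices = c("s_obs", "chao1", "ace",
                                             "shannon", "pielou")) {
  df <- dplyr::mutate(alpha, group = as.factor(grouping)) |>
    tidyr::pivot_longer(dplyr::all_of(indices), names_to = "index",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of a rarity partition
#'
#' @param summary_tbl A [rarity_summary()] tibble.
#' @return A ggplot comparing per-category percentages of OTUs and reads.
#' @export
plot_rarity_summary <- function(summary_tbl) {
  df <- summary_tbl[summary_tbl$category != "total", ] |>
    tidyr::pivot_longer(c("pct_otus", "pct_reads"), names_to = "measure",
                        values_to = "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$pct,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of total", fill = NULL) +
    ggplot2::theme_minimal()
}
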