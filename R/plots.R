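# Convenience plots; all statistics run on tables, never on figures.

utils::globalVariables(c("x", "y", "nes", "set", "significant"))

#' Quadrant scatter plot with dashed cutoff lines
#'
#' Per-cell nuclear-TF versus cytoplasmic-marker medians, faceted by
#' genotype, with the two negativity cutoffs drawn as dashed lines.
#'
#' @param records Per-cell records.
#' @param rule_a,rule_b [fit_threshold()] rules (A on the x axis).
#' @return A ggplot object.
#' @export
plot_quadrants <- function(records, rule_a, rule_b) {
  col_a <- measurement_column(rule_a$channel, rule_a$compartment)
  col_b <- measurement_column(rule_b$channel, rule_b$compartment)
  df <- data.frame(x = records[[col_a]], y = records[[col_b]],
                   genotype = records$genotype)
  df <- df[stats::complete.cases(df), ]
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_vline(xintercept = rule_a$cutoff, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = rule_b$cutoff, linetype = "dashed") +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::labs(
      x = sprintf("%s (%s median)", rule_a$channel, rule_a$compartment),
      y = sprintf("%s (%s median)", rule_b$channel, rule_b$compartment)) +
    ggplot2::theme_bw()
}

#' Horizontal NES bar chart for an enrichment result
#'
#' Bars are shaded by whether the BH-adjusted p value clears `alpha`.
#'
#' @param enrichment An `enrichment_result` from [gsea_collection()].
#' @param alpha Significance threshold on `adj_p`.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, alpha = 0.05) {
  df <- as.data.frame(enrichment)
  df$set <- stats::reorder(df$set, df$nes)
  df$significant <- df$adj_p < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = nes, y = set,
                                   fill = significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                          `FALSE` = "grey60"),
                               name = sprintf("adjP < %.2f", alpha)) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL) +
    ggplot2::theme_bw()
}
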