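#' Plot culturability estimates with exact confidence limits
#'
#' @param object an `htc_culturability` tibble from [culturability()] or
#'   [experiment_summary()].
#' @param ... unused.
#' @return a ggplot: percent culturability by scope and experiment with
#'   Clopper-Pearson error bars.
#' @export
autoplot.htc_culturability <- function(object, ...) {
  td <- tidy(object)
  td$label <- ifelse(is.na(td$experiment), td$scope,
                     paste(td$experiment, td$scope, sep = "\n"))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$label, y = .data$V_pct)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low_pct, ymax = .data$ci_high_pct),
      width = 0.15) +
    ggplot2::labs(x = NULL, y = "Culturability (%)") +
    ggplot2::theme_minimal()
}

#' Bubble plot of ASV co-occurrence across mixed cultures
#'
#' @param cooc long pair-count tibble from [cooccurrence()].
#' @return a ggplot with bubble size giving the number of mixed cultures
#'   sharing each ASV pair.
#' @export
plot_cooccurrence <- function(cooc) {
  dat <- cooc[cooc$n_cultures > 0, , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$asv_1, y = .data$asv_2,
                                    size = .data$n_cultures)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::labs(x = NULL, y = NULL, size = "Mixed\ncultures") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of Venn membership-region sizes
#'
#' @param venn tibble from [venn_membership()].
#' @return a ggplot of ASV counts per membership region.
#' @export
plot_venn_regions <- function(venn) {
  ggplot2::ggplot(venn, ggplot2::aes(x = stats::reorder(.data$region, .data$n),
                                     y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "Membership region", y = "ASVs") +
    ggplot2::theme_minimal()
}
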