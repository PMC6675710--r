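# ggplot2 graphics for the main result types.

#' Scatter of amMs against the ODX recurrence score
#'
#' The concordance picture: each case's average modified Magee score against
#' its Oncotype DX recurrence score, with the risk-band cutoffs (18 and 30)
#' drawn on both axes.
#'
#' @param scored A data frame with `amms` and `odx_rs`.
#' @return A ggplot object.
#' @export
plot_concordance <- function(scored) {
  scored <- dplyr::filter(as_tibble(scored),
                          !is.na(.data$amms), !is.na(.data$odx_rs))
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$amms, y = .data$odx_rs)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = c(18, 30), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(18, 30), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Average modified Magee score (amMs)",
                  y = "Oncotype DX recurrence score") +
    ggplot2::theme_minimal()
}

#' Plot RoMMa category frequencies
#'
#' @param object A `romma_calls` tibble from [romma_classify()].
#' @param ... Unused.
#' @return A ggplot bar chart of the risk-category frequencies.
#' @export
autoplot.romma_calls <- function(object, ...) {
  summ <- romma_summary(object)
  ggplot2::ggplot(summ, ggplot2::aes(
    x = factor(.data$category, levels = summ$category), y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)",
                                                    .data$n, .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "RoMMa category", y = "% of cases") +
    ggplot2::theme_minimal()
}

#' Plot a band-agreement table
#'
#' @param agreement Output of [band_agreement()].
#' @return A ggplot chart of the percent-concordant column by group.
#' @export
plot_band_agreement <- function(agreement) {
  agreement$group <- factor(agreement$group, levels = agreement$group)
  ggplot2::ggplot(agreement, ggplot2::aes(x = .data$group,
                                          y = .data$pct_concordant)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$pct_concordant)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% in concordant ODX band") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
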