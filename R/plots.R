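#' Plot mean productivity loss by multiple-risk tier
#'
#' Bar chart of the mean absenteeism, presenteeism and total loss for the
#' low (0-2 conditions), medium (3-4) and high (5+) multiple-risk tiers.
#'
#' @param tier_means The `tier_means` tibble from [tier_comparison()] (or
#'   `bundle$tiers$tier_means`).
#' @return A ggplot object.
#' @export
plot_loss_by_tier <- function(tier_means) {
  ggplot2::ggplot(tier_means,
                  ggplot2::aes(x = .data$tier, y = .data$mean,
                               fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "multiple health risk tier",
                  y = "mean productivity loss (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot high-risk prevalence by health condition
#'
#' @param prevalence A [prevalence_table()] result.
#' @return A ggplot object.
#' @export
plot_prevalence <- function(prevalence) {
  ggplot2::ggplot(prevalence,
                  ggplot2::aes(x = stats::reorder(.data$label,
                                                  .data$prevalence_pct),
                               y = .data$prevalence_pct)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "high-risk prevalence (%)") +
    ggplot2::theme_minimal()
}
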