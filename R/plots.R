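#' Bar plot of ohnolog pair categories
#'
#' @param pairs pair table from [classify_ohnolog_pairs()] (with
#'   `category`).
#' @return A ggplot.
#' @export
plot_category_counts <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(
      x = "pair category", y = "ohnolog pairs",
      title = "Ohnolog expression evolution categories"
    ) +
    ggplot2::theme_minimal()
}

#' Asymmetry distributions by pair category
#'
#' @param pairs pair table with `category` and `asymmetry` columns.
#' @return A ggplot (boxplots of |mean log2 difference| per category).
#' @export
plot_asymmetry <- function(pairs) {
  ggplot2::ggplot(
    pairs[!is.na(pairs$asymmetry), ],
    ggplot2::aes(x = .data$category, y = .data$asymmetry)
  ) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(
      x = "pair category", y = "expression asymmetry (log2)",
      title = "Expression asymmetry by evolutionary category"
    ) +
    ggplot2::theme_minimal()
}

#' Shift proportions per tree class
#'
#' @param shift_proportions tibble from [summarize_run()].
#' @return A ggplot.
#' @export
plot_shift_proportions <- function(shift_proportions) {
  long <- tidyr::pivot_longer(
    shift_proportions,
    c("prop_up", "prop_down"),
    names_to = "direction", values_to = "proportion"
  )
  long$direction <- sub("prop_", "", long$direction)
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$tree_class, y = .data$proportion, fill = .data$direction
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(down = "#4575b4", up = "#d73027")) +
    ggplot2::labs(
      x = "tree class", y = "proportion of trees",
      title = "Trees with significant expression shifts"
    ) +
    ggplot2::theme_minimal()
}
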