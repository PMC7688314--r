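#' PCA score plot of all replicates
#'
#' Replicate coordinates on two principal components, colored by cell
#' type and shaped by age group.
#'
#' @param object A `proteome_pca` from [pca_embed()].
#' @param components Two components to plot (default PC1 and PC2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot proteome_pca
#' @export
autoplot.proteome_pca <- function(object, components = c("PC1", "PC2"), ...) {
  stopifnot(length(components) == 2L)
  frac <- 100 * object$variance / sum(object$variance)
  names(frac) <- paste0("PC", seq_along(frac))
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(
      .data[[components[1L]]], .data[[components[2L]]],
      colour = .data$cell_type, shape = .data$age
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%% of variance)", components[1L], frac[components[1L]]),
      y = sprintf("%s (%.1f%% of variance)", components[2L], frac[components[2L]])
    ) +
    ggplot2::theme_minimal()
}

#' Null distribution histograms with observed counts
#'
#' One panel per cell type: the reshuffled unique mRNA-only counts, the
#' empirical confidence interval, and the observed count.
#'
#' @param object A `null_distribution` from [run_null()].
#' @param level Confidence level for the interval (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot null_distribution
#' @export
autoplot.null_distribution <- function(object, level = 0.95, ...) {
  long <- as_tibble(object$counts) |>
    tidyr::pivot_longer(
      dplyr::everything(),
      names_to = "cell_type", values_to = "count"
    )
  summary <- tidy(object, level = level)
  ggplot2::ggplot(long, ggplot2::aes(.data$count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(
      data = summary,
      ggplot2::aes(xintercept = .data$observed), colour = "firebrick"
    ) +
    ggplot2::geom_vline(
      data = summary,
      ggplot2::aes(xintercept = .data$lower), linetype = "dashed"
    ) +
    ggplot2::geom_vline(
      data = summary,
      ggplot2::aes(xintercept = .data$upper), linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~cell_type, scales = "free") +
    ggplot2::labs(x = "null unique mRNA-only count", y = "iterations") +
    ggplot2::theme_minimal()
}

#' Discovery-saturation curve plot
#'
#' @param curve Tibble from [discovery_curve()].
#' @return A ggplot object (step curve of cumulative distinct proteins).
#' @export
plot_discovery_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$order, .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "replicate (acquisition order)",
                  y = "cumulative distinct proteins") +
    ggplot2::theme_minimal()
}

#' Stacked category counts per cell type
#'
#' Counts of genes detected as mRNA only, uniquely mRNA only, or in both
#' layers per cell type.
#'
#' @param categories Long category tibble from [classify_transcriptome()].
#' @return A ggplot object.
#' @export
plot_category_counts <- function(categories) {
  counts <- categories |>
    filter(.data$category != "absent") |>
    mutate(category = ifelse(
      .data$unique_mrna_only, "unique mRNA only",
      ifelse(.data$category == "mRNA_only", "mRNA only", "both")
    )) |>
    count(.data$cell_type, .data$category, name = "n")
  ggplot2::ggplot(
    counts,
    ggplot2::aes(.data$cell_type, .data$n, fill = .data$category)
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      "both" = "darkorange", "mRNA only" = "seagreen",
      "unique mRNA only" = "gold"
    )) +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' Mean enrichment score bars per cell type for one set
#'
#' @param score_obj `enrichment_scores` from [score_matrix()].
#' @param set Set name to display.
#' @return A ggplot object.
#' @export
plot_mean_scores <- function(score_obj, set) {
  ms <- mean_scores(score_obj) |> filter(.data$set == !!set)
  if (nrow(ms) == 0L) abort(sprintf("unknown set '%s'", set))
  ggplot2::ggplot(
    ms, ggplot2::aes(stats::reorder(.data$cell_type, -.data$mean_score),
                     .data$mean_score)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "mean enrichment score", title = set) +
    ggplot2::theme_minimal()
}
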