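#' Tidy a null distribution
#'
#' One row per cell type: observed unique count, null mean/sd, empirical
#' confidence interval and verdict.
#'
#' @param x A `null_distribution` from [run_null()].
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A tibble with `cell_type`, `observed`, `null_mean`, `null_sd`,
#'   `lower`, `upper`, `verdict`.
#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, level = 0.95, ...) {
  ci <- empirical_ci(x, level = level)
  tibble(
    cell_type = ci$cell_type,
    observed = as.numeric(x$observed[ci$cell_type]),
    null_mean = colMeans(x$counts)[ci$cell_type],
    null_sd = apply(x$counts, 2L, stats::sd)[ci$cell_type],
    lower = ci$lower, upper = ci$upper
  ) |>
    mutate(verdict = purrr::map_chr(
      seq_along(.data$observed),
      function(i) verdict(.data$observed[i], c(.data$lower[i], .data$upper[i]))
    ))
}

#' Glance at a null distribution
#'
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_cell_types`, `n_iterations`,
#'   `seed`.
#' @method glance null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble(
    n_genes = x$n_genes, n_cell_types = ncol(x$counts),
    n_iterations = x$n_iterations, seed = x$seed
  )
}

#' Tidy a PCA embedding: per-gene loadings
#'
#' @param x A `proteome_pca` from [pca_embed()].
#' @param ... Unused.
#' @return Long tibble `gene`, `component`, `loading`.
#' @method tidy proteome_pca
#' @export
tidy.proteome_pca <- function(x, ...) {
  x$loadings |>
    tidyr::pivot_longer(-"gene", names_to = "component", values_to = "loading")
}

#' Glance at a PCA embedding
#'
#' @param x A `proteome_pca`.
#' @param ... Unused.
#' @return One row per component: `component`, `variance`,
#'   `variance_fraction`, `cumulative_fraction`.
#' @method glance proteome_pca
#' @export
glance.proteome_pca <- function(x, ...) {
  frac <- x$variance / sum(x$variance)
  tibble(
    component = paste0("PC", seq_along(x$variance)),
    variance = x$variance,
    variance_fraction = frac,
    cumulative_fraction = cumsum(frac)
  )
}

#' Tidy an enrichment score object
#'
#' @param x `enrichment_scores` from [score_matrix()].
#' @param ... Unused.
#' @return Long tibble `set`, `replicate_id`, `cell_type`, `age`, `score`.
#' @method tidy enrichment_scores
#' @export
tidy.enrichment_scores <- function(x, ...) {
  x$scores |>
    tidyr::pivot_longer(-"set", names_to = "replicate_id", values_to = "score") |>
    left_join(
      x$design[, c("replicate_id", "cell_type", "age")],
      by = "replicate_id"
    )
}

#' Glance at an enrichment score object
#'
#' @param x `enrichment_scores`.
#' @param ... Unused.
#' @return One-row tibble: `n_sets`, `n_replicates`, `tau`, `normalized`.
#' @method glance enrichment_scores
#' @export
glance.enrichment_scores <- function(x, ...) {
  tibble(
    n_sets = nrow(x$scores), n_replicates = nrow(x$design),
    tau = x$tau, normalized = x$normalized
  )
}
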