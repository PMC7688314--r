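#' Overlap of a gene set with each miRNA's putative targets
#'
#' Counts, per miRNA, how many of the supplied genes (typically the
#' uniquely-undetected-protein list of one cell type) sit in that miRNA's
#' putative target set.
#'
#' @param gene_set Character vector of gene identifiers (common namespace
#'   with the target map).
#' @param target_map Target-map tibble from [read_target_map()].
#' @return A tibble `mirna`, `n_targets`, `overlap`, ordered by descending
#'   overlap then miRNA id.
#' @export
overlap_counts <- function(gene_set, target_map) {
  gene_set <- unique(gene_set)
  target_map |>
    mutate(overlap = purrr::map_int(
      .data$targets, function(t) length(intersect(t, gene_set))
    )) |>
    arrange(dplyr::desc(.data$overlap), .data$mirna) |>
    select("mirna", "n_targets", "overlap")
}

#' Quartile ranking of miRNAs by overlap count
#'
#' Quartiles are computed over miRNAs with at least one overlap by
#' empirical count percentiles; the fourth quartile is the top 25% by
#' count (size fixed at `ceiling(0.25 * n)`, ties at the boundary broken
#' lexicographically). Zero-overlap miRNAs can be included with
#' `include_zero = TRUE`.
#'
#' @param counts Overlap tibble from [overlap_counts()].
#' @param include_zero Include zero-overlap miRNAs in the quartile
#'   computation (default `FALSE`).
#' @return A tibble `mirna`, `overlap`, `quartile` (1-4, 4 = highest),
#'   ordered by descending overlap; attribute `"fourth_quartile"` holds
#'   the fourth-quartile miRNA ids.
#' @export
quartile_rank <- function(counts, include_zero = FALSE) {
  pool <- if (include_zero) counts else counts |> filter(.data$overlap >= 1L)
  if (nrow(pool) == 0L) {
    warn("all overlap counts are zero; fourth quartile is empty")
    out <- counts |> mutate(quartile = NA_integer_) |>
      select("mirna", "overlap", "quartile")
    attr(out, "fourth_quartile") <- character(0)
    return(out)
  }
  if (nrow(pool) < 4L) warn("fewer than 4 miRNAs with overlap; quartiles are coarse")
  n <- nrow(pool)
  k4 <- ceiling_frac(0.25, n)
  q4 <- top_k_lex(pool$overlap, pool$mirna, k4)
  # Remaining quartiles by empirical percentile of the count.
  pct <- rank(pool$overlap, ties.method = "average") / n
  quartile <- pmin(4L, 1L + findInterval(pct, c(0.25, 0.5, 0.75), left.open = TRUE))
  quartile[pool$mirna %in% q4] <- 4L
  out <- pool |>
    mutate(quartile = quartile) |>
    arrange(dplyr::desc(.data$overlap), .data$mirna) |>
    select("mirna", "overlap", "quartile")
  attr(out, "fourth_quartile") <- q4
  out
}

#' Category distribution restricted to putative miRNA targets
#'
#' Restricts the transcriptome/proteome categories to the union of all
#' putative target genes (each gene once) and recomputes per-cell-type
#' category counts plus the reshuffling null verdicts on this restricted
#' universe.
#'
#' @param target_map Target-map tibble from [read_target_map()].
#' @param categories Long category tibble from [classify_transcriptome()].
#' @param n_iterations,seed,level Passed to [null_verdicts()].
#' @return A list with `counts` (tibble `cell_type`, `category`, `n`,
#'   plus unique-mRNA-only counts as rows with
#'   `category = "unique_mRNA_only"`), `verdicts` (tibble from
#'   [null_verdicts()]), and `universe` (the restricted gene set).
#' @export
target_category_distribution <- function(target_map, categories,
                                         n_iterations = 1000L, seed = 1L,
                                         level = 0.95) {
  universe <- sort(unique(unlist(target_map$targets)))
  restricted <- categories |> filter(.data$gene %in% universe)
  if (nrow(restricted) == 0L) {
    return(list(
      counts = tibble(cell_type = character(0), category = character(0), n = integer(0)),
      verdicts = NULL, universe = character(0)
    ))
  }
  counts <- restricted |>
    count(.data$cell_type, .data$category, name = "n")
  if ("unique_mrna_only" %in% names(restricted)) {
    uniq <- restricted |>
      filter(.data$unique_mrna_only) |>
      count(.data$cell_type, name = "n") |>
      mutate(category = "unique_mRNA_only")
    counts <- bind_rows(counts, uniq) |>
      arrange(.data$cell_type, .data$category)
  }
  verdicts <- null_verdicts(
    restricted, n_iterations = n_iterations, seed = seed, level = level
  )
  list(counts = counts, verdicts = verdicts, universe = universe)
}

#' Old-HSC detection of young uniquely-undetected target genes
#'
#' Partitions a gene set (typically: young-HSC uniquely-undetected
#' proteins that are putative miRNA targets) by whether each gene is
#' detected (>= 1 replicate) in the old-HSC proteome -- the "rescue" of
#' protein diversity with age.
#'
#' @param gene_set Character vector of gene identifiers.
#' @param old_profile Old-HSC detection counts ([detection_counts()]),
#'   column named by `cell_type`.
#' @param cell_type Column of `old_profile` to use (default `"HSC"`).
#' @return A one-row tibble: `n_input`, `n_detected_old`,
#'   `n_still_undetected`, `detected_fraction`.
#' @export
old_rescue <- function(gene_set, old_profile, cell_type = "HSC") {
  assert_columns(old_profile, c("gene", cell_type), "old_profile")
  gene_set <- unique(gene_set)
  detected_genes <- old_profile$gene[old_profile[[cell_type]] >= 1L]
  n_det <- sum(gene_set %in% detected_genes)
  tibble(
    n_input = length(gene_set),
    n_detected_old = n_det,
    n_still_undetected = length(gene_set) - n_det,
    detected_fraction = if (length(gene_set) > 0L) n_det / length(gene_set) else NA_real_
  )
}
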