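#' Spearman correlation between protein and mRNA within one cell type
#'
#' Rank correlation (average-rank tie handling) between aggregated protein
#' intensity and mRNA TPM, over genes detected in both layers in that cell
#' type. Being rank-based, the coefficient is invariant to any strictly
#' monotone transform of either input, in particular to the log offset
#' constants used elsewhere.
#'
#' @param protein_profile Aggregated proteome profile (`gene` + cell types).
#' @param mrna_profile Aggregated transcriptome profile.
#' @param cell_type Cell type column shared by both profiles.
#' @return A one-row tibble with `cell_type`, `rho` and `n_genes`.
#' @export
spearman_protein_mrna <- function(protein_profile, mrna_profile, cell_type) {
  assert_columns(protein_profile, c("gene", cell_type), "protein_profile")
  assert_columns(mrna_profile, c("gene", cell_type), "mrna_profile")
  joint <- inner_join(
    tibble(gene = protein_profile$gene, protein = protein_profile[[cell_type]]),
    tibble(gene = mrna_profile$gene, mrna = mrna_profile[[cell_type]]),
    by = "gene"
  ) |>
    filter(.data$protein > 0, .data$mrna > 0)
  if (nrow(joint) < 3L) {
    abort(sprintf(
      "fewer than 3 genes detected in both layers for '%s'", cell_type
    ))
  }
  tibble(
    cell_type = cell_type,
    rho = cor(joint$protein, joint$mrna, method = "spearman"),
    n_genes = nrow(joint)
  )
}

#' Log2 protein-per-mRNA fold-change table
#'
#' `log2(protein intensity / mRNA TPM)` per gene per cell type, restricted
#' to genes detected in both layers in every requested cell type, so no
#' offset is consumed on the restricted table. A zero-tolerant variant
#' (`restrict = FALSE`) applies the offset to both layers instead.
#'
#' @param protein_profile Aggregated proteome profile.
#' @param mrna_profile Aggregated transcriptome profile.
#' @param cell_types Cell types to include (default: shared columns).
#' @param offset Offset used only when `restrict = FALSE` (default 1e-5).
#' @param restrict Keep only genes positive in both layers everywhere
#'   (default `TRUE`).
#' @return A tibble `gene` + one finite log2 fold-change column per cell
#'   type.
#' @export
fold_change_table <- function(protein_profile, mrna_profile,
                              cell_types = NULL, offset = 1e-5,
                              restrict = TRUE) {
  shared <- intersect(
    cell_type_columns(protein_profile), cell_type_columns(mrna_profile)
  )
  cell_types <- cell_types %||% shared
  missing <- setdiff(cell_types, shared)
  if (length(missing) > 0L) {
    abort(sprintf(
      "cell type(s) missing from a profile: %s", paste(missing, collapse = ", ")
    ))
  }
  joint <- inner_join(
    protein_profile[, c("gene", cell_types)],
    mrna_profile[, c("gene", cell_types)],
    by = "gene", suffix = c(".prot", ".mrna")
  )
  prot <- as.matrix(joint[, paste0(cell_types, ".prot"), drop = FALSE])
  mrna <- as.matrix(joint[, paste0(cell_types, ".mrna"), drop = FALSE])
  if (restrict) {
    keep <- rowSums(prot > 0) == length(cell_types) &
      rowSums(mrna > 0) == length(cell_types)
    if (!any(keep)) abort("no gene is detected in both layers in every cell type")
    fc <- log2(prot[keep, , drop = FALSE] / mrna[keep, , drop = FALSE])
    genes <- joint$gene[keep]
  } else {
    fc <- log2((prot + offset) / (mrna + offset))
    genes <- joint$gene
  }
  colnames(fc) <- cell_types
  bind_cols(tibble(gene = genes), as_tibble(fc))
}

#' Pearson correlation of fold changes between cell types
#'
#' Symmetric cell type x cell type grid of Pearson correlations of the
#' per-gene log2 protein/mRNA fold changes. Zero-variance columns yield
#' undefined entries, reported as `NA`.
#'
#' @param fc_table Fold-change table from [fold_change_table()] (>= 3 genes).
#' @return A tibble in long form: `cell_type_1`, `cell_type_2`, `pearson`.
#'   The full grid (unit diagonal included) is attached as attribute
#'   `"grid"`.
#' @export
pearson_between_celltypes <- function(fc_table) {
  cts <- cell_type_columns(fc_table)
  if (nrow(fc_table) < 3L) abort("need at least 3 genes")
  vm <- as.matrix(fc_table[, cts, drop = FALSE])
  grid <- suppressWarnings(cor(vm, method = "pearson"))
  diag(grid) <- ifelse(apply(vm, 2L, function(x) stats::sd(x) > 0), 1, NA_real_)
  long <- as_tibble(as.data.frame.table(grid, stringsAsFactors = FALSE)) |>
    setNames(c("cell_type_1", "cell_type_2", "pearson")) |>
    as_tibble()
  attr(long, "grid") <- grid
  long
}

#' Genes decoupled from their mRNA in the reference cell type
#'
#' For each comparator cell type, genes are ranked by the difference of
#' log2 protein/mRNA fold changes (comparator minus reference --
#' equivalently the log of the ratio of protein-per-mRNA ratios), and the
#' top `top_frac` fraction taken (ties at the cutoff broken by
#' lexicographic gene id). The result is the intersection across all
#' comparators: genes with systematically less protein per mRNA in the
#' reference than in every comparator.
#'
#' @param fc_table Fold-change table containing reference and comparators.
#' @param reference Reference cell type (default `"HSC"`).
#' @param comparators Comparator cell types (default: all other columns).
#' @param top_frac Fraction selected per comparator (default 0.025).
#' @return A tibble with `gene` and one `delta_<comparator>` column per
#'   comparator (difference of log2 fold changes), sorted by gene.
#'   Attribute `"degenerate"` flags comparators whose differences were all
#'   equal.
#' @export
decoupled_genes <- function(fc_table, reference = "HSC", comparators = NULL,
                            top_frac = 0.025) {
  cts <- cell_type_columns(fc_table)
  if (!reference %in% cts) abort(sprintf("reference '%s' not in table", reference))
  comparators <- comparators %||% setdiff(cts, reference)
  missing <- setdiff(comparators, cts)
  if (length(missing) > 0L) {
    abort(sprintf("comparator(s) not in table: %s", paste(missing, collapse = ", ")))
  }
  k <- ceiling_frac(top_frac, nrow(fc_table))
  degenerate <- character(0)
  tops <- list()
  deltas <- tibble(gene = fc_table$gene)
  for (cmp in comparators) {
    delta <- fc_table[[cmp]] - fc_table[[reference]]
    deltas[[paste0("delta_", cmp)]] <- delta
    if (length(unique(delta)) == 1L) degenerate <- c(degenerate, cmp)
    tops[[cmp]] <- top_k_lex(delta, fc_table$gene, k)
  }
  if (length(degenerate) > 0L) {
    warn(sprintf(
      "comparator(s) with constant fold-change difference: %s",
      paste(degenerate, collapse = ", ")
    ))
  }
  hits <- sort(Reduce(intersect, tops))
  out <- deltas |> filter(.data$gene %in% hits) |> arrange(.data$gene)
  attr(out, "degenerate") <- degenerate
  attr(out, "top_k") <- k
  out
}

#' Classify genes by transcriptome/proteome detection per cell type
#'
#' For every gene and cell type of the comparison set: `both` when protein
#' and mRNA are detected, `mRNA_only` when mRNA is detected without
#' protein, `absent` otherwise. A gene is flagged `unique_mrna_only` in a
#' cell type when it is `mRNA_only` there and in no other member of the
#' comparison set, and its protein is detected in at least `min_reps`
#' replicates of at least one other cell type -- the operational signature
#' of post-transcriptional repression.
#'
#' @param protein_profile Aggregated proteome profile.
#' @param mrna_profile Aggregated transcriptome profile (mean TPM).
#' @param detection_profile Proteome detection counts ([detection_counts()]).
#' @param comparison_set Cell types compared (default
#'   `c("HSC", "MPPa", "MPPb", "MPPc")` intersected with available columns).
#' @param min_reps Protein replicate floor elsewhere (default 3).
#' @param tpm_floor mRNA detection floor; detected means TPM strictly
#'   greater than this (default 0).
#' @return A long tibble: `gene`, `cell_type`, `category`,
#'   `unique_mrna_only`, covering the union of both layers' genes.
#' @export
classify_transcriptome <- function(protein_profile, mrna_profile,
                                   detection_profile,
                                   comparison_set = c("HSC", "MPPa", "MPPb", "MPPc"),
                                   min_reps = 3L, tpm_floor = 0) {
  comparison_set <- intersect(
    comparison_set,
    intersect(cell_type_columns(protein_profile), cell_type_columns(mrna_profile))
  )
  if (length(comparison_set) < 2L) abort("comparison set needs at least 2 cell types")
  genes <- sort(union(protein_profile$gene, mrna_profile$gene))
  align <- function(profile, fill = 0) {
    assert_columns(profile, comparison_set, "profile")
    m <- matrix(fill, nrow = length(genes), ncol = length(comparison_set),
                dimnames = list(genes, comparison_set))
    keep <- profile$gene %in% genes
    idx <- match(profile$gene[keep], genes)
    for (ct in comparison_set) m[idx, ct] <- profile[[ct]][keep]
    m
  }
  prot <- align(protein_profile) > 0
  mrna <- align(mrna_profile) > tpm_floor
  counts <- align(detection_profile, fill = 0L)

  category <- matrix("absent", nrow = length(genes), ncol = length(comparison_set),
                     dimnames = list(genes, comparison_set))
  category[mrna & prot] <- "both"
  category[mrna & !prot] <- "mRNA_only"

  is_m_only <- category == "mRNA_only"
  n_m_only <- rowSums(is_m_only)
  strong_other <- matrix(FALSE, length(genes), length(comparison_set))
  for (j in seq_along(comparison_set)) {
    strong_other[, j] <- rowSums(counts[, -j, drop = FALSE] >= min_reps) > 0L
  }
  unique_flag <- is_m_only & (n_m_only == 1L) & strong_other

  tibble(
    gene = rep(genes, times = length(comparison_set)),
    cell_type = rep(comparison_set, each = length(genes)),
    category = as.vector(category),
    unique_mrna_only = as.vector(unique_flag)
  )
}

#' Principal component embedding of all replicates
#'
#' Log2-transforms the normalized matrix after adding a fraction (default
#' 1/1000) of the global non-zero minimum, then runs a centered (unscaled)
#' singular value decomposition with replicates as observations and genes
#' as features. Components are ordered by explained variance, and each
#' component's sign is fixed by making its largest-magnitude gene loading
#' positive so runs are reproducible.
#'
#' @param mat A normalized [replicate_matrix()] with >= 2 replicates.
#' @param offset_fraction Fraction of the global non-zero minimum used as
#'   the log offset (default 1/1000).
#' @return An object of class `proteome_pca`: list with `scores`
#'   (replicate x component tibble joined to the design), `loadings`
#'   (gene x component tibble), `variance` (per-component explained
#'   variance) and `offset`.
#' @export
pca_embed <- function(mat, offset_fraction = 1 / 1000) {
  design <- matrix_design(mat)
  if (nrow(design) < 2L) abort("PCA needs at least 2 replicates")
  vm <- value_matrix(as_tibble(mat), design)
  offset <- pca_offset(vm, offset_fraction)
  lg <- t(log2(vm + offset)) # replicates x genes
  fit <- prcomp(lg, center = TRUE, scale. = FALSE)
  # Deterministic sign: largest-magnitude loading positive per component.
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  scores <- bind_cols(design, as_tibble(fit$x))
  loadings <- bind_cols(tibble(gene = rownames(fit$rotation)), as_tibble(fit$rotation))
  structure(
    list(
      scores = scores, loadings = loadings,
      variance = fit$sdev^2, offset = offset
    ),
    class = "proteome_pca"
  )
}

#' @export
print.proteome_pca <- function(x, ...) {
  pct <- 100 * x$variance / sum(x$variance)
  cat(sprintf(
    "<proteome_pca> %d replicates, %d genes; PC1 %.1f%%, PC2 %.1f%% of variance\n",
    nrow(x$scores), nrow(x$loadings), pct[1L], pct[min(2L, length(pct))]
  ))
  invisible(x)
}
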