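#' Per-gene, per-cell-type detection counts
#'
#' Counts, for every gene and cell type, the number of replicates with a
#' strictly positive value. "Detected" throughout the pipeline means a
#' strictly positive (normalized) intensity; no floor above zero is used.
#'
#' @param mat A [replicate_matrix()].
#' @param age Optional age restriction (see [aggregate_profile()]).
#' @return A tibble with a `gene` column and one integer count column per
#'   cell type; attribute `n_reps` holds the per-cell-type replicate totals.
#' @examples
#' d <- study_design("HSC", 6)
#' m <- replicate_matrix(cbind(
#'   data.frame(gene = "A"),
#'   as.data.frame(as.list(setNames(c(0, 0, 1, 2, 0, 3), d$replicate_id)))
#' ), d)
#' detection_counts(m) # count 3 of 6
#' @export
detection_counts <- function(mat, age = NULL) {
  design <- matrix_design(mat)
  if (!is.null(age)) {
    design <- design[design$age %in% age, , drop = FALSE]
    if (nrow(design) == 0L) abort("no replicates left after age restriction")
  }
  label <- if (dplyr::n_distinct(design$age) > 1L) {
    paste(design$cell_type, design$age, sep = ".")
  } else {
    design$cell_type
  }
  vm <- value_matrix(as_tibble(mat), design)
  out <- tibble(gene = as_tibble(mat)$gene)
  n_reps <- integer(0)
  for (ct in unique(label)) {
    cols <- design$replicate_id[label == ct]
    out[[ct]] <- as.integer(rowSums(vm[, cols, drop = FALSE] > 0))
    n_reps[ct] <- length(cols)
  }
  attr(out, "n_reps") <- n_reps
  out
}

cell_type_columns <- function(profile) setdiff(names(profile), "gene")

#' Discovery-saturation curve for one cell type
#'
#' Cumulative count of distinct genes detected after each additional
#' replicate, replicates taken in acquisition order. The final value equals
#' the number of genes detected in at least one replicate, whatever the
#' ordering.
#'
#' @param mat A [replicate_matrix()].
#' @param cell_type Cell type to trace.
#' @param age Age group of the traced cell type (default `"young"` when
#'   present in the design, otherwise the design's single age).
#' @return A tibble with `order`, `replicate_id`, `cumulative` (distinct
#'   genes so far) and `new` (genes first seen at this replicate).
#' @export
discovery_curve <- function(mat, cell_type, age = NULL) {
  design <- matrix_design(mat)
  age <- age %||% (if ("young" %in% design$age) "young" else design$age[1L])
  design <- design[design$cell_type == cell_type & design$age == age, , drop = FALSE]
  if (nrow(design) == 0L) abort(sprintf("no replicates for cell type '%s'", cell_type))
  design <- design[order(design$order), , drop = FALSE]
  vm <- value_matrix(as_tibble(mat), design) > 0
  seen <- rep(FALSE, nrow(vm))
  cumulative <- integer(nrow(design))
  newly <- integer(nrow(design))
  for (i in seq_len(nrow(design))) {
    newly[i] <- sum(vm[, i] & !seen)
    seen <- seen | vm[, i]
    cumulative[i] <- sum(seen)
  }
  tibble(
    order = design$order, replicate_id = design$replicate_id,
    cumulative = cumulative, new = newly
  )
}

#' Partition detected genes by their detection pattern
#'
#' Every gene detected in at least one cell type of the stated universe is
#' assigned to exactly one pattern: the subset of cell types in which it
#' has at least one detected replicate. Pattern counts therefore sum to the
#' number of detected genes.
#'
#' @param profile Detection-count tibble from [detection_counts()].
#' @param universe Cell types to consider (default: all columns).
#' @return A tibble with `pattern` (cell types joined by `+`, in universe
#'   order), `n_cell_types`, `n_genes`, and a `genes` list column, sorted
#'   by descending `n_genes`.
#' @export
detection_partition <- function(profile, universe = cell_type_columns(profile)) {
  missing <- setdiff(universe, names(profile))
  if (length(missing) > 0L) {
    abort(sprintf("profile lacks cell type(s): %s", paste(missing, collapse = ", ")))
  }
  cm <- as.matrix(profile[, universe, drop = FALSE]) >= 1L
  detected <- rowSums(cm) > 0L
  pattern <- apply(cm[detected, , drop = FALSE], 1L, function(z) {
    paste(universe[z], collapse = "+")
  })
  tibble(gene = profile$gene[detected], pattern = pattern) |>
    group_by(.data$pattern) |>
    summarise(
      n_genes = dplyr::n(),
      genes = list(sort(.data$gene)),
      .groups = "drop"
    ) |>
    mutate(n_cell_types = lengths(strsplit(.data$pattern, "+", fixed = TRUE))) |>
    arrange(dplyr::desc(.data$n_genes)) |>
    select("pattern", "n_cell_types", "n_genes", "genes")
}

#' Genes detected only in one cell type
#'
#' @param profile Detection-count tibble from [detection_counts()].
#' @param cell_type Target cell type.
#' @return Character vector of genes with count >= 1 in `cell_type` and 0
#'   everywhere else.
#' @export
uniquely_detected <- function(profile, cell_type) {
  others <- setdiff(cell_type_columns(profile), cell_type)
  if (!cell_type %in% names(profile)) abort(sprintf("unknown cell type '%s'", cell_type))
  target <- profile[[cell_type]] >= 1L
  elsewhere <- rowSums(as.matrix(profile[, others, drop = FALSE]) >= 1L) > 0L
  sort(profile$gene[target & !elsewhere])
}

#' Genes confidently absent from one cell type
#'
#' A gene counts as uniquely absent when it has no detected replicate in
#' the target cell type but is detected in at least `min_reps` replicates
#' of at least one other cell type -- i.e. it is readily detectable by the
#' assay, so its absence is unlikely to be a sensitivity artifact.
#'
#' @param profile Detection-count tibble from [detection_counts()].
#' @param cell_type Target cell type.
#' @param min_reps Replicate floor required elsewhere (default 3).
#' @return Character vector of gene identifiers.
#' @export
uniquely_absent <- function(profile, cell_type, min_reps = 3L) {
  if (!cell_type %in% names(profile)) abort(sprintf("unknown cell type '%s'", cell_type))
  n_reps <- attr(profile, "n_reps")
  if (!is.null(n_reps) && min_reps > max(n_reps)) {
    abort("min_reps exceeds the largest replicate count in the design")
  }
  others <- setdiff(cell_type_columns(profile), cell_type)
  absent <- profile[[cell_type]] == 0L
  strong <- rowSums(as.matrix(profile[, others, drop = FALSE]) >= min_reps) > 0L
  sort(profile$gene[absent & strong])
}

#' Proteins more detectable in old than in young cells
#'
#' Within genes detected in at least `min_reps` old replicates, selects
#' those that are either (a) undetected in young, or (b) among the top
#' `top_frac` of old/young aggregated-intensity ratios, computed over genes
#' detected in both ages. Ties at the ranking cutoff are broken by
#' lexicographic gene id so the list is deterministic.
#'
#' @param old_counts,young_counts Single-cell-type detection-count tibbles
#'   (columns `gene` + the cell type) for the old and young populations.
#' @param old_values,young_values Aggregated (non-zero mean) profiles with
#'   the same single cell type column.
#' @param cell_type Cell type column name shared by all four tables
#'   (default `"HSC"`).
#' @param min_reps Old-replicate floor (default 3).
#' @param top_frac Fraction for the fold-change branch (default 0.025).
#' @return A tibble with `gene`, `branch` (`"undetected_young"` or
#'   `"top_fold_change"`), `old_value`, `young_value`, `log2_ratio`.
#' @export
old_young_differential <- function(old_counts, young_counts, old_values,
                                   young_values, cell_type = "HSC",
                                   min_reps = 3L, top_frac = 0.025) {
  for (tb in list(old_counts, young_counts, old_values, young_values)) {
    assert_columns(tb, c("gene", cell_type))
  }
  base <- tibble(gene = old_counts$gene, old_n = old_counts[[cell_type]]) |>
    inner_join(
      tibble(gene = young_counts$gene, young_n = young_counts[[cell_type]]),
      by = "gene"
    ) |>
    inner_join(
      tibble(gene = old_values$gene, old_value = old_values[[cell_type]]),
      by = "gene"
    ) |>
    inner_join(
      tibble(gene = young_values$gene, young_value = young_values[[cell_type]]),
      by = "gene"
    ) |>
    filter(.data$old_n >= min_reps)

  branch_a <- base |> filter(.data$young_n == 0L)
  both <- base |> filter(.data$young_n >= 1L, .data$young_value > 0)
  k <- ceiling_frac(top_frac, nrow(both))
  top_genes <- top_k_lex(both$old_value / both$young_value, both$gene, k)
  branch_b <- both |> filter(.data$gene %in% top_genes)

  bind_rows(
    branch_a |> mutate(branch = "undetected_young"),
    branch_b |> mutate(branch = "top_fold_change")
  ) |>
    mutate(log2_ratio = ifelse(
      .data$young_value > 0, log2(.data$old_value / .data$young_value), Inf
    )) |>
    arrange(.data$branch, .data$gene) |>
    select("gene", "branch", "old_value", "young_value", "log2_ratio")
}

#' Cell type holding each ribosomal protein's unique minimum
#'
#' For genes with a ribosomal-protein prefix (`Rpl`/`Rps`), finds the cell
#' type with the uniquely lowest aggregated intensity (including a unique
#' zero). Genes with two or more zero cell types -- or a tie at a non-zero
#' minimum -- are classified as `"other"`, keeping the output a partition
#' of the prefixed genes.
#'
#' @param profile Aggregated profile tibble (`gene` + cell-type columns).
#' @param prefixes Gene-symbol prefixes selecting ribosomal proteins.
#' @return A tibble with `cell_type` (or `"other"`) and `n_genes`;
#'   attribute `assignments` carries the per-gene assignment.
#' @export
ribosomal_min_profile <- function(profile, prefixes = c("Rpl", "Rps")) {
  cts <- cell_type_columns(profile)
  keep <- Reduce(`|`, lapply(prefixes, function(p) startsWith(profile$gene, p)))
  sub <- profile[keep, , drop = FALSE]
  vm <- as.matrix(sub[, cts, drop = FALSE])
  assign_one <- function(v) {
    zeros <- which(v == 0)
    if (length(zeros) >= 2L) return("other")
    mins <- which(v == min(v))
    if (length(mins) > 1L) return("other")
    cts[mins]
  }
  assignment <- apply(vm, 1L, assign_one)
  assignments <- tibble(gene = sub$gene, assigned = assignment)
  out <- assignments |>
    count(.data$assigned, name = "n_genes") |>
    rename(cell_type = "assigned") |>
    arrange(dplyr::desc(.data$n_genes))
  attr(out, "assignments") <- assignments
  out
}
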