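#' Normalize each replicate to a total intensity of one million
#'
#' Every replicate column is divided by its total intensity and multiplied
#' by 1e6, putting all replicates on a common parts-per-million-like scale.
#' Zeros stay exactly zero and the transformation is scale-invariant per
#' column.
#'
#' @param mat A [replicate_matrix()] with at least one positive value per
#'   replicate.
#' @return A [replicate_matrix()] whose columns each sum to 1,000,000.
#' @examples
#' d <- study_design("HSC", 1)
#' m <- replicate_matrix(
#'   data.frame(gene = c("A", "B", "C"), HSC_young_r1 = c(1, 1, 2)), d
#' )
#' normalize_replicates(m)
#' @export
normalize_replicates <- function(mat) {
  design <- matrix_design(mat)
  out <- as_tibble(mat)
  for (col in design$replicate_id) {
    total <- sum(out[[col]])
    if (total <= 0) {
      abort(sprintf("replicate '%s' is all zero; no total intensity to divide by", col))
    }
    out[[col]] <- out[[col]] / total * 1e6
  }
  replicate_matrix(out, design, layer = matrix_layer(mat))
}

#' Aggregate replicates into per-cell-type profiles
#'
#' Collapses the replicates of each cell type to one value per gene.
#' `nonzero_mean` (the proteomics convention here) averages strictly
#' positive values only, returning 0 when a gene is undetected in all
#' replicates; `mean` (the transcriptomics convention) is the plain
#' arithmetic mean over all replicates.
#'
#' @param mat A [replicate_matrix()].
#' @param mode `"nonzero_mean"` or `"mean"`.
#' @param age Restrict to one age group (`NULL` keeps all; cell types are
#'   then labelled `cell_type` for a single age, or `cell_type.age` if both
#'   ages are present).
#' @return A tibble with a `gene` column and one column per cell type.
#' @examples
#' d <- study_design("HSC", 3)
#' m <- replicate_matrix(
#'   data.frame(gene = "A", HSC_young_r1 = 0, HSC_young_r2 = 10,
#'              HSC_young_r3 = 20), d
#' )
#' aggregate_profile(m, "nonzero_mean") # 15
#' aggregate_profile(m, "mean")         # 10
#' @export
aggregate_profile <- function(mat, mode = c("nonzero_mean", "mean"), age = NULL) {
  mode <- match.arg(mode)
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
  for (ct in unique(label)) {
    cols <- design$replicate_id[label == ct]
    block <- vm[, cols, drop = FALSE]
    out[[ct]] <- unname(if (mode == "mean") {
      rowMeans(block)
    } else {
      pos <- block > 0
      npos <- rowSums(pos)
      sums <- rowSums(block)
      ifelse(npos > 0L, sums / npos, 0)
    })
  }
  attr(out, "aggregation_mode") <- mode
  out
}

#' Log2 transform after adding a positive offset
#'
#' `log2(x + offset)` with a strictly positive offset so that zeros
#' (non-detections) map to a finite floor clearly separated from low but
#' detected values. Different stages of the pipeline use different offset
#' constants: 1e-4 for protein-vs-mRNA scatter input, 1e-5 for fold-change
#' computation touching zeros, and 1/1000 of the global non-zero minimum
#' for the PCA input (see [pca_offset()]).
#'
#' @param x Numeric vector/matrix of non-negative values.
#' @param offset Strictly positive constant.
#' @return `log2(x + offset)`.
#' @examples
#' log2_offset(0, 1e-4) # about -13.29
#' @export
log2_offset <- function(x, offset) {
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0) {
    abort("offset must be a single positive number")
  }
  log2(x + offset)
}

#' Offset for PCA input: 1/1000 of the global non-zero minimum
#'
#' @param mat A [replicate_matrix()] (or numeric matrix/tibble of values).
#' @param fraction Fraction of the global non-zero minimum (default 1/1000).
#' @return A single positive offset.
#' @export
pca_offset <- function(mat, fraction = 1 / 1000) {
  vm <- if (inherits(mat, "replicate_matrix")) {
    value_matrix(as_tibble(mat), matrix_design(mat))
  } else {
    as.matrix(mat)
  }
  pos <- vm[vm > 0]
  if (length(pos) == 0L) abort("matrix has no positive values")
  min(pos) * fraction
}

#' Relative percent abundance with respect to a grand mean
#'
#' Each replicate value is divided by the grand mean of the reference
#' values and multiplied by 100, the transformation used to graph a single
#' gene's protein and mRNA levels side by side on a common percent scale.
#'
#' @param values Numeric vector of replicate values.
#' @param reference Values whose mean defines 100% (defaults to `values`).
#' @return Percentages, same length as `values`.
#' @examples
#' relative_percent(c(0, 2)) # 0, 200
#' @export
relative_percent <- function(values, reference = values) {
  grand <- mean(reference)
  if (!is.finite(grand) || grand <= 0) {
    abort("grand mean of the reference values must be positive")
  }
  values / grand * 100
}

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated_density - area * background_mean`. Negative CTCF is a
#' legal outcome (cell dimmer than background). The usual downstream
#' readout is the plain quotient of a protein CTCF and the matched DAPI
#' CTCF.
#'
#' @param integrated_density Integrated fluorescence density of the cell.
#' @param area Cell area (>= 0).
#' @param background_mean Mean background fluorescence.
#' @return CTCF value(s).
#' @examples
#' ctcf(1000, 10, 50) # 500
#' @export
ctcf <- function(integrated_density, area, background_mean) {
  if (any(area < 0)) abort("area must be non-negative")
  integrated_density - area * background_mean
}
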