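#' Construct a study design table
#'
#' A study design assigns every replicate column of a replicate-level
#' intensity table to a cell type, an age group and an acquisition order.
#' Orders within a cell type run 1..n with no gaps, so discovery-saturation
#' curves have a well-defined replicate sequence.
#'
#' @param cell_types Character vector, one entry per replicate block.
#' @param n_replicates Integer vector, replicates per cell type (recycled).
#' @param age Character vector of age groups (`"young"`/`"old"`), recycled.
#'
#' @return A tibble with columns `replicate_id`, `cell_type`, `age`, `order`.
#' @examples
#' study_design(c("HSC", "MPPa"), n_replicates = 2)
#' @export
study_design <- function(cell_types, n_replicates = 6L, age = "young") {
  stopifnot(length(cell_types) >= 1L)
  n_replicates <- rep_len(as.integer(n_replicates), length(cell_types))
  age <- rep_len(age, length(cell_types))
  if (any(n_replicates < 1L)) abort("every cell type needs at least one replicate")
  if (anyDuplicated(paste(cell_types, age))) {
    abort("duplicated cell type / age combination in design")
  }
  purrr::pmap(
    list(cell_types, n_replicates, age),
    function(ct, n, a) {
      tibble(
        replicate_id = sprintf("%s_%s_r%d", ct, a, seq_len(n)),
        cell_type = ct,
        age = a,
        order = seq_len(n)
      )
    }
  ) |>
    bind_rows()
}

#' Default 12-cell-type hematopoietic study design
#'
#' The layout of the full young + old mouse stem/progenitor study: eight
#' young cell types (HSC, MPPa, MPPb, MPPc, CMP, GMP, MEP, CLP) with six
#' replicates each, old HSC with six, and the three old MPPs with four.
#'
#' @param old_mpp_replicates Replicates per old MPP population (default 4).
#' @return A study-design tibble (66 replicates with the defaults).
#' @examples
#' nrow(hspc_design())
#' @export
hspc_design <- function(old_mpp_replicates = 4L) {
  young <- study_design(
    c("HSC", "MPPa", "MPPb", "MPPc", "CMP", "GMP", "MEP", "CLP"),
    n_replicates = 6L, age = "young"
  )
  old <- study_design(
    c("HSC", "MPPa", "MPPb", "MPPc"),
    n_replicates = c(6L, rep(old_mpp_replicates, 3L)), age = "old"
  )
  bind_rows(young, old)
}

validate_design <- function(design) {
  assert_columns(design, c("replicate_id", "cell_type", "age", "order"), "design")
  if (anyDuplicated(design$replicate_id)) abort("replicate ids must be unique")
  bad <- design |>
    group_by(.data$cell_type, .data$age) |>
    summarise(ok = identical(sort(.data$order), seq_along(.data$order)), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "acquisition orders must be 1..n with no gaps (violated for %s)",
      paste(bad$cell_type, collapse = ", ")
    ))
  }
  invisible(design)
}

#' Assemble a replicate-level matrix table
#'
#' Bundles a genes x replicates value table with its study design and layer
#' tag. The table keeps one `gene` column of unique harmonized identifiers
#' plus one numeric, non-negative column per design replicate.
#'
#' @param values Data frame with a `gene` column and one column per
#'   replicate in `design`.
#' @param design Study-design tibble (see [study_design()]).
#' @param layer `"proteome"` or `"transcriptome"`.
#' @return A tibble with attributes `design` and `layer`
#'   (class `replicate_matrix`).
#' @examples
#' d <- study_design("HSC", 2)
#' replicate_matrix(
#'   data.frame(gene = c("A", "B"), HSC_young_r1 = 1:2, HSC_young_r2 = 3:4),
#'   d
#' )
#' @export
replicate_matrix <- function(values, design, layer = c("proteome", "transcriptome")) {
  layer <- match.arg(layer)
  validate_design(design)
  values <- as_tibble(values)
  assert_columns(values, "gene", "values")
  missing <- setdiff(design$replicate_id, names(values))
  if (length(missing) > 0L) {
    abort(sprintf(
      "value table is missing replicate column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  extra <- setdiff(names(values), c("gene", design$replicate_id))
  if (length(extra) > 0L) {
    abort(sprintf(
      "value table has column(s) not assigned in the design: %s",
      paste(extra, collapse = ", ")
    ))
  }
  if (anyDuplicated(values$gene)) abort("gene identifiers must be unique")
  vm <- as.matrix(values[, design$replicate_id, drop = FALSE])
  if (!is.numeric(vm)) abort("replicate columns must be numeric")
  if (anyNA(vm)) abort("replicate columns must not contain missing values")
  if (any(vm < 0)) abort("intensity values must be non-negative")
  out <- values[, c("gene", design$replicate_id)]
  attr(out, "design") <- design
  attr(out, "layer") <- layer
  class(out) <- c("replicate_matrix", class(tibble()))
  out
}

#' Study design attached to a replicate matrix
#' @param mat A [replicate_matrix()].
#' @return The design tibble.
#' @export
matrix_design <- function(mat) {
  d <- attr(mat, "design")
  if (is.null(d)) abort("object carries no study design; use replicate_matrix()")
  d
}

#' Layer tag of a replicate matrix
#' @param mat A [replicate_matrix()].
#' @return `"proteome"` or `"transcriptome"`.
#' @export
matrix_layer <- function(mat) attr(mat, "layer") %||% "proteome"

#' @export
print.replicate_matrix <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf(
    "<replicate_matrix> %s: %d genes x %d replicates (%d cell types)\n",
    matrix_layer(x), nrow(x), nrow(d), dplyr::n_distinct(d$cell_type, d$age)
  ))
  NextMethod()
}
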