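#' Read a genes x replicates table from disk
#'
#' Reads a tab-delimited (`.tsv`/`.txt`) or comma-delimited (`.csv`) table
#' with a leading identifier column and one column per replicate, validates
#' it against the study design, and returns a [replicate_matrix()].
#' Non-numeric or blank intensity cells are a hard error naming the cell.
#'
#' @param path File path.
#' @param design Study design the columns must satisfy.
#' @param layer Layer tag for the matrix.
#' @return A [replicate_matrix()].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, design, layer = "proteome") {
  validate_design(design)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  names(raw)[1L] <- "gene"
  missing <- setdiff(design$replicate_id, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf(
      "file %s is missing replicate column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  for (col in design$replicate_id) {
    x <- raw[[col]]
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(num))
    if (length(bad) > 0L) {
      abort(sprintf(
        "non-numeric or blank value in %s at row %d, column '%s' ('%s')",
        path, bad[1L], col, x[bad[1L]] %||% ""
      ))
    }
    raw[[col]] <- num
  }
  replicate_matrix(raw[, c("gene", design$replicate_id)], design, layer = layer)
}

#' Write a replicate matrix to disk
#'
#' Writes the table with full precision (17 significant digits) so that
#' `read_matrix(write_matrix(m))` round-trips decimal-representable values
#' bit-exactly.
#'
#' @param mat A [replicate_matrix()].
#' @param path Destination; `.csv` writes comma-delimited, anything else
#'   tab-delimited.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  design <- matrix_design(mat)
  out <- as_tibble(mat)[, c("gene", design$replicate_id)]
  for (col in design$replicate_id) {
    out[[col]] <- format(out[[col]], digits = 17, scientific = FALSE, trim = TRUE)
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(out, path, progress = FALSE)
  } else {
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then members. Duplicate members
#' within a set are removed; empty sets are retained with size zero and
#' flagged so downstream filters can report them.
#'
#' @param path GMT file path.
#' @return A tibble with columns `set`, `n_genes`, `genes` (list column)
#'   and `empty` flag.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  tibble(
    set = names(sets),
    genes = map(unname(sets), unique)
  ) |>
    mutate(
      n_genes = purrr::map_int(.data$genes, length),
      empty = .data$n_genes == 0L
    ) |>
    select("set", "n_genes", "genes", "empty")
}

#' Write a gene-set collection to GMT
#'
#' @param collection Tibble as returned by [read_gmt()].
#' @param path Destination path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "na") {
  lines <- purrr::map2_chr(
    collection$set, collection$genes,
    function(nm, g) paste(c(nm, description, g), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA -> putative-target table
#'
#' Two-column tab-delimited table in the miRDB dialect: miRNA identifier
#' (e.g. `mmu-miR-29a-3p`) and target gene identifier. Rows can be
#' restricted to one species by identifier prefix (`"mmu"` for mouse).
#' Targets are deduplicated per miRNA.
#'
#' @param path File path (no header).
#' @param species_filter Identifier prefix to keep, or `NULL` for all rows.
#' @return A tibble with columns `mirna`, `n_targets`, `targets`
#'   (list column); miRNAs emptied by the filter are kept with size 0 and
#'   `empty = TRUE`.
#' @export
read_target_map <- function(path, species_filter = "mmu") {
  tb <- readr::read_tsv(
    path, col_names = c("mirna", "target"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  all_mirnas <- unique(tb$mirna)
  if (!is.null(species_filter)) {
    keep_mirnas <- all_mirnas[startsWith(all_mirnas, species_filter)]
    tb <- tb |> filter(startsWith(.data$mirna, species_filter))
  } else {
    keep_mirnas <- all_mirnas
  }
  out <- tb |>
    group_by(.data$mirna) |>
    summarise(targets = list(unique(.data$target)), .groups = "drop")
  missing <- setdiff(keep_mirnas, out$mirna)
  if (length(missing) > 0L) {
    out <- bind_rows(out, tibble(mirna = missing, targets = list(character(0))))
  }
  out |>
    mutate(
      n_targets = purrr::map_int(.data$targets, length),
      empty = .data$n_targets == 0L
    ) |>
    arrange(.data$mirna) |>
    select("mirna", "n_targets", "targets", "empty")
}

#' Write a miRNA target map
#'
#' @param target_map Tibble as returned by [read_target_map()].
#' @param path Destination path (two-column tab-delimited, no header).
#' @return `path`, invisibly.
#' @export
write_target_map <- function(target_map, path) {
  long <- target_map |>
    select("mirna", "targets") |>
    tidyr::unnest_longer("targets", values_to = "target")
  readr::write_tsv(
    long[, c("mirna", "target")], path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}
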