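#' Harmonize gene / protein identifiers and assemble one replicate table
#'
#' Search engines report overlapping but inconsistent pairs of gene symbols
#' and protein accessions (isoforms, synonyms, one-sided identifiers).
#' This step groups mutually-mapped symbols and accessions into equivalence
#' groups, picks one deterministic representative per group, fills the
#' one-sided identifiers with placeholders, and compiles the per-replicate
#' intensity tables into a single genes x replicates table.
#'
#' Grouping is a connected-components pass over the bipartite symbol /
#' accession graph built from the mapping table and from co-occurrence in
#' the raw tables. Within a replicate, rows falling into one group are
#' summed (they are the same molecular species measured under two labels).
#' Identifiers are matched case-sensitively after stripping surrounding
#' whitespace. The group representative is the lexicographically smallest
#' gene symbol (accessions likewise); accessions with no symbol receive a
#' `"Unm <k>"` gene-name placeholder, symbols with no accession a
#' `"UNM <k>"` protein-id placeholder, `k` assigned in input order.
#'
#' @param raw_tables Named list of per-replicate data frames with columns
#'   `gene_symbol`, `protein_accession`, `intensity`. Names must be the
#'   design's replicate ids. Empty strings / `NA` mark missing identifiers.
#' @param mapping Data frame with columns `gene_symbol`,
#'   `protein_accession` and optionally `entrez_id`, giving known
#'   equivalences (a symbol may map to several accessions and vice versa).
#' @param design Study design covering exactly `names(raw_tables)`.
#' @param layer Layer tag for the output matrix.
#'
#' @return A list with elements
#'   * `matrix`: a [replicate_matrix()] with one row per equivalence group,
#'     keyed by the representative gene symbol, plus the representative
#'     accession and (when available) Entrez id carried in a `key` table
#'     attached as attribute `"keys"`;
#'   * `report`: tibble with counts of symbol-less and accession-less
#'     groups, merged rows, and all placeholder assignments.
#' @examples
#' d <- study_design("HSC", 1)
#' raw <- list(HSC_young_r1 = data.frame(
#'   gene_symbol = c("Hprt", "Pfkl"),
#'   protein_accession = c("P1", "P2"),
#'   intensity = c(10, 20)
#' ))
#' map <- data.frame(gene_symbol = c("Hprt", "Pfkl"),
#'                   protein_accession = c("P1", "P2"))
#' harmonize_ids(raw, map, d)$report
#' @export
harmonize_ids <- function(raw_tables, mapping, design, layer = "proteome") {
  stopifnot(is.list(raw_tables), length(raw_tables) >= 1L)
  validate_design(design)
  if (!setequal(names(raw_tables), design$replicate_id)) {
    abort("names(raw_tables) must match the design replicate ids")
  }
  mapping <- as_tibble(mapping)
  assert_columns(mapping, c("gene_symbol", "protein_accession"), "mapping")

  canon <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% c("", "nan", "2 SV") | is.na(x)] <- NA_character_
    x
  }
  mapping <- mapping |>
    mutate(
      gene_symbol = canon(.data$gene_symbol),
      protein_accession = canon(.data$protein_accession)
    )

  if ("entrez_id" %in% names(mapping)) {
    conflict <- mapping |>
      filter(!is.na(.data$gene_symbol), !is.na(.data$entrez_id)) |>
      distinct(.data$gene_symbol, .data$entrez_id) |>
      count(.data$gene_symbol) |>
      filter(.data$n > 1L)
    if (nrow(conflict) > 0L) {
      abort(sprintf(
        "conflicting mapping: symbol(s) %s assigned to more than one Entrez id",
        paste(conflict$gene_symbol, collapse = ", ")
      ))
    }
  }

  raw <- imap(raw_tables, function(tb, rep_id) {
    tb <- as_tibble(tb)
    assert_columns(tb, c("gene_symbol", "protein_accession", "intensity"), rep_id)
    tb |>
      mutate(
        gene_symbol = canon(.data$gene_symbol),
        protein_accession = canon(.data$protein_accession),
        replicate_id = rep_id
      )
  }) |>
    bind_rows()
  if (any(is.na(raw$gene_symbol) & is.na(raw$protein_accession))) {
    abort("raw rows with neither a gene symbol nor an accession cannot be compiled")
  }

  # Placeholders, assigned in input order, live in a namespace ("Unm <k>" /
  # "UNM <k>") that search engines and UniProt never emit, so they cannot
  # collide with real identifiers.
  sym_less <- unique(raw$protein_accession[is.na(raw$gene_symbol)])
  sym_less <- setdiff(sym_less, mapping$protein_accession[!is.na(mapping$gene_symbol)])
  acc_less <- unique(raw$gene_symbol[is.na(raw$protein_accession)])
  acc_less <- setdiff(acc_less, mapping$gene_symbol[!is.na(mapping$protein_accession)])
  placeholder_sym <- setNames(sprintf("Unm %d", seq_along(sym_less)), sym_less)
  placeholder_acc <- setNames(sprintf("UNM %d", seq_along(acc_less)), acc_less)
  universe <- unique(c(
    raw$gene_symbol, raw$protein_accession,
    mapping$gene_symbol, mapping$protein_accession
  ))
  if (any(c(placeholder_sym, placeholder_acc) %in% universe)) {
    abort("placeholder identifier collides with a real identifier in the input")
  }

  fill_ids <- function(tb) {
    sym <- tb$gene_symbol
    acc <- tb$protein_accession
    idx <- is.na(sym) & acc %in% names(placeholder_sym)
    sym[idx] <- placeholder_sym[acc[idx]]
    idx <- is.na(acc) & sym %in% names(placeholder_acc)
    acc[idx] <- placeholder_acc[sym[idx]]
    tb$gene_symbol <- sym
    tb$protein_accession <- acc
    tb
  }
  raw <- fill_ids(raw)
  mapping_pairs <- mapping |>
    filter(!is.na(.data$gene_symbol), !is.na(.data$protein_accession)) |>
    distinct(.data$gene_symbol, .data$protein_accession)

  # Connected components over the bipartite identifier graph.
  edges <- bind_rows(
    mapping_pairs,
    raw |>
      filter(!is.na(.data$gene_symbol), !is.na(.data$protein_accession)) |>
      distinct(.data$gene_symbol, .data$protein_accession)
  ) |>
    distinct()
  g <- igraph::graph_from_data_frame(
    data.frame(
      from = paste0("S|", edges$gene_symbol),
      to = paste0("P|", edges$protein_accession)
    ),
    directed = FALSE
  )
  comp <- igraph::components(g)$membership
  node <- names(comp)
  node_type <- substr(node, 1L, 1L)
  node_id <- substring(node, 3L)
  groups <- tibble(member = node_id, type = node_type, group = unname(comp))
  reps <- groups |>
    group_by(.data$group) |>
    summarise(
      rep_symbol = if (any(.data$type == "S")) min(.data$member[.data$type == "S"]) else NA_character_,
      rep_accession = if (any(.data$type == "P")) min(.data$member[.data$type == "P"]) else NA_character_,
      .groups = "drop"
    )

  sym_to_group <- groups |> filter(.data$type == "S")
  acc_to_group <- groups |> filter(.data$type == "P")
  raw <- raw |>
    left_join(
      setNames(sym_to_group[, c("member", "group")], c("gene_symbol", "group")),
      by = "gene_symbol"
    ) |>
    left_join(
      setNames(acc_to_group[, c("member", "group")], c("protein_accession", "group_acc")),
      by = "protein_accession"
    ) |>
    mutate(group = dplyr::coalesce(.data$group, .data$group_acc)) |>
    select(-"group_acc")
  if (anyNA(raw$group)) abort("internal error: ungrouped compiled row")

  compiled <- raw |>
    group_by(.data$group, .data$replicate_id) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    left_join(reps, by = "group")

  n_merged <- raw |>
    count(.data$group, .data$replicate_id) |>
    summarise(n = sum(.data$n - 1L)) |>
    pull(.data$n)

  wide <- compiled |>
    select("rep_symbol", "rep_accession", "replicate_id", "intensity") |>
    tidyr::pivot_wider(
      names_from = "replicate_id", values_from = "intensity", values_fill = 0
    ) |>
    arrange(.data$rep_symbol)
  for (rep_id in setdiff(design$replicate_id, names(wide))) wide[[rep_id]] <- 0
  keys <- wide |>
    select(gene = "rep_symbol", accession = "rep_accession")
  if ("entrez_id" %in% names(mapping)) {
    keys <- keys |>
      left_join(
        mapping |>
          filter(!is.na(.data$gene_symbol)) |>
          distinct(gene = .data$gene_symbol, entrez_id = .data$entrez_id),
        by = "gene"
      )
  }
  mat <- replicate_matrix(
    wide |> select(gene = "rep_symbol", all_of(design$replicate_id)),
    design, layer = layer
  )
  attr(mat, "keys") <- keys

  report <- tibble(
    n_symbol_missing = length(sym_less),
    n_accession_missing = length(acc_less),
    n_groups = nrow(wide),
    n_merged_rows = n_merged
  )
  attr(report, "placeholders") <- list(
    symbols = placeholder_sym, accessions = placeholder_acc
  )
  list(matrix = mat, report = report)
}
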