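# Fixture builders shared across test files. All fixtures are constructed
# in code; nothing is read from disk except explicit round-trip tests.

# A replicate matrix from a plain genes x replicates numeric matrix.
toy_matrix <- function(values, cell_types, n_replicates, age = "young",
                       layer = "proteome", genes = NULL) {
  design <- study_design(cell_types, n_replicates, age = age)
  values <- as.matrix(values)
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(values)))
  stopifnot(ncol(values) == nrow(design))
  df <- data.frame(gene = genes, values)
  names(df) <- c("gene", design$replicate_id)
  replicate_matrix(df, design, layer = layer)
}

`%||%` <- rlang::`%||%`

# Small default-shaped generator config that keeps tests fast.
small_config <- function(seed = 1L, ...) {
  generator_config(
    seed = seed, n_genes = 400L, n_planted_repressed = 12L,
    n_mirnas = 10L, target_set_size = 40L, n_enriched_mirnas = 3L,
    n_gene_sets = 6L, set_size_range = c(10L, 25L), ...
  )
}

# Naive rank-by-rank ssGSEA oracle, written independently of the
# implementation: explicit loop accumulating the running difference.
naive_ssgsea <- function(sample, gene_set, tau) {
  ids <- names(sample)
  ord <- order(-sample, ids)
  ids <- ids[ord]
  vals <- sample[ord]
  in_set <- ids %in% gene_set
  n <- length(vals)
  n_in <- sum(in_set)
  denom_in <- 0
  for (i in seq_len(n)) if (in_set[i]) denom_in <- denom_in + abs(vals[i])^tau
  es <- 0
  acc_in <- 0
  acc_out <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      acc_in <- acc_in + abs(vals[i])^tau / denom_in
    } else {
      acc_out <- acc_out + 1 / (n - n_in)
    }
    es <- es + (acc_in - acc_out)
  }
  unname(es)
}
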