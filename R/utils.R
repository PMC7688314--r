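# Internal helpers shared across modules.

# Deterministic top-k selection: rank by value descending, ties broken by
# lexicographic identifier so repeated runs agree across platforms.
top_k_lex <- function(values, ids, k) {
  stopifnot(length(values) == length(ids))
  if (k <= 0L) return(character(0))
  ord <- order(-values, ids)
  ids[ord[seq_len(min(k, length(ids)))]]
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Numeric matrix of the replicate columns of a genes-x-replicates tibble.
value_matrix <- function(mat, design) {
  reps <- design$replicate_id
  m <- as.matrix(mat[, reps, drop = FALSE])
  rownames(m) <- mat$gene
  storage.mode(m) <- "double"
  m
}

ceiling_frac <- function(frac, n) as.integer(ceiling(frac * n))
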