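#' Single-sample gene-set enrichment score
#'
#' Rank-weighted running-sum enrichment score of one gene set in one
#' sample. Genes are ranked by sample value descending (ties broken by
#' lexicographic gene id); walking down the ranking, the in-set empirical
#' CDF weighted by `|value|^tau` is accumulated against the uniform
#' out-of-set CDF, and the score is the sum of their differences over all
#' ranks:
#' \deqn{ES = \sum_{i=1}^{N} [P_{in}(i) - P_{out}(i)]}
#' with \eqn{P_{in}(i) = \sum_{g \in S, rank(g) \le i} |x_g|^\tau /
#' \sum_{g \in S} |x_g|^\tau} and \eqn{P_{out}(i) = |\{g \notin S :
#' rank(g) \le i\}| / (N - |S|)}. At `tau = 0` the score depends on ranks
#' only and is invariant to any strictly monotone transform of the sample.
#'
#' @param sample Named numeric vector (gene -> value, e.g. log2 normalized
#'   intensity).
#' @param gene_set Character vector of set member ids; members absent from
#'   the sample universe are ignored.
#' @param tau Rank weighting exponent (default 0.25).
#' @return The enrichment score (single number).
#' @examples
#' x <- setNames(c(5, 4, 3, 2, 1), letters[1:5])
#' ssgsea_score(x, c("a", "b"), tau = 0)
#' @export
ssgsea_score <- function(sample, gene_set, tau = 0.25) {
  ids <- names(sample)
  if (is.null(ids)) abort("sample must be a named vector")
  in_set <- ids %in% gene_set
  n <- length(sample)
  n_in <- sum(in_set)
  if (n_in == 0L) abort("gene set has no member in the sample universe")
  if (n_in == n) abort("gene set covers the whole universe; P_out is undefined")
  ord <- order(-sample, ids)
  w <- abs(sample[ord])^tau
  m <- in_set[ord]
  p_in <- cumsum(w * m) / sum(w * m)
  p_out <- cumsum(!m) / (n - n_in)
  sum(p_in - p_out)
}

#' Enrichment scores for a collection across all replicates
#'
#' Applies [ssgsea_score()] to every (gene set, replicate) pair of a
#' log2-offset-transformed normalized matrix. When `normalize = TRUE` all
#' scores are divided by the global score range (max - min), the
#' conventional ssGSEA normalization.
#'
#' @param mat A normalized [replicate_matrix()].
#' @param collection Gene-set tibble ([read_gmt()] /[filter_sets()]).
#' @param tau Rank weighting exponent (default 0.25).
#' @param offset Log2 offset added before transforming (default 1e-4).
#' @param normalize Divide by the global score range (default `TRUE`).
#' @return An object of class `enrichment_scores`: list with `scores`
#'   (tibble `set` x replicate columns), `design`, `tau`, `normalized`.
#' @export
score_matrix <- function(mat, collection, tau = 0.25, offset = 1e-4,
                         normalize = TRUE) {
  design <- matrix_design(mat)
  vm <- log2_offset(value_matrix(as_tibble(mat), design), offset)
  genes <- rownames(vm)
  scores <- matrix(
    NA_real_, nrow(collection), ncol(vm),
    dimnames = list(collection$set, colnames(vm))
  )
  for (r in seq_len(ncol(vm))) {
    x <- setNames(vm[, r], genes)
    ord <- order(-x, genes)
    xo <- x[ord]
    ido <- genes[ord]
    w <- abs(xo)^tau
    for (s in seq_len(nrow(collection))) {
      m <- ido %in% collection$genes[[s]]
      n_in <- sum(m)
      if (n_in == 0L || n_in == length(m)) {
        abort(sprintf(
          "set '%s' has no usable member split in the universe", collection$set[s]
        ))
      }
      p_in <- cumsum(w * m) / sum(w * m)
      p_out <- cumsum(!m) / (length(m) - n_in)
      scores[s, r] <- sum(p_in - p_out)
    }
  }
  normalized <- FALSE
  rng <- diff(range(scores))
  if (normalize) {
    if (rng > 0) {
      scores <- scores / rng
      normalized <- TRUE
    } else {
      warn("all enrichment scores are equal; range normalization skipped")
    }
  }
  structure(
    list(
      scores = bind_cols(tibble(set = rownames(scores)), as_tibble(scores)),
      design = design, tau = tau, normalized = normalized
    ),
    class = "enrichment_scores"
  )
}

#' Filter gene sets by size and detected fraction
#'
#' Retains sets with at least `min_size` members and at least
#' `min_detected_frac` of their members present in the detection universe
#' (genes detected in the proteome). Sizes count the full set; members
#' missing from the measured universe still count toward the size but are
#' ignored during scoring.
#'
#' @param collection Gene-set tibble ([read_gmt()]).
#' @param universe Character vector of detected gene ids.
#' @param min_size Minimum set size (default 30, inclusive).
#' @param min_detected_frac Minimum detected fraction (default 0.5,
#'   inclusive).
#' @return The filtered collection with `detected_frac` added.
#' @export
filter_sets <- function(collection, universe, min_size = 30L,
                        min_detected_frac = 0.5) {
  collection |>
    mutate(detected_frac = purrr::map_dbl(
      .data$genes,
      function(g) if (length(g) == 0L) 0 else mean(g %in% universe)
    )) |>
    filter(.data$n_genes >= min_size, .data$detected_frac >= min_detected_frac)
}

#' Kruskal-Wallis rank test of scores across cell types
#'
#' Tie-corrected H statistic with the chi-squared approximation on k - 1
#' degrees of freedom. Identical values in all groups give H = 0, p = 1.
#'
#' @param values Numeric vector of scores.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return A one-row tibble with `H`, `df`, `p_value`.
#' @examples
#' kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3)) # H = 7.2
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) abort("need at least 2 groups")
  if (any(tabulate(groups) == 0L)) abort("every group must be non-empty")
  if (length(unique(values)) == 1L) {
    return(tibble(H = 0, df = nlevels(groups) - 1L, p_value = 1))
  }
  kt <- kruskal.test(values, groups)
  tibble(
    H = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value
  )
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up adjusted p values capped at 1, plus flags at the stated FDR.
#'
#' @param p_values Raw p values in `[0, 1]`.
#' @param fdr False discovery rate for flagging (default 0.05).
#' @return A tibble with `p_value`, `p_adjusted`, `significant`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all adjusted to 0.04
#' @export
bh_adjust <- function(p_values, fdr = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p values must be in [0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble(p_value = p_values, p_adjusted = adj, significant = adj <= fdr)
}

#' Test every gene set for differences across cell types
#'
#' Runs the Kruskal-Wallis test per set on the replicate scores grouped by
#' cell type and applies Benjamini-Hochberg control across sets. No
#' post-hoc pairwise tests are performed; the interest is in global
#' differences and rankings between cell types.
#'
#' @param score_obj `enrichment_scores` from [score_matrix()].
#' @param fdr FDR for flagging (default 0.05).
#' @return A tibble with `set`, `H`, `df`, `p_value`, `p_adjusted`,
#'   `significant`, ordered by `p_value`.
#' @export
enrichment_test <- function(score_obj, fdr = 0.05) {
  stopifnot(inherits(score_obj, "enrichment_scores"))
  design <- score_obj$design
  groups <- if (dplyr::n_distinct(design$age) > 1L) {
    paste(design$cell_type, design$age, sep = ".")
  } else {
    design$cell_type
  }
  sm <- score_obj$scores
  res <- purrr::map(seq_len(nrow(sm)), function(i) {
    vals <- as.numeric(unlist(sm[i, design$replicate_id]))
    kruskal_wallis(vals, groups)
  }) |>
    bind_rows() |>
    mutate(set = sm$set, .before = 1L)
  bind_cols(
    res,
    bh_adjust(res$p_value, fdr = fdr) |> select(-"p_value")
  ) |>
    arrange(.data$p_value)
}

#' Per-cell-type mean enrichment scores
#'
#' Bar-chart-ready table of replicate-averaged scores per cell type.
#'
#' @param score_obj `enrichment_scores` from [score_matrix()].
#' @return A tibble `set`, `cell_type`, `mean_score`.
#' @export
mean_scores <- function(score_obj) {
  stopifnot(inherits(score_obj, "enrichment_scores"))
  design <- score_obj$design
  label <- if (dplyr::n_distinct(design$age) > 1L) {
    paste(design$cell_type, design$age, sep = ".")
  } else {
    design$cell_type
  }
  score_obj$scores |>
    tidyr::pivot_longer(-"set", names_to = "replicate_id", values_to = "score") |>
    left_join(
      tibble(replicate_id = design$replicate_id, cell_type = label),
      by = "replicate_id"
    ) |>
    group_by(.data$set, .data$cell_type) |>
    summarise(mean_score = mean(.data$score), .groups = "drop")
}
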