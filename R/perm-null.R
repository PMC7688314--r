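#' Reshuffling null distribution for unique mRNA-only counts
#'
#' Builds the empirical null for the number of genes that are mRNA-only in
#' exactly one cell type. Per iteration, each cell type's labels are
#' reassigned independently: every gene eligible in that cell type (i.e.
#' observed as `mRNA_only` or `both` there) is drawn `mRNA_only` with the
#' cell type's observed proportion (independent Bernoulli per gene per
#' cell type). A gene counts as null-unique for a cell type when it is
#' assigned `mRNA_only` there and in no other cell type. The observed
#' count compared against this null uses the same uniqueness rule (no
#' replicate filter), so observed and null share one code path; the
#' replicate-filtered list is the separate high-confidence gene list from
#' [classify_transcriptome()].
#'
#' @param categories Long category tibble from [classify_transcriptome()]
#'   (columns `gene`, `cell_type`, `category`).
#' @param n_iterations Number of reshuffles (default 1000).
#' @param seed Root seed; the run is fully reproducible from it.
#' @param fixed_count Use a fixed-count permutation (exactly the observed
#'   number of `mRNA_only` labels per cell type) instead of Bernoulli
#'   draws (default `FALSE`).
#' @return An object of class `null_distribution`: list with `counts`
#'   (n_iterations x cell-type matrix of null-unique counts), `observed`
#'   (named observed unique counts), `proportions`, `n_genes`,
#'   `n_iterations`, `seed`.
#' @examples
#' cats <- tibble::tibble(
#'   gene = rep(sprintf("g%02d", 1:20), 2),
#'   cell_type = rep(c("HSC", "MPPa"), each = 20),
#'   category = c(rep(c("mRNA_only", "both"), 10), rep("both", 20))
#' )
#' nd <- run_null(cats, n_iterations = 50, seed = 1)
#' tidy(nd)
#' @export
run_null <- function(categories, n_iterations = 1000L, seed = 1L,
                     fixed_count = FALSE) {
  assert_columns(categories, c("gene", "cell_type", "category"), "categories")
  cts <- unique(categories$cell_type)
  if (length(cts) < 2L) abort("need at least 2 cell types")
  genes <- unique(categories$gene)
  n <- length(genes)

  # gene x cell type logical matrices of eligibility and observed labels
  eligible <- matrix(FALSE, n, length(cts), dimnames = list(genes, cts))
  observed_m <- eligible
  idx <- cbind(match(categories$gene, genes), match(categories$cell_type, cts))
  eligible[idx] <- categories$category %in% c("mRNA_only", "both")
  observed_m[idx] <- categories$category == "mRNA_only"

  n_elig <- colSums(eligible)
  n_monly <- colSums(observed_m)
  props <- ifelse(n_elig > 0L, n_monly / n_elig, 0)
  names(props) <- cts
  degenerate <- cts[props %in% c(0, 1) & n_elig > 0L]
  if (length(degenerate) > 0L) {
    inform(sprintf(
      "cell type(s) with degenerate mRNA-only proportion (0 or 1): %s",
      paste(degenerate, collapse = ", ")
    ))
  }

  observed <- unique_counts(observed_m)

  set.seed(as.integer(seed))
  counts <- matrix(0L, n_iterations, length(cts), dimnames = list(NULL, cts))
  # Vectorized over iterations in blocks to bound memory.
  block <- max(1L, min(n_iterations, as.integer(2e7 / max(n, 1L))))
  done <- 0L
  while (done < n_iterations) {
    b <- min(block, n_iterations - done)
    draws <- vector("list", length(cts))
    for (j in seq_along(cts)) {
      if (fixed_count) {
        m <- matrix(FALSE, n, b)
        elig_idx <- which(eligible[, j])
        for (it in seq_len(b)) {
          m[sample(elig_idx, n_monly[j]), it] <- TRUE
        }
        draws[[j]] <- m
      } else {
        draws[[j]] <- matrix(runif(n * b) < props[j], n, b) & eligible[, j]
      }
    }
    for (j in seq_along(cts)) {
      other <- Reduce(`|`, draws[-j])
      counts[done + seq_len(b), j] <- colSums(draws[[j]] & !other)
    }
    done <- done + b
  }

  structure(
    list(
      counts = counts, observed = observed, proportions = props,
      n_genes = n, n_iterations = n_iterations, seed = as.integer(seed),
      fixed_count = fixed_count
    ),
    class = "null_distribution"
  )
}

# Unique counts for a gene x cell type logical matrix of mRNA-only labels.
unique_counts <- function(m) {
  u <- rowSums(m) == 1L
  setNames(colSums(m & u), colnames(m))
}

#' Empirical confidence interval of a null sample
#'
#' Percentile interval with linear interpolation (the default quantile
#' definition): for level 0.95, the 2.5th and 97.5th empirical percentiles.
#'
#' @param distribution A `null_distribution`, or a numeric sample.
#' @param level Coverage level in (0, 1), default 0.95.
#' @return For a numeric sample, `c(lower, upper)`; for a
#'   `null_distribution`, a tibble with `cell_type`, `lower`, `upper`.
#' @examples
#' empirical_ci(1:1000) # approximately (25.975, 975.025)
#' @export
empirical_ci <- function(distribution, level = 0.95) {
  stopifnot(level > 0, level < 1)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (inherits(distribution, "null_distribution")) {
    qs <- apply(distribution$counts, 2L, quantile, probs = probs, names = FALSE)
    return(tibble(
      cell_type = colnames(distribution$counts),
      lower = qs[1L, ], upper = qs[2L, ]
    ))
  }
  if (length(distribution) == 0L) abort("empty sample")
  setNames(quantile(distribution, probs = probs, names = FALSE), c("lower", "upper"))
}

#' Verdict of an observed count against a null interval
#'
#' @param observed Observed count.
#' @param ci Two-element interval `c(lower, upper)`.
#' @return `"above"` if observed > upper, `"below"` if observed < lower,
#'   `"within"` otherwise.
#' @examples
#' verdict(10, c(2, 8)) # "above"
#' @export
verdict <- function(observed, ci) {
  stopifnot(length(ci) == 2L, ci[1L] <= ci[2L])
  dplyr::case_when(
    observed > ci[2L] ~ "above",
    observed < ci[1L] ~ "below",
    TRUE ~ "within"
  )
}

#' Observed counts, null intervals and verdicts per cell type
#'
#' Convenience wrapper running [run_null()], [empirical_ci()] and
#' [verdict()] in one call.
#'
#' @inheritParams run_null
#' @param level Confidence level (default 0.95).
#' @return A tibble with `cell_type`, `observed`, `null_mean`, `lower`,
#'   `upper`, `verdict`.
#' @export
null_verdicts <- function(categories, n_iterations = 1000L, seed = 1L,
                          level = 0.95, fixed_count = FALSE) {
  nd <- run_null(categories, n_iterations = n_iterations, seed = seed,
                 fixed_count = fixed_count)
  ci <- empirical_ci(nd, level = level)
  tibble(
    cell_type = ci$cell_type,
    observed = as.numeric(nd$observed[ci$cell_type]),
    null_mean = colMeans(nd$counts)[ci$cell_type],
    lower = ci$lower, upper = ci$upper
  ) |>
    mutate(verdict = purrr::map2_chr(
      .data$observed, seq_along(.data$observed),
      function(obs, i) verdict(obs, c(ci$lower[i], ci$upper[i]))
    ))
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %d iterations, %d genes, %d cell types (seed %d)\n",
    x$n_iterations, x$n_genes, ncol(x$counts), x$seed
  ))
  print(tidy(x))
  invisible(x)
}
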