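make_profiles <- function(n = 60, seed = 21) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n))
  cts <- c("HSC", "MPPa", "MPPb", "MPPc")
  prot <- tibble::tibble(gene = genes)
  mrna <- tibble::tibble(gene = genes)
  for (ct in cts) {
    prot[[ct]] <- runif(n, 1, 100)
    mrna[[ct]] <- runif(n, 1, 100)
  }
  list(prot = prot, mrna = mrna)
}

test_that("Spearman correlation is monotone-invariant and guarded", {
  p <- make_profiles()
  # perfectly monotone pair
  prot <- tibble::tibble(gene = p$prot$gene, HSC = seq_len(60))
  mrna <- tibble::tibble(gene = p$prot$gene, HSC = exp(seq_len(60) / 10))
  expect_equal(spearman_protein_mrna(prot, mrna, "HSC")$rho, 1)
  mrna$HSC <- rev(mrna$HSC)
  expect_equal(spearman_protein_mrna(prot, mrna, "HSC")$rho, -1)

  # invariance to the offset/log choice (strictly monotone transforms)
  r1 <- spearman_protein_mrna(p$prot, p$mrna, "MPPa")$rho
  p2 <- p
  p2$prot$MPPa <- log2(p2$prot$MPPa + 1e-4)
  p2$mrna$MPPa <- log2(p2$mrna$MPPa + 1e-5)
  expect_equal(spearman_protein_mrna(p2$prot, p2$mrna, "MPPa")$rho, r1)

  few <- tibble::tibble(gene = c("a", "b"), HSC = c(1, 2))
  expect_error(spearman_protein_mrna(few, few, "HSC"), "fewer than 3")
})

test_that("fold-change table restricts to doubly-detected genes", {
  p <- make_profiles(n = 50)
  p$prot$HSC[1] <- 0   # undetected in one layer, one cell type
  p$mrna$MPPb[2] <- 0
  fc <- fold_change_table(p$prot, p$mrna)
  expect_false(any(c("g001", "g002") %in% fc$gene))
  expect_equal(nrow(fc), 48)
  expect_true(all(is.finite(as.matrix(fc[, -1]))))

  # elementwise log-ratio oracle
  keep <- match(fc$gene, p$prot$gene)
  for (ct in c("HSC", "MPPa", "MPPb", "MPPc")) {
    expect_equal(fc[[ct]], log2(p$prot[[ct]][keep] / p$mrna[[ct]][keep]),
                 tolerance = 1e-12)
  }

  simple_p <- tibble::tibble(gene = "x", HSC = 8)
  simple_m <- tibble::tibble(gene = "x", HSC = 2)
  expect_equal(fold_change_table(simple_p, simple_m)$HSC, 2)
})

test_that("between-cell-type Pearson grid matches the textbook formula", {
  p <- make_profiles(n = 40, seed = 22)
  fc <- fold_change_table(p$prot, p$mrna)
  grid <- attr(pearson_between_celltypes(fc), "grid")
  expect_equal(grid, t(grid))
  expect_equal(unname(diag(grid)), rep(1, 4))
  pearson_oracle <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(grid["HSC", "MPPb"], pearson_oracle(fc$HSC, fc$MPPb),
               tolerance = 1e-12)

  dup <- tibble::tibble(gene = fc$gene, A = fc$HSC, B = fc$HSC, C = -fc$HSC)
  g2 <- attr(pearson_between_celltypes(dup), "grid")
  expect_equal(g2["A", "B"], 1)
  expect_equal(g2["A", "C"], -1)

  flat <- tibble::tibble(gene = fc$gene, A = fc$HSC, B = rep(1, nrow(fc)))
  g3 <- attr(suppressWarnings(pearson_between_celltypes(flat)), "grid")
  expect_true(is.na(g3["A", "B"]))
})

test_that("decoupling selector recovers exactly the planted genes", {
  set.seed(23)
  n <- 400
  genes <- sprintf("g%03d", seq_len(n))
  fc <- tibble::tibble(
    gene = genes,
    HSC = rnorm(n, 0, 0.5),
    MPPa = rnorm(n, 0, 0.5),
    MPPb = rnorm(n, 0, 0.5),
    MPPc = rnorm(n, 0, 0.5)
  )
  planted <- sample(genes, 8)
  rows <- fc$gene %in% planted
  for (ct in c("MPPa", "MPPb", "MPPc")) fc[[ct]][rows] <- fc[[ct]][rows] + 4
  res <- decoupled_genes(fc)
  expect_setequal(res$gene, planted)

  # full-sort oracle per comparator
  k <- ceiling(0.025 * n)
  oracle <- Reduce(intersect, lapply(c("MPPa", "MPPb", "MPPc"), function(ct) {
    delta <- fc[[ct]] - fc$HSC
    fc$gene[order(-delta, fc$gene)][seq_len(k)]
  }))
  expect_setequal(res$gene, oracle)

  # invariance to adding a constant to all fold changes of a gene
  fc2 <- fc
  shift <- rnorm(n)
  for (ct in c("HSC", "MPPa", "MPPb", "MPPc")) fc2[[ct]] <- fc2[[ct]] + shift
  expect_equal(decoupled_genes(fc2)$gene, res$gene)

  # degenerate comparator: flagged, deterministic size
  fc3 <- fc[, c("gene", "HSC")]
  fc3$MPPa <- fc3$HSC
  expect_warning(res3 <- decoupled_genes(fc3, comparators = "MPPa"), "constant")
  expect_equal(nrow(res3), k)
  expect_equal(attr(res3, "degenerate"), "MPPa")
})

test_that("transcriptome classifier matches exhaustive rule evaluation", {
  set.seed(24)
  n <- 30
  genes <- sprintf("g%02d", seq_len(n))
  cts <- c("HSC", "MPPa", "MPPb", "MPPc")
  prot <- tibble::tibble(gene = genes)
  mrna <- tibble::tibble(gene = genes)
  counts <- tibble::tibble(gene = genes)
  for (ct in cts) {
    counts[[ct]] <- sample(0:6, n, replace = TRUE)
    prot[[ct]] <- ifelse(counts[[ct]] > 0, runif(n, 1, 10), 0)
    mrna[[ct]] <- rbinom(n, 1, 0.8) * runif(n, 1, 10)
  }
  cats <- classify_transcriptome(prot, mrna, counts, comparison_set = cts)

  # brute force over all genes and cell types
  for (i in seq_len(n)) {
    for (ct in cts) {
      expected_cat <- if (mrna[[ct]][i] > 0 && prot[[ct]][i] > 0) {
        "both"
      } else if (mrna[[ct]][i] > 0) {
        "mRNA_only"
      } else {
        "absent"
      }
      row <- cats[cats$gene == genes[i] & cats$cell_type == ct, ]
      expect_equal(row$category, expected_cat)
      m_only_elsewhere <- vapply(setdiff(cts, ct), function(o) {
        mrna[[o]][i] > 0 && prot[[o]][i] == 0
      }, logical(1))
      strong <- any(vapply(setdiff(cts, ct), function(o) {
        counts[[o]][i] >= 3
      }, logical(1)))
      expect_equal(
        row$unique_mrna_only,
        expected_cat == "mRNA_only" && !any(m_only_elsewhere) && strong
      )
    }
  }

  # invariant: unique flag implies mRNA_only in exactly one cell type
  flagged <- cats[cats$unique_mrna_only, ]
  for (g in unique(flagged$gene)) {
    sub <- cats[cats$gene == g, ]
    expect_equal(sum(sub$category == "mRNA_only"), 1L)
  }
})

test_that("the paper motif gene is flagged unique in the repressed cell type", {
  cts <- c("HSC", "MPPa", "MPPb", "MPPc")
  prot <- tibble::tibble(gene = "gX", HSC = 0, MPPa = 5, MPPb = 4, MPPc = 6)
  mrna <- tibble::tibble(gene = "gX", HSC = 3, MPPa = 3, MPPb = 3, MPPc = 3)
  counts <- tibble::tibble(gene = "gX", HSC = 0L, MPPa = 4L, MPPb = 3L, MPPc = 5L)
  cats <- classify_transcriptome(prot, mrna, counts, comparison_set = cts)
  expect_true(cats$unique_mrna_only[cats$cell_type == "HSC"])
  expect_equal(sum(cats$unique_mrna_only), 1L)

  # everywhere-both gene: no flag anywhere
  prot$HSC <- 2
  counts$HSC <- 3L
  cats <- classify_transcriptome(prot, mrna, counts, comparison_set = cts)
  expect_true(all(cats$category == "both"))
  expect_false(any(cats$unique_mrna_only))
})

test_that("PCA embedding conserves variance and separates planted clusters", {
  set.seed(25)
  base <- matrix(rexp(200 * 12, 1 / 50), 200, 12)
  base[1:50, 1:4] <- base[1:50, 1:4] * 20 # composition shift in the HSC replicates
  m <- toy_matrix(base, c("HSC", "MPPa", "MPPb"), 4)
  m <- normalize_replicates(m)
  emb <- pca_embed(m)

  # explained variances sum to the total variance of the log2 input
  vm <- log2(as.matrix(tibble::as_tibble(m)[, -1]) + emb$offset)
  total_var <- sum(apply(t(vm), 2, stats::var))
  expect_equal(sum(emb$variance), total_var, tolerance = 1e-8)

  # PC1 separates the planted cluster: positive silhouette on PC1
  pc1 <- emb$scores$PC1
  is_hsc <- emb$scores$cell_type == "HSC"
  gap <- abs(mean(pc1[is_hsc]) - mean(pc1[!is_hsc]))
  spread <- stats::sd(pc1[is_hsc]) + stats::sd(pc1[!is_hsc])
  expect_gt(gap, spread)

  # duplicate replicates land on identical coordinates
  dup <- toy_matrix(cbind(base[, 1], base[, 1], base[, 2]), "HSC", 3)
  emb2 <- pca_embed(normalize_replicates(dup))
  expect_equal(emb2$scores$PC1[1], emb2$scores$PC1[2], tolerance = 1e-8)

  # deterministic sign: the largest-magnitude loading is positive
  for (j in c("PC1", "PC2")) {
    l <- emb$loadings[[j]]
    expect_gte(l[which.max(abs(l))], 0)
  }
})
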