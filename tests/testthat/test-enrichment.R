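test_that("ssGSEA matches the naive rank-by-rank oracle", {
  # tau = 0, set occupying the top ranks: value fixed by the oracle
  x <- setNames(10:1, letters[1:10])
  s <- letters[1:3]
  expect_equal(ssgsea_score(x, s, tau = 0), naive_ssgsea(x, s, tau = 0))

  set.seed(51)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    genes <- sprintf("g%03d", seq_len(n))
    x <- setNames(rnorm(n, 0, 3), genes)
    s <- sample(genes, sample(5:20, 1))
    tau <- sample(c(0, 0.25, 1), 1)
    expect_equal(ssgsea_score(x, s, tau), naive_ssgsea(x, s, tau),
                 tolerance = 1e-10)
  }
})

test_that("ssGSEA symmetry, rank invariance and CDF conservation hold", {
  x <- setNames(c(9, 7, 5, 3, 1, -1), sprintf("g%d", 1:6))
  s <- c("g1", "g2", "g3")
  # at tau = 0 the complement at the bottom mirrors the set at the top
  expect_equal(ssgsea_score(x, s, tau = 0),
               -ssgsea_score(x, setdiff(names(x), s), tau = 0))

  # tau = 0 depends on ranks only: monotone transform leaves it unchanged
  set.seed(52)
  y <- setNames(runif(40, 1, 9), sprintf("g%02d", 1:40))
  s2 <- sample(names(y), 8)
  expect_equal(ssgsea_score(y, s2, tau = 0),
               ssgsea_score(exp(y / 3), s2, tau = 0))

  # both running CDFs reach exactly 1 at the last rank
  ids <- names(y)
  ord <- order(-y, ids)
  m <- ids[ord] %in% s2
  w <- abs(y[ord])^0.25
  expect_equal(sum(w * m) / sum(w * m), 1)
  expect_equal(max(cumsum(!m) / sum(!m)), 1)

  expect_error(ssgsea_score(y, names(y)), "whole universe")
  expect_error(ssgsea_score(y, "absent-gene"), "no member")
})

test_that("score matrices respect replicate structure and normalization", {
  set.seed(53)
  vals <- matrix(rexp(120 * 8, 1 / 40), 120, 8)
  genes <- sprintf("g%03d", 1:120)
  shifted_set <- genes[1:20]
  vals[1:20, 7:8] <- vals[1:20, 7:8] * 16 # up-shift in the last cell type
  m <- normalize_replicates(
    toy_matrix(vals, c("HSC", "MPPa", "MPPb", "MPPc"), 2, genes = genes)
  )
  coll <- tibble::tibble(
    set = c("shifted", "background"),
    n_genes = c(20L, 30L),
    genes = list(shifted_set, genes[50:79]),
    empty = FALSE
  )
  sc <- score_matrix(m, coll)
  expect_equal(dim(sc$scores), c(2L, 9L))
  ms <- mean_scores(sc)
  shifted_means <- ms[ms$set == "shifted", ]
  expect_equal(
    shifted_means$cell_type[which.max(shifted_means$mean_score)], "MPPc"
  )

  # single set, single replicate reduces to ssgsea_score
  one <- normalize_replicates(toy_matrix(vals[, 1, drop = FALSE], "HSC", 1,
                                         genes = genes))
  sc1 <- score_matrix(one, coll[1, ], normalize = FALSE)
  x <- setNames(
    log2_offset(tibble::as_tibble(one)$HSC_young_r1, 1e-4), genes
  )
  expect_equal(sc1$scores$HSC_young_r1, ssgsea_score(x, shifted_set))

  # duplicated replicate columns give duplicated scores
  dupvals <- cbind(vals[, 1], vals[, 1])
  dup <- normalize_replicates(toy_matrix(dupvals, "HSC", 2, genes = genes))
  scd <- score_matrix(dup, coll, normalize = FALSE)
  expect_equal(scd$scores$HSC_young_r1, scd$scores$HSC_young_r2)

  # global range normalization maps max - min to exactly 1
  rng <- range(as.matrix(sc$scores[, -1]))
  expect_equal(diff(rng), 1)
  expect_true(sc$normalized)
})

test_that("set filtering applies inclusive size and detection thresholds", {
  universe <- sprintf("g%03d", 1:50)
  coll <- tibble::tibble(
    set = c("small", "half", "low"),
    n_genes = c(29L, 30L, 40L),
    genes = list(
      sprintf("g%03d", 1:29),
      c(sprintf("g%03d", 1:15), sprintf("x%03d", 1:15)),
      c(sprintf("g%03d", 1:10), sprintf("x%03d", 1:30))
    ),
    empty = FALSE
  )
  kept <- filter_sets(coll, universe)
  expect_equal(kept$set, "half") # 29-gene set dropped; exactly-half kept
  expect_equal(kept$detected_frac, 0.5)

  fixture <- tibble::tibble(
    set = sprintf("s%02d", 1:10),
    n_genes = seq(26L, 44L, by = 2L),
    genes = lapply(seq(26, 44, by = 2), function(k) {
      c(sprintf("g%03d", seq_len(floor(k * 0.6))),
        sprintf("x%03d", seq_len(k - floor(k * 0.6))))
    }),
    empty = FALSE
  )
  kept <- filter_sets(fixture, universe)
  manual <- fixture$set[fixture$n_genes >= 30 &
                          vapply(fixture$genes,
                                 function(g) mean(g %in% universe),
                                 numeric(1)) >= 0.5]
  expect_equal(kept$set, manual)
})

test_that("Kruskal-Wallis reproduces the textbook H and guards ties", {
  res <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(res$H, 7.2, tolerance = 1e-12)
  expect_equal(res$df, 2)

  flat <- kruskal_wallis(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(flat$H, 0)
  expect_equal(flat$p_value, 1)

  # type-I error of the chi-squared approximation near nominal level
  set.seed(54)
  rejections <- mean(replicate(2000, {
    kruskal_wallis(rnorm(15), rep(c("a", "b", "c"), each = 5))$p_value < 0.05
  }))
  expect_gt(rejections, 0.03)
  expect_lt(rejections, 0.07)
})

test_that("BH adjustment is step-up with flags and dominance", {
  res <- bh_adjust(0.01)
  expect_equal(res$p_adjusted, 0.01)

  res <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(res$p_adjusted, rep(0.04, 4))
  expect_true(all(res$significant))

  set.seed(55)
  p <- runif(50)
  res <- bh_adjust(p)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$p_adjusted <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH keeps the null false-flag fraction at or below the FDR", {
  set.seed(56)
  flagged <- replicate(400, {
    scores <- matrix(rnorm(20 * 9), 20, 9)
    p <- apply(scores, 1, function(v) {
      kruskal_wallis(v, rep(c("a", "b", "c"), each = 3))$p_value
    })
    mean(bh_adjust(p)$significant)
  })
  expect_lte(mean(flagged), 0.05 + 3 * stats::sd(flagged) / sqrt(length(flagged)))
})

test_that("enrichment testing ties scores, tests and adjustment together", {
  set.seed(57)
  vals <- matrix(rexp(100 * 9, 1 / 30), 100, 9)
  genes <- sprintf("g%03d", 1:100)
  vals[1:15, 7:9] <- vals[1:15, 7:9] * 32
  m <- normalize_replicates(
    toy_matrix(vals, c("HSC", "MPPa", "MPPb"), 3, genes = genes)
  )
  coll <- tibble::tibble(
    set = c("planted", "noise"),
    n_genes = c(15L, 20L),
    genes = list(genes[1:15], genes[60:79]),
    empty = FALSE
  )
  res <- enrichment_test(score_matrix(m, coll))
  expect_equal(res$set[1], "planted")
  expect_lt(res$p_value[1], res$p_value[2])
  expect_true(all(res$p_adjusted >= res$p_value))
})
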