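test_that("generation is deterministic in the seed", {
  b1 <- generate(small_config(seed = 7))
  b2 <- generate(small_config(seed = 7))
  expect_identical(
    as.data.frame(tibble::as_tibble(b1$proteome)),
    as.data.frame(tibble::as_tibble(b2$proteome))
  )
  expect_identical(b1$truth, b2$truth)
  b3 <- generate(small_config(seed = 8))
  expect_false(identical(
    as.data.frame(tibble::as_tibble(b1$proteome)),
    as.data.frame(tibble::as_tibble(b3$proteome))
  ))
})

test_that("planted genes satisfy the unique-mRNA-only preconditions", {
  b <- generate(small_config(seed = 9))
  cfg <- b$config
  planted <- b$truth$planted_repressed
  expect_length(planted, cfg$n_planted_repressed)
  dc <- detection_counts(b$proteome)
  rows <- match(planted, dc$gene)
  # protein forced to zero in the repressed cell type
  expect_true(all(dc[[cfg$repressed_cell_type]][rows] == 0L))
  # >= 3 detected replicates in every other cell type
  for (ct in setdiff(cfg$cell_types, cfg$repressed_cell_type)) {
    expect_true(all(dc[[ct]][rows] >= 3L))
  }
  # mRNA drawn like everything else: overwhelmingly detected
  mrna_prof <- aggregate_profile(b$transcriptome, "mean")
  expect_gt(mean(mrna_prof[[cfg$repressed_cell_type]][
    match(planted, mrna_prof$gene)
  ] > 0), 0.95)
})

test_that("per-replicate detection rates track the configured probabilities", {
  cfg <- generator_config(seed = 10, n_genes = 2000L)
  b <- generate(cfg)
  vm <- as.matrix(tibble::as_tibble(b$proteome)[, -1])
  design <- b$design
  unplanted <- !(b$proteome$gene %in% b$truth$planted_repressed)
  for (ct in cfg$cell_types) {
    cols <- design$replicate_id[design$cell_type == ct]
    p_hat <- mean(vm[unplanted, cols] > 0)
    p <- cfg$detection_prob[[ct]]
    n_draws <- sum(unplanted) * length(cols)
    se <- sqrt(p * (1 - p) / n_draws)
    expect_lt(abs(p_hat - p), 3 * se)
  }
})

test_that("degenerate full-detection configs give zero-free matrices", {
  cfg <- generator_config(
    seed = 11, n_genes = 100L, n_planted_repressed = 0L,
    detection_prob = c(HSC = 1, MPPa = 1, MPPb = 1, MPPc = 1),
    mrna_detection_prob = 1,
    n_mirnas = 4L, target_set_size = 20L, n_enriched_mirnas = 0L,
    n_gene_sets = 3L, set_size_range = c(10L, 20L)
  )
  b <- generate(cfg)
  expect_true(all(as.matrix(tibble::as_tibble(b$proteome)[, -1]) > 0))
  expect_length(b$truth$planted_repressed, 0)
  # no protein absences -> no mRNA-only genes anywhere
  cats <- classify_transcriptome(
    aggregate_profile(b$proteome, "nonzero_mean"),
    aggregate_profile(b$transcriptome, "mean"),
    detection_counts(b$proteome)
  )
  expect_false(any(cats$category == "mRNA_only"))
})

test_that("enriched miRNAs oversample planted genes", {
  b <- generate(generator_config(seed = 12, n_genes = 2000L))
  planted <- b$truth$planted_repressed
  tm <- b$target_map
  enriched <- tm$mirna %in% b$truth$enriched_mirnas
  frac_enriched <- mean(unlist(purrr::map(
    tm$targets[enriched], ~ mean(.x %in% planted)
  )))
  frac_background <- mean(unlist(purrr::map(
    tm$targets[!enriched], ~ mean(.x %in% planted)
  )))
  expect_gt(frac_enriched, 2 * frac_background)
})

test_that("infeasible configurations fail before sampling", {
  expect_error(generator_config(n_genes = 100L, n_planted_repressed = 200L),
               "exceed")
  expect_error(generator_config(n_genes = 50L, target_set_size = 100L),
               "exceed")
  expect_error(generator_config(detection_prob = c(HSC = 1.2, MPPa = 0.5,
                                                   MPPb = 0.5, MPPc = 0.5)),
               "\\[0, 1\\]")
  expect_error(generator_config(rescue_fraction = 1.5), "rescue_fraction")
  expect_error(generator_config(repressed_cell_type = "XXX"), "cell_types")
})

test_that("bundles round-trip through the plain-text readers", {
  b <- generate(small_config(seed = 13))
  dir <- withr::local_tempdir()
  manifest <- write_bundle(b, dir, force = TRUE)
  prot_back <- read_matrix(file.path(dir, "proteome.tsv"), b$design)
  expect_identical(
    as.matrix(tibble::as_tibble(prot_back)[, -1]),
    as.matrix(tibble::as_tibble(b$proteome)[, -1])
  )
  tm_back <- read_target_map(file.path(dir, "mirna_targets.tsv"))
  expect_equal(tm_back$mirna, b$target_map$mirna)
  expect_equal(
    purrr::map(tm_back$targets, sort),
    purrr::map(b$target_map$targets, sort)
  )
  gs_back <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_equal(gs_back$set, b$gene_sets$set)
  expect_equal(gs_back$genes, b$gene_sets$genes)

  # refusing to clobber a non-empty directory without force
  expect_error(write_bundle(b, dir), "not empty")

  # manifest hash is sensitive to any config change and stable otherwise
  b2 <- generate(small_config(seed = 13, rescue_fraction = 0.8))
  dir2 <- withr::local_tempdir()
  manifest2 <- write_bundle(b2, dir2, force = TRUE)
  expect_false(identical(manifest$config_hash, manifest2$config_hash))
  dir3 <- withr::local_tempdir()
  manifest3 <- write_bundle(generate(small_config(seed = 13)), dir3, force = TRUE)
  expect_identical(manifest$config_hash, manifest3$config_hash)
})

test_that("old-HSC rescue assignments are Bernoulli per planted gene", {
  b <- generate(generator_config(seed = 14, n_genes = 1000L,
                                 n_planted_repressed = 200L))
  planted <- b$truth$planted_repressed
  old_dc <- detection_counts(b$old_proteome)
  detected <- old_dc$gene[old_dc$HSC >= 1L]
  # truth bookkeeping matches the matrix
  expect_identical(
    unname(b$truth$rescue_assignments[planted]),
    planted %in% detected
  )
})
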