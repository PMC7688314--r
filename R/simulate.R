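#' Configuration for the synthetic data generator
#'
#' The generator emulates the statistical structure the downstream
#' analysis assumes: zero-inflated log-normal replicate intensities with
#' per-cell-type detection probabilities (lowest protein diversity in the
#' repressed cell type), a matched transcriptome, a planted set of genes
#' with mRNA present but protein absent in exactly one cell type, a miRNA
#' target map enriched for the planted set, gene sets (some up-shifted in
#' one cell type), and an old-HSC proteome that re-detects planted genes
#' with a configurable rescue fraction.
#'
#' Default per-replicate protein detection probabilities are parameterized
#' through the probability that a background gene escapes detection in all
#' replicates of a cell type: 0.55 for HSC and 0.50 for each MPP
#' (`detection_prob = 1 - miss^(1/n_reps)`), reflecting the lowest
#' proteome diversity of the stem-cell compartment with roughly half the
#' transcriptome universe lacking protein evidence.
#'
#' @param seed Root seed; every draw derives from it.
#' @param n_genes Number of genes (default 5000).
#' @param cell_types Cell types (default HSC, MPPa, MPPb, MPPc).
#' @param n_replicates Proteome replicates per cell type (default 6).
#' @param n_mrna_replicates Transcriptome replicates per cell type
#'   (default 4).
#' @param detection_prob Named per-replicate protein detection
#'   probabilities, one per cell type.
#' @param mrna_detection_prob Per-replicate mRNA detection probability
#'   (default 0.9).
#' @param intensity_logmean,intensity_logsd Natural-log mean / sd of the
#'   log-normal intensity draw (defaults 8 and 2, giving a realistic
#'   dynamic range in arbitrary units).
#' @param n_planted_repressed Planted post-transcriptionally repressed
#'   genes (default 120).
#' @param repressed_cell_type Cell type carrying the planted repression
#'   (default `"HSC"`).
#' @param n_mirnas,target_set_size miRNA target map shape (default 60 x 100).
#' @param target_enrichment Sampling weight of planted genes in enriched
#'   miRNAs' target sets relative to background (default 4).
#' @param n_enriched_mirnas miRNAs whose target sets are enriched for the
#'   planted genes (default 10).
#' @param n_gene_sets,set_size_range Gene-set collection shape (default 25
#'   sets of 30-80 genes).
#' @param n_shifted_sets,shifted_set_effect Sets whose member intensities
#'   are multiplied by `2^effect` in `shifted_cell_type` (default 2 sets,
#'   +2 log2 units).
#' @param shifted_cell_type Cell type receiving the shift (default
#'   `"MPPc"`).
#' @param rescue_fraction Probability a planted gene is re-detected in the
#'   old-HSC proteome (default 0.9).
#' @return A validated config list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_genes = 5000L,
                             cell_types = c("HSC", "MPPa", "MPPb", "MPPc"),
                             n_replicates = 6L,
                             n_mrna_replicates = 4L,
                             detection_prob = NULL,
                             mrna_detection_prob = 0.9,
                             intensity_logmean = 8,
                             intensity_logsd = 2,
                             n_planted_repressed = 120L,
                             repressed_cell_type = "HSC",
                             n_mirnas = 60L,
                             target_set_size = 100L,
                             target_enrichment = 4,
                             n_enriched_mirnas = 10L,
                             n_gene_sets = 25L,
                             set_size_range = c(30L, 80L),
                             n_shifted_sets = 2L,
                             shifted_set_effect = 2,
                             shifted_cell_type = "MPPc",
                             rescue_fraction = 0.9) {
  if (is.null(detection_prob)) {
    miss <- setNames(rep(0.5, length(cell_types)), cell_types)
    miss[repressed_cell_type] <- 0.55
    detection_prob <- 1 - miss^(1 / n_replicates)
  }
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    cell_types = cell_types, n_replicates = as.integer(n_replicates),
    n_mrna_replicates = as.integer(n_mrna_replicates),
    detection_prob = detection_prob,
    mrna_detection_prob = mrna_detection_prob,
    intensity_logmean = intensity_logmean, intensity_logsd = intensity_logsd,
    n_planted_repressed = as.integer(n_planted_repressed),
    repressed_cell_type = repressed_cell_type,
    n_mirnas = as.integer(n_mirnas),
    target_set_size = as.integer(target_set_size),
    target_enrichment = target_enrichment,
    n_enriched_mirnas = as.integer(n_enriched_mirnas),
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    n_shifted_sets = as.integer(n_shifted_sets),
    shifted_set_effect = shifted_set_effect,
    shifted_cell_type = shifted_cell_type,
    rescue_fraction = rescue_fraction
  )
  validate_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!all(detection_prob >= 0 & detection_prob <= 1)) {
      abort("detection probabilities must be in [0, 1]")
    }
    if (mrna_detection_prob < 0 || mrna_detection_prob > 1) {
      abort("mrna_detection_prob must be in [0, 1]")
    }
    if (rescue_fraction < 0 || rescue_fraction > 1) {
      abort("rescue_fraction must be in [0, 1]")
    }
    if (n_planted_repressed > n_genes) {
      abort("n_planted_repressed cannot exceed n_genes")
    }
    if (!repressed_cell_type %in% cell_types) {
      abort("repressed_cell_type must be one of cell_types")
    }
    if (!setequal(names(detection_prob), cell_types)) {
      abort("detection_prob must be named by cell_types")
    }
    if (target_set_size > n_genes) {
      abort("target_set_size cannot exceed n_genes")
    }
    if (n_enriched_mirnas > n_mirnas) {
      abort("n_enriched_mirnas cannot exceed n_mirnas")
    }
    if (target_enrichment < 1) abort("target_enrichment must be >= 1")
    if (n_genes < 1 || n_replicates < 1 || n_mrna_replicates < 1) {
      abort("all counts must be positive")
    }
    if (set_size_range[1L] > set_size_range[2L] || set_size_range[2L] > n_genes) {
      abort("set_size_range must be increasing and within n_genes")
    }
    if (n_shifted_sets > n_gene_sets) abort("n_shifted_sets cannot exceed n_gene_sets")
  })
  invisible(cfg)
}

#' Generate a complete synthetic input bundle
#'
#' Draws a proteome, a transcriptome, an old-HSC proteome, a miRNA target
#' map, a gene-set collection and the ground truth, all reproducible from
#' `config$seed`. Zeroing is per replicate (not per gene per cell type) so
#' detection-count thresholds are meaningfully exercised. Planted
#' repressed genes have their protein forced to zero in all replicates of
#' the repressed cell type, forced to at least 3 detected replicates in
#' every other cell type, and their mRNA drawn from the same distribution
#' as unplanted genes. Enriched miRNAs include planted genes at
#' `target_enrichment` times the background sampling weight. The old-HSC
#' matrix re-detects each planted gene with probability `rescue_fraction`
#' (and forces the rest absent); its background genes use MPP-level
#' detection, matching the higher protein diversity of aged stem cells.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_bundle`: `proteome`,
#'   `transcriptome`, `old_proteome` (each a [replicate_matrix()]),
#'   `target_map`, `gene_sets`, `design`, `mrna_design`, `old_design`,
#'   `truth` (list: `planted_repressed`, `enriched_mirnas`,
#'   `shifted_gene_sets`, `rescue_assignments`), and `config`.
#' @examples
#' b <- generate(generator_config(n_genes = 50, n_planted_repressed = 3,
#'                                set_size_range = c(5L, 10L),
#'                                target_set_size = 10L, n_mirnas = 5L,
#'                                n_enriched_mirnas = 2L, n_gene_sets = 4L))
#' b$truth$planted_repressed
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  planted <- if (cfg$n_planted_repressed > 0L) {
    sort(sample(genes, cfg$n_planted_repressed))
  } else {
    character(0)
  }
  is_planted <- genes %in% planted

  design <- study_design(cfg$cell_types, cfg$n_replicates, age = "young")
  mrna_design <- study_design(cfg$cell_types, cfg$n_mrna_replicates, age = "young")
  old_design <- study_design(cfg$repressed_cell_type, cfg$n_replicates, age = "old")

  draw_block <- function(n_genes, n_reps, p_detect) {
    vals <- matrix(
      exp(rnorm(n_genes * n_reps, cfg$intensity_logmean, cfg$intensity_logsd)),
      n_genes, n_reps
    )
    vals * (matrix(runif(n_genes * n_reps), n_genes, n_reps) < p_detect)
  }
  force_detected <- function(block, rows, min_reps = 3L) {
    # guarantee >= min_reps strictly positive replicates for the given rows
    for (i in rows) {
      det <- which(block[i, ] > 0)
      need <- min_reps - length(det)
      if (need > 0L) {
        fill <- sample(setdiff(seq_len(ncol(block)), det), need)
        block[i, fill] <- exp(rnorm(need, cfg$intensity_logmean, cfg$intensity_logsd))
      }
    }
    block
  }

  # --- proteome ---
  prot <- tibble(gene = genes)
  shifted_sets <- character(0)
  for (ct in cfg$cell_types) {
    block <- draw_block(cfg$n_genes, cfg$n_replicates, cfg$detection_prob[[ct]])
    if (ct == cfg$repressed_cell_type) {
      block[is_planted, ] <- 0
    } else {
      block <- force_detected(block, which(is_planted))
    }
    cols <- design$replicate_id[design$cell_type == ct]
    colnames(block) <- cols
    for (cc in cols) prot[[cc]] <- block[, cc]
  }

  # --- transcriptome (planted genes drawn like everything else) ---
  mrna <- tibble(gene = genes)
  for (ct in cfg$cell_types) {
    block <- draw_block(cfg$n_genes, cfg$n_mrna_replicates, cfg$mrna_detection_prob)
    cols <- mrna_design$replicate_id[mrna_design$cell_type == ct]
    colnames(block) <- cols
    for (cc in cols) mrna[[cc]] <- block[, cc]
  }

  # --- gene sets, with some sets up-shifted in one cell type ---
  set_names <- sprintf("SET_%03d", seq_len(cfg$n_gene_sets))
  sizes <- sample(seq(cfg$set_size_range[1L], cfg$set_size_range[2L]),
                  cfg$n_gene_sets, replace = TRUE)
  members <- lapply(sizes, function(k) sort(sample(genes, k)))
  gene_sets <- tibble(
    set = set_names, n_genes = lengths(members), genes = members,
    empty = FALSE
  )
  if (cfg$n_shifted_sets > 0L) {
    shifted_sets <- set_names[seq_len(cfg$n_shifted_sets)]
    shift_cols <- design$replicate_id[design$cell_type == cfg$shifted_cell_type]
    shift_genes <- unique(unlist(members[seq_len(cfg$n_shifted_sets)]))
    rows <- prot$gene %in% shift_genes
    for (cc in shift_cols) {
      prot[[cc]][rows] <- prot[[cc]][rows] * 2^cfg$shifted_set_effect
    }
  }

  # --- miRNA target map, enriched for the planted set ---
  enriched <- sprintf("mmu-miR-%03d", seq_len(cfg$n_enriched_mirnas))
  others <- if (cfg$n_mirnas > cfg$n_enriched_mirnas) {
    sprintf("mmu-miR-%03d", seq(cfg$n_enriched_mirnas + 1L, cfg$n_mirnas))
  } else {
    character(0)
  }
  weights_bg <- rep(1, cfg$n_genes)
  weights_en <- ifelse(is_planted, cfg$target_enrichment, 1)
  draw_targets <- function(w) sort(sample(genes, cfg$target_set_size, prob = w))
  target_map <- tibble(
    mirna = c(enriched, others),
    targets = c(
      lapply(enriched, function(m) draw_targets(weights_en)),
      lapply(others, function(m) draw_targets(weights_bg))
    )
  ) |>
    mutate(n_targets = lengths(.data$targets), empty = FALSE) |>
    arrange(.data$mirna) |>
    select("mirna", "n_targets", "targets", "empty")

  # --- old-HSC proteome with binomial rescue of the planted genes ---
  old_p <- cfg$detection_prob
  old_p_hsc <- max(old_p[setdiff(cfg$cell_types, cfg$repressed_cell_type)],
                   old_p[[cfg$repressed_cell_type]])
  old_block <- draw_block(cfg$n_genes, cfg$n_replicates, old_p_hsc)
  rescued <- setNames(rep(NA, cfg$n_genes), genes)
  if (length(planted) > 0L) {
    rescue_draw <- runif(length(planted)) < cfg$rescue_fraction
    rescued_genes <- planted[rescue_draw]
    lost_genes <- planted[!rescue_draw]
    old_block[genes %in% lost_genes, ] <- 0
    old_block <- force_detected(old_block, which(genes %in% rescued_genes))
    rescued[planted] <- rescue_draw
  }
  colnames(old_block) <- old_design$replicate_id
  old_prot <- bind_cols(tibble(gene = genes), as_tibble(old_block))

  structure(
    list(
      proteome = replicate_matrix(prot, design, "proteome"),
      transcriptome = replicate_matrix(mrna, mrna_design, "transcriptome"),
      old_proteome = replicate_matrix(old_prot, old_design, "proteome"),
      target_map = target_map,
      gene_sets = gene_sets,
      design = design, mrna_design = mrna_design, old_design = old_design,
      truth = list(
        planted_repressed = planted,
        enriched_mirnas = enriched,
        shifted_gene_sets = shifted_sets,
        rescue_assignments = rescued[planted]
      ),
      config = cfg
    ),
    class = "synthetic_bundle"
  )
}

#' Write a synthetic bundle to disk
#'
#' Writes all bundle components in the package's plain-text interchange
#' formats and a JSON manifest recording paths, the seed and a hash of the
#' full configuration (so any config change changes the manifest).
#'
#' @param bundle A bundle from [generate()].
#' @param directory Output directory.
#' @param force Overwrite a non-empty directory (default `FALSE`).
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
write_bundle <- function(bundle, directory, force = FALSE) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (dir.exists(directory) && length(dir(directory)) > 0L && !force) {
    abort(sprintf("directory '%s' is not empty; use force = TRUE", directory))
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    proteome = file.path(directory, "proteome.tsv"),
    transcriptome = file.path(directory, "transcriptome.tsv"),
    old_proteome = file.path(directory, "old_hsc_proteome.tsv"),
    target_map = file.path(directory, "mirna_targets.tsv"),
    gene_sets = file.path(directory, "gene_sets.gmt"),
    design = file.path(directory, "design.tsv"),
    mrna_design = file.path(directory, "mrna_design.tsv"),
    old_design = file.path(directory, "old_design.tsv"),
    truth = file.path(directory, "truth.json")
  )
  write_matrix(bundle$proteome, paths$proteome)
  write_matrix(bundle$transcriptome, paths$transcriptome)
  write_matrix(bundle$old_proteome, paths$old_proteome)
  write_target_map(bundle$target_map, paths$target_map)
  write_gmt(bundle$gene_sets, paths$gene_sets)
  readr::write_tsv(bundle$design, paths$design, progress = FALSE)
  readr::write_tsv(bundle$mrna_design, paths$mrna_design, progress = FALSE)
  readr::write_tsv(bundle$old_design, paths$old_design, progress = FALSE)
  jsonlite::write_json(
    bundle$truth, paths$truth,
    auto_unbox = TRUE, pretty = TRUE, na = "null"
  )
  manifest <- list(
    seed = bundle$config$seed,
    config_hash = rlang::hash(unclass(bundle$config)),
    files = lapply(paths, normalizePath)
  )
  jsonlite::write_json(
    manifest, file.path(directory, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
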