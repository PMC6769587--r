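test_that("the component backbone respects the configuration", {
  cfg <- generator_config(
    n_genes_per_class = c(eukaryote = 40, bacteria = 40),
    fusion_prob = c(eukaryote = 0, bacteria = 0),
    n_families = 10, rng_seed = 8
  )
  comp <- generate_components(cfg)
  expect_equal(nrow(comp$genes), 80)
  expect_false(any(comp$genes$is_composite))
  # members carry their family archetype length
  len_by_fam <- setNames(comp$families$archetype_length,
                         comp$families$family_id)
  expect_equal(comp$genes$length,
               unname(len_by_fam[comp$genes$family_id]))
  # determinism under a fixed seed
  comp2 <- generate_components(cfg)
  expect_identical(comp$genes, comp2$genes)
})

test_that("with no composites every family is isolated from the others", {
  cfg <- generator_config(
    n_genes_per_class = c(bacteria = 60),
    fusion_prob = c(bacteria = 0),
    n_families = 12, rng_seed = 3
  )
  sim <- simulate_gene_set(cfg)
  expect_true(all(sim$truth$true_class == "non_remodelled"))
  ssn <- build_ssn(sim$genes, filter_hits(sim$hits))
  fam <- assign_families(ssn)
  truth_fam <- sim$genes$family_id
  # recovered families refine to exactly the generated ones
  tab <- table(fam$family_id, truth_fam)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(length(unique(fam$family_id)),
               length(unique(truth_fam)))
})

test_that("composite construction tiles genes with detectable segments", {
  cfg <- small_config(seed = 13)
  sim <- generate_composites(generate_components(cfg))
  prov <- sim$provenance
  expect_true(all(prov$seg_len >= cfg$segment_min))
  by_comp <- split(prov, prov$composite)
  for (p in by_comp) {
    p <- p[order(p$segment_index), ]
    # segments tile the composite without overlap
    expect_equal(p$comp_start[1], 1)
    expect_equal(p$comp_start[-1], p$comp_end[-nrow(p)] + 1)
    len <- sim$genes$length[sim$genes$gene_id == p$composite[1]]
    expect_equal(p$comp_end[nrow(p)], len)
    # two distinct sources
    expect_equal(length(unique(p$source_id)), 2)
  }
})

test_that("truth classes follow the generated fusion structure", {
  cfg <- small_config(seed = 4)
  sim <- simulate_gene_set(cfg)
  truth <- sim$truth
  genes <- sim$genes
  # every generated composite is a composite in truth
  comp_truth <- truth$true_class[match(genes$gene_id[genes$is_composite],
                                       truth$gene_id)]
  expect_true(all(comp_truth %in% c("nested_composite",
                                    "strict_composite")))
  # a parent reused in a nested fusion is a nested composite
  parents <- sim$provenance$source_id[
    sim$provenance$source_type == "composite"]
  if (length(parents) > 0) {
    expect_true(all(
      truth$true_class[match(unique(parents), truth$gene_id)] ==
        "nested_composite"))
  }
  # with nesting disabled no nested composites exist in truth
  cfg0 <- small_config(seed = 4, nested_fraction = 0)
  sim0 <- generate_composites(generate_components(cfg0))
  expect_equal(sum(sim0$truth$true_class == "nested_composite"), 0)
})

test_that("zero-noise detection recovers the truth perfectly", {
  # the flagship property, checked across seeds and configurations
  configs <- list(
    small_config(seed = 1),
    small_config(seed = 42, nested_fraction = 0.5),
    generator_config(
      n_genes_per_class = c(eukaryote = 120, virus = 60, plasmid = 60),
      fusion_prob = c(eukaryote = 0.3, virus = 0.05, plasmid = 0.15),
      n_families = 30, rng_seed = 77
    )
  )
  for (cfg in configs) {
    sim <- simulate_gene_set(cfg)
    rec <- score_recovery(classify_sim(sim), sim$truth)
    expect_equal(rec$precision, 1.0)
    expect_equal(rec$recall, 1.0)
    # the whole 4x4 confusion matrix is diagonal
    expect_equal(sum(rec$confusion) - sum(diag(rec$confusion)), 0)
  }
})

test_that("generation is deterministic under a fixed seed", {
  s1 <- simulate_gene_set(small_config(seed = 9))
  s2 <- simulate_gene_set(small_config(seed = 9))
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$annotations, s2$annotations)
  s3 <- simulate_gene_set(small_config(seed = 10))
  expect_false(identical(s1$hits, s3$hits))
})

test_that("dropout lowers recall and spurious edges lower precision", {
  noisy_scores <- function(seed, dropout = 0, spurious = 0) {
    sim <- simulate_gene_set(small_config(
      seed = seed, dropout_rate = dropout,
      spurious_edge_rate = spurious))
    score_recovery(classify_sim(sim), sim$truth)
  }
  seeds <- 101:110
  rec_clean <- vapply(seeds, function(s) noisy_scores(s)$recall, 1)
  rec_drop <- vapply(seeds, function(s) noisy_scores(s, dropout = 0.4)$recall, 1)
  expect_lt(mean(rec_drop), mean(rec_clean))

  prec_clean <- vapply(seeds, function(s) noisy_scores(s)$precision, 1)
  prec_sp <- vapply(seeds,
                    function(s) noisy_scores(s, spurious = 1.5)$precision,
                    1)
  expect_lt(mean(prec_sp), mean(prec_clean))
})

test_that("per-class composite rates match the configured probabilities", {
  cfg <- generator_config(
    n_genes_per_class = c(eukaryote = 600, bacteria = 600),
    fusion_prob = c(eukaryote = 0.25, bacteria = 0.10),
    n_families = 120, rng_seed = 55
  )
  sim <- simulate_gene_set(cfg)
  cen <- census(classify_sim(sim), sim_metadata(sim), "domain_class")
  for (cl in c("eukaryote", "bacteria")) {
    p <- cfg$fusion_prob[[cl]]
    n <- cfg$n_genes_per_class[[cl]]
    got <- cen$n_composite[cen$group == cl] / cen$total_genes[cen$group == cl]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(got - p), 3 * se)
  }
})

test_that("recovery scores match an independent scorer", {
  sim <- simulate_gene_set(small_config(seed = 17, dropout_rate = 0.3))
  pred <- classify_sim(sim)
  rec <- score_recovery(pred, sim$truth)
  # independent scorer: plain logical arithmetic on the merged table
  m <- merge(as.data.frame(pred), as.data.frame(sim$truth),
             by = "gene_id")
  comp <- c("nested_composite", "strict_composite")
  tp <- sum(m$gene_class %in% comp & m$true_class %in% comp)
  fp <- sum(m$gene_class %in% comp & !(m$true_class %in% comp))
  fn <- sum(!(m$gene_class %in% comp) & m$true_class %in% comp)
  expect_equal(rec$precision, tp / (tp + fp))
  expect_equal(rec$recall, tp / (tp + fn))
  expect_error(score_recovery(pred[-1, ], sim$truth), "differ")
})

test_that("written synthetic datasets re-load identically through the readers", {
  sim <- simulate_gene_set(small_config(seed = 23))
  dir <- withr::local_tempdir()
  files <- write_synthetic_dataset(sim, dir)
  hits <- read_blast_tab(files[["hits"]])
  expect_equal(nrow(hits), nrow(sim$hits))
  expect_equal(hits$evalue, sim$hits$evalue)
  md <- read_metadata(files[["metadata"]])
  expect_identical(md, sim_metadata(sim))
  ann <- read_annotations(files[["annotations"]],
                          cog_column = "COG_category",
                          gene_column = "query")
  expect_identical(as.data.frame(ann), as.data.frame(sim$annotations))
})

test_that("FASTA emission writes sequences whose lengths match the genes", {
  skip_if_not_installed("Biostrings")
  cfg <- generator_config(
    n_genes_per_class = c(bacteria = 30, eukaryote = 30),
    fusion_prob = c(bacteria = 0.2, eukaryote = 0.3),
    n_families = 10, rng_seed = 12
  )
  sim <- simulate_gene_set(cfg)
  dir <- withr::local_tempdir()
  files <- write_synthetic_dataset(sim, dir, fasta = TRUE)
  lens <- Biostrings::fasta.seqlengths(files[["fasta"]])
  expect_equal(unname(lens[sim$genes$gene_id]), sim$genes$length)
})
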