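test_that("multi-letter categories expand to one count per letter", {
  ann <- tibble::tibble(gene_id = c("g1", "g2"),
                        cog_letters = c("ABC", "A"))
  inc <- expand_categories(ann)
  expect_equal(sum(inc$gene_id == "g1"), 3)
  expect_setequal(inc$category[inc$gene_id == "g1"], c("A", "B", "C"))
  expect_equal(sum(inc$category == "A"), 2)
  # unannotated genes contribute nowhere
  expect_false("g3" %in% inc$gene_id)
})

test_that("contingency cells follow the quadrant definitions", {
  ids <- c(paste0("e", 1:5), paste0("p", 1:5), "v1")
  cls <- classify_genes(ids,
                        composites = c("e1", "e2", "p1"),
                        components = character(0))
  md <- tibble::tibble(
    gene_id = ids, genome_id = "G",
    domain_class = c(rep("eukaryote", 5), rep("bacteria", 3),
                     rep("archaea", 2), "virus")
  )
  inc <- expand_categories(tibble::tibble(gene_id = ids,
                                          cog_letters = "J"))
  tab <- build_contingency("J", cls, md, inc)
  expect_equal(unname(unlist(tab[c("a", "b", "c", "d")])), c(2, 3, 1, 4))
  # the virus gene was excluded from every cell
  expect_equal(tab$a + tab$b + tab$c + tab$d, 10L)
  # absent category: all-zero table
  tab0 <- build_contingency("Z", cls, md, inc)
  expect_equal(unname(unlist(tab0[c("a", "b", "c", "d")])), rep(0L, 4))
})

test_that("odds ratio arithmetic and zero-cell skipping", {
  expect_equal(odds_ratio(1, 1, 1, 1), 1)
  expect_equal(odds_ratio(20, 80, 10, 90), 2.25)
  expect_true(is.na(odds_ratio(0, 80, 10, 90)))
})

test_that("Woolf interval matches an independent textbook computation", {
  a <- 20; b <- 80; c <- 10; d <- 90; z <- 3.09
  ci <- or_confidence_interval(a, b, c, d, z)
  # independent recomputation, written out term by term
  lor <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  expect_equal(ci$ci_low, exp(lor - z * se))
  expect_equal(ci$ci_high, exp(lor + z * se))
  # this table is non-significant at the corrected quantile: CI spans 1
  expect_lt(ci$ci_low, 1)
  expect_gt(ci$ci_high, 1)

  # symmetric about 1 on the log scale for the unit table
  ci1 <- or_confidence_interval(1, 1, 1, 1, 1.96)
  expect_equal(ci1$ci_low, 1 / ci1$ci_high)

  # tenfold counts give a strictly narrower interval
  ci_big <- or_confidence_interval(200, 800, 100, 900, 1.96)
  ci_small <- or_confidence_interval(20, 80, 10, 90, 1.96)
  expect_lt(ci_big$ci_high / ci_big$ci_low,
            ci_small$ci_high / ci_small$ci_low)
})

test_that("odds-ratio identities hold over random positive tables", {
  withr::with_seed(99, {
    for (i in 1:50) {
      t <- sample(1:500, 4, replace = TRUE)
      a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
      # reciprocity: swapping the two rows inverts the OR
      expect_equal(odds_ratio(a, b, c, d) * odds_ratio(c, d, a, b), 1)
      # invariance under scaling one row
      k <- sample(2:9, 1)
      expect_equal(odds_ratio(k * a, k * b, c, d),
                   odds_ratio(a, b, c, d))
      # strict CI ordering around the point estimate
      z <- runif(1, 0.5, 4)
      ci <- or_confidence_interval(a, b, c, d, z)
      or <- odds_ratio(a, b, c, d)
      expect_lt(ci$ci_low, or)
      expect_gt(ci$ci_high, or)
    }
  })
})

test_that("the corrected quantile follows the normal-table convention", {
  corr <- bonferroni_z(0.05, 24)
  expect_equal(corr$alpha_corrected, 0.05 / 48)
  expect_equal(round(corr$z, 2), 3.09)

  corr1 <- bonferroni_z(0.05, 1)
  expect_equal(corr1$alpha_corrected, 0.025)
  expect_equal(round(corr1$z, 2), 1.96)

  # the exact convention keeps the unrounded level
  expect_equal(bonferroni_z(0.05, 24, convention = "exact")$z,
               qnorm(1 - 0.05 / 48))

  expect_error(bonferroni_z(0.05, 0), "n_tests")
})

test_that("run_enrichment reports every category, skipping zero cells", {
  sim <- simulate_gene_set(small_config(seed = 3))
  cls <- classify_sim(sim)
  enr <- run_enrichment(cls, sim_metadata(sim), sim$annotations)
  res <- tidy(enr)
  expect_setequal(res$category,
                  sort(unique(unlist(strsplit(sim$annotations$cog_letters,
                                              "")))))
  expect_identical(res$category, sort(res$category))
  expect_true(all(is.na(res$or[res$skipped])))
  expect_true(all(res$skip_reason[res$skipped] == "zero_cell"))
  ok <- !res$skipped
  expect_true(all(res$ci_low[ok] < res$or[ok] &
                    res$or[ok] < res$ci_high[ok]))
  expect_identical(res$significant,
                   !res$skipped & (res$ci_low > 1 | res$ci_high < 1))
  # N defaults to the number of tests actually performed
  expect_equal(enr$n_tests, sum(ok))
})

test_that("an engineered zero cell is emitted as skipped", {
  ids <- c("e1", "e2", "p1", "p2")
  cls <- classify_genes(ids, composites = "e1", components = character(0))
  md <- tibble::tibble(gene_id = ids, genome_id = "G",
                       domain_class = c("eukaryote", "eukaryote",
                                        "bacteria", "bacteria"))
  ann <- tibble::tibble(gene_id = ids, cog_letters = "Y")
  enr <- run_enrichment(cls, md, ann)
  res <- tidy(enr)
  expect_true(res$skipped[res$category == "Y"])
  expect_true(is.na(res$or[res$category == "Y"]))
})

test_that("enrichment with no annotated overlap is an error", {
  cls <- classify_genes(c("a", "b"), character(0), character(0))
  md <- tibble::tibble(gene_id = c("a", "b"), genome_id = "G",
                       domain_class = "eukaryote")
  ann <- tibble::tibble(gene_id = "zz", cog_letters = "J")
  expect_error(run_enrichment(cls, md, ann), "no annotated genes")
})

test_that("an eukaryote-enriched regime yields mostly OR > 1 calls", {
  cfg <- generator_config(
    n_genes_per_class = c(eukaryote = 700, bacteria = 350, archaea = 350),
    fusion_prob = c(eukaryote = 0.35, bacteria = 0.08, archaea = 0.08),
    n_families = 80, rng_seed = 11
  )
  sim <- simulate_gene_set(cfg)
  cls <- classify_sim(sim)
  enr <- run_enrichment(cls, sim_metadata(sim), sim$annotations)
  res <- tidy(enr)
  ok <- !res$skipped
  expect_gt(mean(res$or[ok] > 1), 0.9)
  # pooled over all functions the enrichment is unambiguous
  pooled <- run_enrichment(
    cls, sim_metadata(sim),
    tibble::tibble(gene_id = cls$gene_id, cog_letters = "J"),
    n_tests = 1)
  expect_true(tidy(pooled)$significant)
  expect_gt(tidy(pooled)$or, 1)
})
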