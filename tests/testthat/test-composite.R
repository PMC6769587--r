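test_that("interval overlap uses inclusive 1-based arithmetic", {
  expect_equal(interval_overlap(c(1, 100), c(90, 150)), 11)
  expect_equal(interval_overlap(c(1, 50), c(60, 100)), 0)
  expect_equal(interval_overlap(c(10, 20), c(10, 20)), 11)
})

test_that("the six-gene fusion toy is detected and classified correctly", {
  ssn <- fig2_ssn()
  det <- detect_composites(ssn)
  expect_equal(det$composites, c("A", "D"))
  expect_setequal(det$components, c("A", "B", "C", "E"))

  trip_a <- find_triplets(ssn, "A")
  expect_equal(nrow(trip_a), 1)
  expect_equal(trip_a$component_a, "B")
  expect_equal(trip_a$component_b, "C")
  expect_equal(trip_a$overlap, 0)

  cls <- classify_genes(ssn$nodes$gene_id, det$composites, det$components)
  got <- setNames(as.character(cls$gene_class), cls$gene_id)
  expect_equal(got[["A"]], "nested_composite")
  expect_equal(got[["D"]], "strict_composite")
  expect_equal(got[["B"]], "strict_component")
  expect_equal(got[["C"]], "strict_component")
  expect_equal(got[["E"]], "strict_component")
  expect_equal(got[["F"]], "non_remodelled")
})

test_that("a triangle is transitive and certifies nothing", {
  genes <- tibble::tibble(gene_id = c("a", "b", "c"), length = 100)
  hits <- dplyr::bind_rows(
    hit_row("a", "b", 1, 40, 1, 40),
    hit_row("b", "c", 60, 100, 1, 41),
    hit_row("a", "c", 1, 40, 60, 99)
  )
  det <- detect_composites(build_ssn(genes, hits))
  expect_equal(length(det$composites), 0)
})

test_that("component footprints overlapping beyond the tolerance are rejected", {
  genes <- tibble::tibble(gene_id = c("g", "x", "y"),
                          length = c(200, 110, 90))
  make_det <- function(y_start) {
    hits <- dplyr::bind_rows(
      hit_row("g", "x", 1, 100, 1, 100),
      hit_row("g", "y", y_start, y_start + 80, 1, 81)
    )
    detect_composites(build_ssn(genes, hits))
  }
  # overlap 21 > 20: no composite
  expect_equal(length(make_det(80)$composites), 0)
  # overlap exactly 20 is tolerated
  expect_equal(make_det(81)$composites, "g")
})

test_that("find_triplets errors for genes outside the network", {
  expect_error(find_triplets(fig2_ssn(), "nope"), "not in the network")
})

test_that("detection matches the brute-force oracle on random networks", {
  for (seed in 1:12) {
    ssn <- random_ssn(seed, n_genes = 50, n_hits = 160)
    det <- detect_composites(ssn)
    oracle <- brute_force_detect(ssn)
    expect_identical(det$composites, oracle$composites)
    expect_identical(det$components, oracle$components)
    expect_identical(nrow(det$triplets), oracle$n_triplets)
  }
})

test_that("stored witnesses re-verify against the network", {
  for (seed in c(2, 8, 21)) {
    ssn <- random_ssn(seed)
    det <- detect_composites(ssn)
    expect_true(verify_triplets(ssn, det$triplets))
  }
  # a corrupted witness is caught
  ssn <- fig2_ssn()
  det <- detect_composites(ssn)
  bad <- det$triplets
  bad$component_b[1] <- "F"
  expect_error(verify_triplets(ssn, bad), "failed re-verification")
})

test_that("the four classes partition the gene set", {
  for (seed in c(4, 16)) {
    ssn <- random_ssn(seed)
    det <- detect_composites(ssn)
    cls <- classify_genes(ssn$nodes$gene_id, det$composites,
                          det$components)
    expect_equal(nrow(cls), nrow(ssn$nodes))
    counts <- table(cls$gene_class)
    expect_equal(sum(counts), nrow(ssn$nodes))
    expect_equal(counts[["nested_composite"]] +
                   counts[["strict_composite"]],
                 length(det$composites))
  }
  # empty sets: everything non-remodelled
  cls0 <- classify_genes(c("a", "b"), character(0), character(0))
  expect_true(all(cls0$gene_class == "non_remodelled"))
  # membership in both sets means nested
  cls1 <- classify_genes("a", "a", "a")
  expect_equal(as.character(cls1$gene_class), "nested_composite")
})

test_that("raising the allowed overlap never shrinks the composite set", {
  for (seed in c(6, 13)) {
    ssn <- random_ssn(seed)
    prev <- character(0)
    for (mo in c(0, 10, 20, 50, 150)) {
      det <- detect_composites(
        ssn, detection_params(max_component_overlap = mo))
      expect_true(all(prev %in% det$composites))
      prev <- det$composites
    }
  }
})

test_that("classification output is byte-identical across reruns", {
  sim <- simulate_gene_set(small_config(seed = 5))
  write_once <- function() {
    cls <- classify_sim(sim)
    md <- sim_metadata(sim)
    det <- detect_composites(build_ssn(sim$genes, filter_hits(sim$hits)))
    rep <- classification_report(cls, md, det$triplets)
    f <- tempfile(fileext = ".tsv")
    readr::write_tsv(rep, f, progress = FALSE)
    on.exit(unlink(f))
    readr::read_file(f)
  }
  expect_identical(write_once(), write_once())
})

test_that("census arithmetic reproduces printed-style proportions", {
  # grouping and rounding on a toy classification
  cls <- classify_genes(c("e1", "e2", "e3", "p1", "p2"),
                        composites = c("e1", "p1"),
                        components = c("e2", "p2"))
  md <- tibble::tibble(
    gene_id = c("e1", "e2", "e3", "p1", "p2"),
    genome_id = c("G1", "G1", "G1", "G2", "G2"),
    domain_class = c("eukaryote", "eukaryote", "eukaryote",
                     "bacteria", "bacteria")
  )
  cen <- census(cls, md, "genome_id")
  g1 <- cen[cen$group == "G1", ]
  expect_equal(g1$total_genes, 3)
  expect_equal(g1$n_composite, 1)
  expect_equal(g1$proportion_composite, 33.33)
  # zero-composite group
  cls2 <- classify_genes(c("a", "b"), character(0), character(0))
  md2 <- tibble::tibble(gene_id = c("a", "b"), genome_id = "G",
                        domain_class = "virus")
  expect_equal(census(cls2, md2)$proportion_composite, 0)
  # genes lacking metadata surface as an 'unassigned' row with a warning
  expect_warning(cen3 <- census(cls, md[-1, ], "genome_id"), "unassigned")
  expect_true("unassigned" %in% cen3$group)
  expect_equal(sum(cen3$total_genes), 5)
})

test_that("per-genome proportions match hand-checked percentages", {
  expect_equal(composite_proportion(34455, 109018), 31.60)
  expect_equal(composite_proportion(175, 1885), 9.28)
  expect_equal(composite_proportion(0, 1000), 0)
})
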