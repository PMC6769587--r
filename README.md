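# fusenet

Detection of composite (fused) genes in protein sequence similarity
networks, with a four-way remodelling classification, equal-size class
resampling, and odds-ratio enrichment statistics.

## The problem

New genes frequently arise by **gene fusion**: fragments of two unrelated
parental ("component") genes merge into a single **composite** gene. Such
reticulate events are invisible to tree-based phylogenetics but leave a
characteristic motif in a **sequence similarity network (SSN)** — an
undirected graph whose nodes are genes and whose edges record significant
pairwise homology from an all-vs-all protein search. A composite gene *g*
sits at the centre of a **non-transitive triplet** `a – g – b`:

* both `a` and `b` are homologous to `g`,
* `a` and `b` show **no** homology to each other, and
* the alignments of `a` and `b` occupy (near-)disjoint regions of `g` —
  their footprints overlap by at most a small tolerance (20 aa by
  default).

`fusenet` finds every such triplet, certifies composites by their witness
triplets, and partitions all genes into four classes: **nested
composites** (composites that also act as components of other
composites), **strict composites**, **strict components**, and
**non-remodelled** genes. Downstream, it asks whether composite genes are
over-represented in eukaryotes relative to prokaryotes, per functional
(COG) category, with the odds ratio

```
OR = (a·d) / (b·c)
```

where `a`/`b` are composite/non-composite eukaryote gene counts and
`c`/`d` the prokaryote counts, and the Woolf log-scale confidence
interval

```
exp[ ln(OR) ± z · sqrt(1/a + 1/b + 1/c + 1/d) ]
```

at the Bonferroni-corrected quantile `z = Φ⁻¹(1 − α/2N)` (3.09 for
α = 0.05 over N = 24 categories, by standard-normal-table convention).
A category is significant when the interval excludes 1.

The package is aimed at comparative genomicists studying gene
remodelling across the domains of life and mobile genetic elements. It
consumes standard 12-column BLAST tabular output plus a gene-metadata
table, and ships a **synthetic-data generator** with known fusion ground
truth so the entire pipeline is testable without downloads or an
aligner.

## Worked example

Simulate a benchmark with a known eukaryote fusion excess, run the full
pipeline, and test the enrichment:

```r
library(fusenet)

cfg <- generator_config(
  n_genes_per_class = c(eukaryote = 400, bacteria = 300, archaea = 300),
  fusion_prob       = c(eukaryote = 0.25, bacteria = 0.12, archaea = 0.12),
  n_families = 120, rng_seed = 42)
sim <- simulate_gene_set(cfg)

analysis <- run_composite_pipeline(
  sim$hits, sim_metadata(sim),
  gene_lengths = sim$genes[c("gene_id", "length")])
#> filtered hits: 5057 of 5057 retained
#> network: 1000 nodes, 5057 edges
#> families: 302
#> classes: 29 nested composite, 153 strict composite, 745 strict component,
#>   73 non-remodelled (182 composite total, 18.20%)

analysis$census_domain
#> # A tibble: 3 × 8
#>   group     total_genes n_composite n_nested n_strict_composite ...
#> 1 eukaryote         400         108       10                 98
#> 2 bacteria          300          40        8                 32
#> 3 archaea           300          34       11                 23

score_recovery(analysis$classification, sim$truth)
#> Composite recovery on 1000 genes: precision 1.000, recall 1.000
```

At zero generator noise the detector recovers the ground truth exactly
(precision = recall = 1): every generated fusion is certified by a
triplet and nothing else is. The census shows the engineered contrast —
27.00% of eukaryote genes are composite against 13.33% / 11.33% for the
prokaryotes. The per-category odds-ratio test then quantifies it:

```r
enr <- run_enrichment(analysis$classification, sim_metadata(sim),
                      sim$annotations)
glance(enr)
#> # A tibble: 1 × 7
#>   n_categories n_tested n_skipped n_significant alpha alpha_corrected     z
#> 1           24       23         1             0  0.05         0.00109  3.09
autoplot(enr)   # forest plot of per-category ORs
```

With only ~40 annotated genes per category none of the 24 individual
categories clears the conservative corrected quantile (z = 3.09), while
the pooled table does — the correction is doing its job at this sample
size. One category is skipped because a cell of its 2×2 table is zero
(no composite prokaryote gene carries that letter), mirroring how such
categories are excluded rather than continuity-corrected.

Equal-size resampling (`resample_spec()`, `run_resampling()`,
`summarize_replicates()`) re-analyses node-induced subnetworks of equal
gene counts per genome class; because subsampling removes triplet
witnesses, its mean composite fraction is a lower bound on the
full-network fraction.

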