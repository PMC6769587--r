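---
title: "Detecting composite genes in sequence similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting composite genes in sequence similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusenet)
```

## The model

Gene fusion joins fragments of two unrelated parental genes into one
composite gene. In a sequence similarity network (SSN) — genes as nodes,
significant pairwise homology as undirected edges — a composite gene `g`
is certified by a *non-transitive triplet*: a pair of neighbours `a`, `b`
of `g` such that (i) no edge joins `a` and `b`, and (ii) the alignment
footprints of `a` and `b` on `g` overlap by at most
`max_component_overlap` residues. Condition (i) says the two parents are
unrelated; condition (ii) says they account for essentially disjoint
parts of `g`, as expected if `g` is their concatenation.

Detection certifies each composite with its witness triplets, then
partitions all genes by set algebra: `nested_composite` = composite ∩
component, `strict_composite` = composite \ component,
`strict_component` = component \ composite, `non_remodelled` = the rest.
This partition is exhaustive and exclusive by construction, and the
identity `nested + strict composite = all composites` is asserted in the
tests.

Assumptions worth stating:

* **Homology is symmetric.** A hit found in only one direction (possible
  under max-target-seqs truncation in the upstream search) still creates
  an edge.
* **Non-adjacency is evaluated on the filtered network**, after the
  E-value/identity/length cuts, not on the raw hit table: one network is
  built and motifs are found in it.
* **Components are individual genes**, not families, at detection time.
  Requiring the two components to belong to different *families* is a
  stricter criterion; gene-level non-adjacency is more general and is
  what is implemented (family-level summaries can be derived afterwards
  from `assign_families()`).
* **Absence of evidence is evidence of absence**: a missing edge is
  treated as non-homology. Detection rates are therefore lower bounds —
  sparser sampling removes witnesses and can only hide composites, never
  invent them. The resampling module quantifies exactly this effect.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `max_evalue` | 1e-5 | — | hit filter; the conventional significance cutoff for all-vs-all BLASTP |
| `min_identity` | 30 | % | hit filter; below ~30% protein homology inference is unreliable |
| `min_alignment_length` | 20 | aa | hit filter; discards micro-alignments |
| `max_component_overlap` | 20 | aa | triplet tolerance; allows short overlaps between component footprints to limit false negatives |
| `family_min_coverage` | 0.8 | fraction | an edge joins two genes into one family only if its merged footprint covers ≥ 80% of *both* genes |

The 20-aa overlap tolerance is read as an *allowed overlap* between
component footprints. A different reading — 20 aa as a minimum alignment
length — is covered independently by `min_alignment_length`; the two
knobs are deliberately separate.

## Footprints and families

All HSPs of a gene pair are merged into a per-endpoint union of
intervals, and the triplet test uses the *envelope* (the span from the
first to the last covered residue). Merging is the conservative choice:
a fragmented alignment of a true full-length homolog must not masquerade
as two disjoint components. Coordinates are 1-based inclusive exactly as
in BLAST tabular output throughout; reverse-orientation coordinates are
rejected because inputs are proteins.

Families are connected components of the subgraph restricted to
mutual-coverage ≥ 80% edges. Under this rule a composite never drags its
component families together, because fusion edges are partial on the
composite side. The published family counts for networks of this kind do
not state whether coverage filtering was applied, so a
`mode = "components"` alternative (families = components of the whole
network) is exposed for comparison. Family labels derive from the
lexicographically smallest member, making the assignment stable across
re-runs.

## The enrichment test

Per functional category, the 2×2 table counts composite/non-composite ×
eukaryote/prokaryote genes (archaea + bacteria; viruses and plasmids
excluded). A gene annotated with k category letters counts once in each
of the k categories, with no de-duplication. The odds ratio is
`(a·d)/(b·c)` with the Woolf interval
`exp[ln(OR) ± z·sqrt(1/a + 1/b + 1/c + 1/d)]`. Some presentations of
this interval omit the square root; without it the log-scale term has
the wrong units, so the standard Woolf form with the square root is the
only one implemented.

The corrected quantile uses the level `α/2N`. Under the default
`convention = "table"` the corrected level is rounded to three decimals
before the quantile lookup — the behaviour of reading a standard normal
table at "99.9%" — giving z = 3.09 for α = 0.05, N = 24; the `"exact"`
convention (z = 3.078 for the same case) is available. N defaults to
the number of categories actually tested: a category with any zero cell
is reported but skipped, not continuity-corrected (a Haldane–Anscombe
0.5 correction was considered and rejected as default because skipping
matches how zero-cell categories are conventionally reported in this
setting). Whether skipped categories should still count towards N is
genuinely ambiguous; `n_tests` is therefore user-overridable.

## The synthetic generator

`generator_config()` defines the benchmark conditions:

* **Component families** of mutually homologous, full-length,
  identical-length genes; non-composite genes are assigned to
  `n_families` families uniformly. The default (2,000 families for
  ~7,200 non-composite genes) gives a mean family size near 3.5,
  matching the granularity of family assignments in million-gene
  protein networks.
* **Composites** concatenate a *prefix* segment from each of two
  distinct families. Prefixes guarantee that two composites drawing on
  the same family overlap heavily on the shared members, so no spurious
  triplet forms at a component. Segments are ≥ `segment_min` = 41 aa
  (minimum alignment length + overlap tolerance + 1), guaranteeing
  detectability, and are capped at three times each other so neither
  side reaches the 80% family-coverage threshold.
* **Nested composites** fuse one existing composite (kept full length)
  with a segment from a family the parent has no homology link to; the
  exclusion prevents the parent–segment edge that would destroy the
  certifying triplet.
* **Class labels and fusion rates**: per-class gene counts and fusion
  probabilities default to the relative composite rates reported across
  the domains of life (eukaryote 0.2266, bacteria 0.1476, archaea
  0.1278, plasmid 0.1469, virus 0.0482) at a total of 8,500 genes. The
  implied eukaryote-vs-prokaryote generating odds ratio
  (`generating_odds_ratio()`) is ≈ 1.83.
* **Noise knobs**, all zero by default: footprint jitter (± residues on
  alignment endpoints), spurious-edge rate (expected false hits per
  gene), dropout rate (probability a true hit is lost). At zero noise,
  detection provably recovers the ground truth exactly — the flagship
  property test — and the noise knobs move precision/recall in the
  expected directions (asserted as trends across seeds).

What the generator does **not** emulate: realistic BLAST score
statistics, indels (FASTA mode mutates archetypes by substitution only,
keeping coordinates exact), phylogenetic correlation between families,
domain-database structure, and within-family length variation. Passing
tests therefore demonstrate the correctness of the graph-analytic
machinery and the statistical calibration of the enrichment test — not
robustness to alignment artefacts in real data.

## Numerical choices

* Percentages are rounded half-up to two decimals
  (`composite_proportion()`), matching how published census tables are
  printed; R's default banker's rounding would disagree on exact halves.
* Triplets and classifications are emitted in lexicographic gene-id
  order; re-running the same input yields byte-identical TSVs.
* Degenerate inputs: empty hit files parse to empty streams; an edgeless
  network classifies everything non-remodelled; two-node connected
  components can never yield composites (a triplet needs three nodes)
  and need no special casing.
* Resampling RNG: each (replicate, class) draw derives its own seed from
  the master seed, so replicates are independently reproducible and the
  result is invariant to the order classes are listed. Uniform sampling
  over genes within a class is used; per-genome balancing within a class
  is a design alternative that was not adopted, since the experiment's
  purpose is to equalise *class* totals.

## Problem sizes

The shipped tests run detection on networks up to ~200 nodes against a
brute-force triplet oracle (100 random networks), parameter-recovery and
calibration simulations on 100/40 seeds of an 800-gene two-class
benchmark, and the resampling contrast on an 8,000-gene four-class
benchmark (500 genes per class, 20 replicates). These sizes keep the
whole suite in the minutes range on a single CPU while leaving each
statistical assertion adequately powered; the acceptance script runs the
full default 8,500-gene benchmark in well under a minute.

## Known limitations

* The detector treats missing edges as true non-homology; divergent
  homologs below the identity cutoff inflate the composite count in
  real data (and deflate it in subsamples). All reported rates are
  lower bounds with respect to witness loss and upper bounds with
  respect to remote-homology false negatives on the component edge.
* Multi-composite chains are not a separate category: nesting is binary
  (a composite either is or is not also a component).
* The induced-subgraph resampling is exact for all-vs-all hit tables
  but diverges from a true re-run when the original search truncated
  hit lists (max-target-seqs effects).
* Woolf intervals are asymptotic; with per-cell counts below ~5 their
  coverage degrades. The generator's calibration tests use cell counts
  comfortably above that regime.
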