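# shared fixtures, all built in code

# a hit row in read_blast_tab() layout
hit_row <- function(q, s, qs, qe, ss, se,
                    pident = 90, evalue = 1e-50) {
  tibble::tibble(
    query_id = q, subject_id = s, percent_identity = pident,
    aln_length = qe - qs + 1, mismatches = 0, gap_opens = 0,
    q_start = qs, q_end = qe, s_start = ss, s_end = se,
    evalue = evalue, bitscore = 100, self_hit = q == s
  )
}

# the toy six-family network: A fused from B and C, D fused from A and E,
# F untouched. Genes stand in for their families.
fig2_genes <- function() {
  tibble::tibble(
    gene_id = c("A", "B", "C", "D", "E", "F"),
    genome_id = "toy",
    domain_class = "bacteria",
    length = c(200, 95, 90, 500, 110, 150)
  )
}

fig2_hits <- function() {
  dplyr::bind_rows(
    hit_row("A", "B", 1, 90, 1, 90),      # B covers the N-terminal part of A
    hit_row("A", "C", 120, 200, 5, 85),   # C covers the C-terminal part of A
    hit_row("D", "A", 1, 200, 1, 200),    # D contains all of A
    hit_row("D", "E", 280, 380, 5, 105)   # plus a disjoint piece of E
  )
}

fig2_ssn <- function() {
  build_ssn(fig2_genes(), filter_hits(fig2_hits()))
}

# random SSN: genes with lengths, random pairs with random footprints
random_ssn <- function(seed, n_genes = 60, n_hits = 3 * n_genes) {
  withr::with_seed(seed, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      genome_id = "sim",
      domain_class = sample(domain_classes(), n_genes, replace = TRUE),
      length = sample(150:500, n_genes, replace = TRUE)
    )
    qi <- sample(genes$gene_id, n_hits, replace = TRUE)
    si <- sample(genes$gene_id, n_hits, replace = TRUE)
    len <- stats::setNames(genes$length, genes$gene_id)
    span <- sample(25:220, n_hits, replace = TRUE)
    span_q <- pmin(span, len[qi])
    span_s <- pmin(span, len[si])
    qs <- vapply(len[qi] - span_q + 1, function(m) sample.int(m, 1), 1)
    ss <- vapply(len[si] - span_s + 1, function(m) sample.int(m, 1), 1)
    hits <- tibble::tibble(
      query_id = qi, subject_id = si,
      percent_identity = round(runif(n_hits, 20, 100), 1),
      aln_length = span_q, mismatches = 0, gap_opens = 0,
      q_start = qs, q_end = qs + span_q - 1,
      s_start = ss, s_end = ss + span_s - 1,
      evalue = 10^runif(n_hits, -60, -3),
      bitscore = 100, self_hit = qi == si
    )
    build_ssn(genes, filter_hits(hits))
  })
}

# independent brute-force triplet oracle: plain loops over the stored
# edge envelopes, no shared code with the detector's enumeration
brute_force_detect <- function(ssn, params = detection_params()) {
  e <- ssn$edges
  has_edge <- function(a, b) {
    any((e$gene1 == a & e$gene2 == b) | (e$gene1 == b & e$gene2 == a))
  }
  env_on <- function(g, nbr) {
    i <- which((e$gene1 == g & e$gene2 == nbr) |
                 (e$gene2 == g & e$gene1 == nbr))
    if (e$gene1[i] == g) c(e$env1_start[i], e$env1_end[i])
    else c(e$env2_start[i], e$env2_end[i])
  }
  composites <- character(0)
  components <- character(0)
  n_triplets <- 0L
  for (g in ssn$nodes$gene_id) {
    nbrs <- sort(unique(c(e$gene2[e$gene1 == g], e$gene1[e$gene2 == g])))
    if (length(nbrs) < 2) next
    for (i in seq_len(length(nbrs) - 1)) {
      for (j in seq(i + 1, length(nbrs))) {
        a <- nbrs[i]; b <- nbrs[j]
        if (has_edge(a, b)) next
        fa <- env_on(g, a); fb <- env_on(g, b)
        ov <- max(0, min(fa[2], fb[2]) - max(fa[1], fb[1]) + 1)
        if (ov <= params$max_component_overlap) {
          composites <- c(composites, g)
          components <- c(components, a, b)
          n_triplets <- n_triplets + 1L
        }
      }
    }
  }
  list(composites = sort(unique(composites)),
       components = sort(unique(components)),
       n_triplets = n_triplets)
}

# small synthetic config for fast tests
small_config <- function(seed = 1, ...) {
  generator_config(
    n_genes_per_class = c(eukaryote = 150, bacteria = 100, archaea = 100,
                          plasmid = 80, virus = 40),
    n_families = 60,
    rng_seed = seed,
    ...
  )
}

# run detection + classification on a simulated gene set
classify_sim <- function(sim, params = detection_params()) {
  ssn <- build_ssn(sim$genes, filter_hits(sim$hits, params))
  det <- detect_composites(ssn, params)
  classify_genes(ssn$nodes$gene_id, det$composites, det$components)
}
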