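#' Filter homology hits by E-value, identity and alignment length
#'
#' Retains exactly the hits with `evalue <= max_evalue`,
#' `percent_identity >= min_identity` and query-side alignment length
#' (`q_end - q_start + 1`) at least `min_alignment_length`. Self-hits are
#' removed: a gene is trivially homologous to itself and triplet logic
#' requires distinct nodes.
#'
#' @param hits Hit tibble (see [read_blast_tab()]).
#' @param params [detection_params()].
#' @return Filtered hit tibble.
#' @export
filter_hits <- function(hits, params = detection_params()) {
  stopifnot(inherits(params, "fusenet_params"))
  dplyr::filter(
    hits,
    .data$query_id != .data$subject_id,
    .data$evalue <= params$max_evalue,
    .data$percent_identity >= params$min_identity,
    (.data$q_end - .data$q_start + 1) >= params$min_alignment_length
  )
}

#' Build a sequence similarity network from filtered hits
#'
#' Nodes are genes; one undirected edge joins every unordered pair with at
#' least one surviving hit in either direction (homology is symmetric, so a
#' hit found in only one direction still creates an edge). Each edge stores,
#' for both endpoints, the merged union of all surviving HSP intervals
#' falling on that gene - query-side coordinates when the gene was the
#' query, subject-side when it was the subject. Merging all HSPs into one
#' envelope per neighbour is deliberate: fragmented alignments of a true
#' full-length homolog must not masquerade as two disjoint components.
#' Genes with no surviving edges remain isolated nodes.
#'
#' @param genes Tibble with at least `gene_id`; `genome_id`, `domain_class`
#'   and `length` are carried along when present. `length` (amino acids)
#'   enables coverage computation for family assignment.
#' @param hits Filtered hit tibble ([filter_hits()]).
#' @return An object of class `fusenet_ssn`: list with `nodes` (tibble),
#'   `edges` (tibble with merged footprints, envelopes, coverages,
#'   best identity / E-value) and `skipped_hits` (hits referencing genes
#'   absent from `genes`, reported rather than silently dropped).
#' @export
build_ssn <- function(genes, hits) {
  stopifnot(is.data.frame(genes), "gene_id" %in% names(genes))
  if (anyDuplicated(genes$gene_id) > 0) {
    abort("gene_id must be unique in the gene table")
  }
  nodes <- as_tibble(genes)
  if (!"length" %in% names(nodes)) nodes$length <- NA_real_

  known <- hits$query_id %in% nodes$gene_id &
    hits$subject_id %in% nodes$gene_id
  skipped <- hits[!known, ]
  hits <- hits[known, ]
  hits <- hits[hits$query_id != hits$subject_id, ]

  if (nrow(hits) == 0) {
    edges <- tibble(
      gene1 = character(), gene2 = character(),
      fp1 = list(), fp2 = list(),
      env1_start = numeric(), env1_end = numeric(),
      env2_start = numeric(), env2_end = numeric(),
      cov1 = numeric(), cov2 = numeric(),
      best_identity = numeric(), best_evalue = numeric()
    )
  } else {
    flip <- hits$query_id > hits$subject_id
    g1 <- ifelse(flip, hits$subject_id, hits$query_id)
    g2 <- ifelse(flip, hits$query_id, hits$subject_id)
    s1 <- ifelse(flip, hits$s_start, hits$q_start)
    e1 <- ifelse(flip, hits$s_end, hits$q_end)
    s2 <- ifelse(flip, hits$q_start, hits$s_start)
    e2 <- ifelse(flip, hits$q_end, hits$s_end)
    per_hit <- tibble(
      gene1 = g1, gene2 = g2, s1 = s1, e1 = e1, s2 = s2, e2 = e2,
      identity = hits$percent_identity, evalue = hits$evalue
    )
    edges <- per_hit |>
      group_by(.data$gene1, .data$gene2) |>
      summarise(
        fp1 = list(merge_intervals(cbind(.data$s1, .data$e1))),
        fp2 = list(merge_intervals(cbind(.data$s2, .data$e2))),
        best_identity = max(.data$identity),
        best_evalue = min(.data$evalue),
        .groups = "drop"
      ) |>
      mutate(
        env1_start = map_dbl(.data$fp1, ~ .x[1, 1]),
        env1_end = map_dbl(.data$fp1, ~ .x[nrow(.x), 2]),
        env2_start = map_dbl(.data$fp2, ~ .x[1, 1]),
        env2_end = map_dbl(.data$fp2, ~ .x[nrow(.x), 2])
      )
    len <- setNames(nodes$length, nodes$gene_id)
    edges$cov1 <- map_dbl(edges$fp1, covered_length) /
      unname(len[edges$gene1])
    edges$cov2 <- map_dbl(edges$fp2, covered_length) /
      unname(len[edges$gene2])
    edges <- arrange(edges, .data$gene1, .data$gene2)
  }

  structure(
    list(nodes = nodes, edges = edges, skipped_hits = skipped),
    class = "fusenet_ssn"
  )
}

#' @export
print.fusenet_ssn <- function(x, ...) {
  cat(sprintf("Sequence similarity network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$skipped_hits) > 0) {
    cat(sprintf("  (%d hit(s) referenced genes absent from the gene table)\n",
                nrow(x$skipped_hits)))
  }
  invisible(x)
}

#' @export
glance.fusenet_ssn <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_isolated = nrow(x$nodes) -
      length(unique(c(x$edges$gene1, x$edges$gene2))),
    n_skipped_hits = nrow(x$skipped_hits)
  )
}

#' @export
tidy.fusenet_ssn <- function(x, ...) {
  select(x$edges, "gene1", "gene2", "env1_start", "env1_end",
         "env2_start", "env2_end", "cov1", "cov2",
         "best_identity", "best_evalue")
}

# igraph view of the SSN topology (names preserved)
ssn_graph <- function(ssn) {
  igraph::graph_from_data_frame(
    ssn$edges[c("gene1", "gene2")], directed = FALSE,
    vertices = ssn$nodes$gene_id
  )
}

#' Assign genes to families
#'
#' In `"coverage"` mode (the default) families are the connected components
#' of the subgraph restricted to edges whose merged footprint covers at
#' least `family_min_coverage` of BOTH genes' lengths - i.e. near
#' full-length homology. Partial-coverage edges (such as composite-component
#' links) do not merge families, so a composite does not drag its component
#' families together. `"components"` mode uses all edges (families =
#' connected components of the whole network) for comparison. Isolated
#' genes form singleton families. Family labels are derived from the
#' lexicographically smallest member, so the assignment is stable across
#' re-runs of the same input.
#'
#' @param ssn A `fusenet_ssn`.
#' @param params [detection_params()]; supplies `family_min_coverage`.
#' @param mode `"coverage"` or `"components"`.
#' @return Tibble `gene_id`, `family_id`, `family_size`.
#' @export
assign_families <- function(ssn, params = detection_params(),
                            mode = c("coverage", "components")) {
  mode <- arg_match(mode)
  stopifnot(inherits(ssn, "fusenet_ssn"))
  edges <- ssn$edges
  if (mode == "coverage") {
    if (nrow(edges) > 0 && anyNA(c(edges$cov1, edges$cov2))) {
      abort(paste0(
        "gene lengths are required for coverage-based families; ",
        "supply a 'length' column in the gene table (e.g. from a FASTA)"))
    }
    fc <- params$family_min_coverage
    edges <- edges[edges$cov1 >= fc & edges$cov2 >= fc, ]
  }
  g <- igraph::graph_from_data_frame(
    edges[c("gene1", "gene2")], directed = FALSE,
    vertices = ssn$nodes$gene_id
  )
  comp <- igraph::components(g)
  member <- comp$membership
  # stable ids: label components by their lexicographically smallest member
  reps <- tapply(names(member), member, min)
  rank <- match(reps, sort(reps))
  fam_of_comp <- sprintf("F%05d", rank)
  out <- tibble(
    gene_id = names(member),
    family_id = fam_of_comp[member]
  )
  sizes <- table(out$family_id)
  out$family_size <- as.integer(sizes[out$family_id])
  arrange(out, .data$gene_id)
}

#' Restrict a network to a gene subset (node-induced subgraph)
#'
#' Keeps edges with both endpoints in `gene_ids`; footprints are unchanged.
#' With an all-vs-all hit table this is exactly the network a fresh
#' analysis of the subset would build (up to max-target-seqs truncation in
#' the original search).
#'
#' @param ssn A `fusenet_ssn`.
#' @param gene_ids Character vector of genes to keep.
#' @return A `fusenet_ssn` on the subset.
#' @export
induce_ssn <- function(ssn, gene_ids) {
  stopifnot(inherits(ssn, "fusenet_ssn"))
  nodes <- ssn$nodes[ssn$nodes$gene_id %in% gene_ids, ]
  edges <- ssn$edges[ssn$edges$gene1 %in% gene_ids &
                       ssn$edges$gene2 %in% gene_ids, ]
  structure(
    list(nodes = nodes, edges = edges,
         skipped_hits = ssn$skipped_hits[0, ]),
    class = "fusenet_ssn"
  )
}
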