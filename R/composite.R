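# long neighbour table: one row per (gene, neighbour) with the envelope of
# the neighbour's alignment footprint ON the gene
neighbour_table <- function(ssn) {
  e <- ssn$edges
  bind_rows(
    tibble(gene = e$gene1, nbr = e$gene2,
           env_start = e$env1_start, env_end = e$env1_end),
    tibble(gene = e$gene2, nbr = e$gene1,
           env_start = e$env2_start, env_end = e$env2_end)
  )
}

edge_keys <- function(ssn) {
  paste(ssn$edges$gene1, ssn$edges$gene2, sep = "\r")
}

# all certifying triplets of the network (or of a subset of focal genes)
enumerate_triplets <- function(ssn, params, focal = NULL) {
  empty <- tibble(
    composite = character(), component_a = character(),
    component_b = character(),
    a_start = numeric(), a_end = numeric(),
    b_start = numeric(), b_end = numeric(), overlap = numeric()
  )
  if (nrow(ssn$edges) == 0) return(empty)
  nb <- neighbour_table(ssn)
  if (!is.null(focal)) nb <- nb[nb$gene %in% focal, ]
  deg <- table(nb$gene)
  nb <- nb[nb$gene %in% names(deg)[deg >= 2], ]
  if (nrow(nb) == 0) return(empty)
  cand <- inner_join(nb, nb, by = "gene", suffix = c("_a", "_b"),
                     relationship = "many-to-many")
  cand <- cand[cand$nbr_a < cand$nbr_b, ]
  cand$overlap <- overlap_len(cand$env_start_a, cand$env_end_a,
                              cand$env_start_b, cand$env_end_b)
  cand <- cand[cand$overlap <= params$max_component_overlap, ]
  if (nrow(cand) == 0) return(empty)
  keys <- paste(cand$nbr_a, cand$nbr_b, sep = "\r")
  cand <- cand[!(keys %in% edge_keys(ssn)), ]
  if (nrow(cand) == 0) return(empty)
  out <- tibble(
    composite = cand$gene,
    component_a = cand$nbr_a, component_b = cand$nbr_b,
    a_start = cand$env_start_a, a_end = cand$env_end_a,
    b_start = cand$env_start_b, b_end = cand$env_end_b,
    overlap = cand$overlap
  )
  arrange(out, .data$composite, .data$component_a, .data$component_b)
}

#' Non-transitive triplets certifying one gene as a composite
#'
#' A gene g is certified composite by a pair of neighbours (a, b) such that
#' (i) a and b are not themselves connected in the network, and (ii) their
#' alignment footprints on g overlap by at most `max_component_overlap`
#' residues - i.e. a and b align to essentially disjoint regions of g while
#' showing no homology to each other. Footprints are the merged envelopes
#' stored on the edges.
#'
#' @param ssn A `fusenet_ssn`.
#' @param gene A gene id present in the network.
#' @param params [detection_params()].
#' @return Tibble of triplets, ordered lexicographically by component ids:
#'   `composite`, `component_a`, `component_b`, the two footprint envelopes
#'   on the composite (`a_start`, `a_end`, `b_start`, `b_end`) and their
#'   `overlap` in residues.
#' @export
find_triplets <- function(ssn, gene, params = detection_params()) {
  stopifnot(inherits(ssn, "fusenet_ssn"))
  if (!gene %in% ssn$nodes$gene_id) {
    abort(paste0("gene not in the network: ", gene))
  }
  enumerate_triplets(ssn, params, focal = gene)
}

#' Detect composite and component genes in a network
#'
#' Enumerates every certifying non-transitive triplet (see
#' [find_triplets()]). Composites are genes with at least one triplet;
#' components are genes appearing as a component in at least one triplet of
#' any composite. Every composite retains its witnessing triplets.
#'
#' @param ssn A `fusenet_ssn`.
#' @param params [detection_params()].
#' @return A list of class `fusenet_detection`: `composites` and
#'   `components` (sorted character vectors) and `triplets` (tibble as in
#'   [find_triplets()], over all genes, in deterministic order).
#' @export
detect_composites <- function(ssn, params = detection_params()) {
  stopifnot(inherits(ssn, "fusenet_ssn"))
  triplets <- enumerate_triplets(ssn, params)
  structure(
    list(
      composites = sort(unique(triplets$composite)),
      components = sort(unique(c(triplets$component_a,
                                 triplets$component_b))),
      triplets = triplets
    ),
    class = "fusenet_detection"
  )
}

#' @export
print.fusenet_detection <- function(x, ...) {
  cat(sprintf(
    "Composite detection: %d composite gene(s), %d component gene(s), %d certifying triplet(s)\n",
    length(x$composites), length(x$components), nrow(x$triplets)))
  invisible(x)
}

#' Re-check stored triplets against the network
#'
#' Witness soundness: every stored triplet must still satisfy the defining
#' conditions - both composite-component edges present, no component-
#' component edge, and footprint overlap within the allowed tolerance.
#'
#' @param ssn A `fusenet_ssn`.
#' @param triplets Triplet tibble.
#' @param params [detection_params()].
#' @return `TRUE` if all triplets check out, otherwise an error.
#' @export
verify_triplets <- function(ssn, triplets, params = detection_params()) {
  if (nrow(triplets) == 0) return(TRUE)
  keys <- edge_keys(ssn)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ok_edges <- ekey(triplets$composite, triplets$component_a) %in% keys &
    ekey(triplets$composite, triplets$component_b) %in% keys
  ok_gap <- !(ekey(triplets$component_a, triplets$component_b) %in% keys)
  ok_overlap <- triplets$overlap <= params$max_component_overlap
  ok_distinct <- triplets$component_a != triplets$component_b &
    triplets$composite != triplets$component_a &
    triplets$composite != triplets$component_b
  if (!all(ok_edges & ok_gap & ok_overlap & ok_distinct)) {
    abort("stored triplet(s) failed re-verification against the network")
  }
  TRUE
}

#' Four-way remodelling classification
#'
#' Genes certified as composites that also serve as components elsewhere are
#' nested composites; composites never seen as components are strict
#' composites; genes only ever seen as components are strict components;
#' everything else is non-remodelled. The four classes partition the gene
#' set.
#'
#' @param gene_ids Character vector of all genes to classify.
#' @param composites,components Sets from [detect_composites()].
#' @return Tibble `gene_id`, `gene_class` (factor with levels
#'   [gene_classes()]), sorted by gene id.
#' @export
classify_genes <- function(gene_ids, composites, components) {
  gene_ids <- sort(unique(gene_ids))
  is_comp <- gene_ids %in% composites
  is_cmpt <- gene_ids %in% components
  cls <- ifelse(is_comp & is_cmpt, "nested_composite",
         ifelse(is_comp, "strict_composite",
         ifelse(is_cmpt, "strict_component", "non_remodelled")))
  tibble(
    gene_id = gene_ids,
    gene_class = factor(cls, levels = gene_classes())
  )
}

#' Census of remodelling classes per genome or genome class
#'
#' One row per group with the four class counts, the composite total
#' (nested + strict composite) and the composite proportion as a percentage
#' rounded half-up to two decimals, mirroring how per-genome composite
#' rates are conventionally tabulated. Genes lacking metadata are gathered
#' into an `"unassigned"` row with a warning rather than dropped.
#'
#' @param classification Tibble from [classify_genes()].
#' @param metadata Metadata tibble (`gene_id`, `genome_id`,
#'   `domain_class`).
#' @param group_by `"domain_class"` or `"genome_id"`.
#' @return Tibble with columns `group`, `total_genes`, `n_nested`,
#'   `n_strict_composite`, `n_strict_component`, `n_non_remodelled`,
#'   `n_composite`, `proportion_composite`, sorted by descending
#'   proportion.
#' @export
census <- function(classification, metadata,
                   group_by = c("domain_class", "genome_id")) {
  group_by <- arg_match(group_by)
  joined <- left_join(classification, metadata, by = "gene_id")
  grp <- joined[[group_by]]
  if (anyNA(grp)) {
    warn(sprintf("%d gene(s) lack metadata; reported as 'unassigned'",
                 sum(is.na(grp))))
    grp[is.na(grp)] <- "unassigned"
  }
  joined$group <- grp
  out <- joined |>
    count(.data$group, .data$gene_class, .drop = FALSE) |>
    pivot_wider(names_from = "gene_class", values_from = "n",
                values_fill = 0L) |>
    rename(
      n_nested = "nested_composite",
      n_strict_composite = "strict_composite",
      n_strict_component = "strict_component",
      n_non_remodelled = "non_remodelled"
    ) |>
    mutate(
      total_genes = .data$n_nested + .data$n_strict_composite +
        .data$n_strict_component + .data$n_non_remodelled,
      n_composite = .data$n_nested + .data$n_strict_composite,
      proportion_composite = composite_proportion(.data$n_composite,
                                                  .data$total_genes)
    ) |>
    relocate("group", "total_genes", "n_composite") |>
    arrange(desc(.data$proportion_composite), .data$group)
  out
}

#' Composite proportion as a reported percentage
#'
#' `100 * n_composite / total`, rounded half-up to two decimals - the
#' arithmetic behind per-genome composite rates such as 34,455 of 109,018
#' genes = 31.60%.
#'
#' @param n_composite,total Counts.
#' @return Percentage(s), two decimals.
#' @export
#' @examples
#' composite_proportion(34455, 109018) # 31.60
composite_proportion <- function(n_composite, total) {
  round_half_up(100 * n_composite / total, 2)
}

#' Assemble the per-gene classification report
#'
#' Joins metadata, triplet counts and one example witness per composite
#' into the tabular report written by the pipeline.
#'
#' @param classification Tibble from [classify_genes()].
#' @param metadata Metadata tibble.
#' @param triplets Triplet tibble from [detect_composites()].
#' @return Tibble `gene_id`, `genome_id`, `domain_class`, `gene_class`,
#'   `n_triplets`, `example_witness`, sorted by gene id.
#' @export
classification_report <- function(classification, metadata, triplets) {
  wit <- triplets |>
    group_by(.data$composite) |>
    summarise(
      n_triplets = n(),
      example_witness = paste0(.data$component_a[1], "+",
                               .data$component_b[1]),
      .groups = "drop"
    )
  classification |>
    left_join(metadata, by = "gene_id") |>
    left_join(wit, by = c(gene_id = "composite")) |>
    mutate(
      n_triplets = if_else(is.na(.data$n_triplets), 0L,
                           as.integer(.data$n_triplets)),
      example_witness = if_else(is.na(.data$example_witness), "",
                                .data$example_witness)
    ) |>
    select("gene_id", "genome_id", "domain_class", "gene_class",
           "n_triplets", "example_witness") |>
    arrange(.data$gene_id)
}
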