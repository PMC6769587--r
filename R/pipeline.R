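#' Run the full composite-gene detection pipeline
#'
#' Orchestrates filter -> build -> families -> detect -> classify ->
#' census, optionally writing every tabular report plus the GraphML/CSV
#' network export. All effective parameters are logged via [message()] so
#' a run is reconstructible from its log; the pipeline is deterministic,
#' so re-running the same inputs yields byte-identical outputs.
#'
#' @param hits Hit tibble ([read_blast_tab()]), unfiltered.
#' @param metadata Metadata tibble ([read_metadata()]).
#' @param params [detection_params()].
#' @param gene_lengths Optional tibble `gene_id`, `length` enabling
#'   coverage-based families.
#' @param family_mode `"coverage"` or `"components"`
#'   (see [assign_families()]).
#' @param out_dir Optional output directory; when given, writes
#'   `classification.tsv`, `triplets.tsv`, `families.tsv`,
#'   `census_domain.tsv`, `census_genome.tsv` and the network export
#'   under `network.*`.
#' @param quiet Suppress progress messages.
#' @return List of class `fusenet_analysis`: `ssn`, `detection`,
#'   `classification`, `families`, `census_domain`, `census_genome`,
#'   `report`, `params`.
#' @export
run_composite_pipeline <- function(hits, metadata,
                                   params = detection_params(),
                                   gene_lengths = NULL,
                                   family_mode = c("coverage",
                                                   "components"),
                                   out_dir = NULL, quiet = FALSE) {
  family_mode <- arg_match(family_mode)
  say <- function(...) if (!quiet) inform(sprintf(...))
  say("parameters: max_evalue=%g min_identity=%g min_alignment_length=%g max_component_overlap=%g family_min_coverage=%g family_mode=%s",
      params$max_evalue, params$min_identity, params$min_alignment_length,
      params$max_component_overlap, params$family_min_coverage,
      family_mode)

  miss <- missing_metadata(hits, metadata)
  if (length(miss) > 0) {
    warn(sprintf("%d gene(s) in the hit table lack metadata (first: %s)",
                 length(miss), miss[1]))
  }
  genes <- metadata
  if (!is.null(gene_lengths)) {
    genes <- left_join(genes, gene_lengths[c("gene_id", "length")],
                       by = "gene_id")
  }

  flt <- filter_hits(hits, params)
  say("filtered hits: %d of %d retained", nrow(flt), nrow(hits))
  ssn <- build_ssn(genes, flt)
  say("network: %d nodes, %d edges", nrow(ssn$nodes), nrow(ssn$edges))
  families <- assign_families(ssn, params, mode = family_mode)
  say("families: %d", length(unique(families$family_id)))
  detection <- detect_composites(ssn, params)
  classification <- classify_genes(ssn$nodes$gene_id,
                                   detection$composites,
                                   detection$components)
  n_cls <- table(classification$gene_class)
  say("classes: %d nested composite, %d strict composite, %d strict component, %d non-remodelled (%d composite total, %.2f%%)",
      n_cls[["nested_composite"]], n_cls[["strict_composite"]],
      n_cls[["strict_component"]], n_cls[["non_remodelled"]],
      length(detection$composites),
      100 * length(detection$composites) / nrow(classification))

  census_domain <- census(classification, metadata, "domain_class")
  census_genome <- census(classification, metadata, "genome_id")
  report <- classification_report(classification, metadata,
                                  detection$triplets)

  res <- structure(
    list(ssn = ssn, detection = detection,
         classification = classification, families = families,
         census_domain = census_domain, census_genome = census_genome,
         report = report, params = params),
    class = "fusenet_analysis"
  )
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' Write every tabular report of an analysis
#'
#' @param analysis A `fusenet_analysis`.
#' @param out_dir Output directory (created if needed).
#' @return Named vector of files written, invisibly.
#' @export
write_analysis <- function(analysis, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- c(
    classification = file.path(out_dir, "classification.tsv"),
    triplets = file.path(out_dir, "triplets.tsv"),
    families = file.path(out_dir, "families.tsv"),
    census_domain = file.path(out_dir, "census_domain.tsv"),
    census_genome = file.path(out_dir, "census_genome.tsv")
  )
  readr::write_tsv(analysis$report, files[["classification"]],
                   progress = FALSE)
  readr::write_tsv(analysis$detection$triplets, files[["triplets"]],
                   progress = FALSE)
  readr::write_tsv(analysis$families, files[["families"]],
                   progress = FALSE)
  readr::write_tsv(analysis$census_domain, files[["census_domain"]],
                   progress = FALSE)
  readr::write_tsv(analysis$census_genome, files[["census_genome"]],
                   progress = FALSE)
  net <- write_network(analysis$ssn, file.path(out_dir, "network"),
                       classification = analysis$classification,
                       families = analysis$families)
  invisible(c(files, net))
}

#' @export
print.fusenet_analysis <- function(x, ...) {
  print(x$ssn)
  print(x$detection)
  cat("Census by genome class:\n")
  print(x$census_domain)
  invisible(x)
}

#' @export
glance.fusenet_analysis <- function(x, ...) {
  cls <- table(x$classification$gene_class)
  tibble(
    n_nodes = nrow(x$ssn$nodes),
    n_edges = nrow(x$ssn$edges),
    n_families = length(unique(x$families$family_id)),
    n_composite = length(x$detection$composites),
    n_nested = cls[["nested_composite"]],
    n_strict_composite = cls[["strict_composite"]],
    n_strict_component = cls[["strict_component"]],
    n_non_remodelled = cls[["non_remodelled"]],
    pct_composite = composite_proportion(
      length(x$detection$composites), nrow(x$classification))
  )
}

#' @export
tidy.fusenet_analysis <- function(x, ...) x$report
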