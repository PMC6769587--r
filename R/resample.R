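#' Specification of the equal-size class resampling experiment
#'
#' Repeatedly draws equal numbers of genes per genome class, re-analyses
#' the induced network, and summarises the class-wise remodelling counts.
#' Viruses are excluded from the default class list: the resampling design
#' balances the three cellular domains and plasmids.
#'
#' @param classes Genome classes to sample (subset of [domain_classes()]).
#' @param n_per_class Genes drawn per class and replicate.
#' @param replicates Number of replicates.
#' @param rng_seed Master seed; each (replicate, class) draw derives its
#'   own stream so replicates are independently reproducible and the result
#'   is invariant to the order classes are listed in.
#' @return List of class `fusenet_resample_spec`.
#' @export
resample_spec <- function(classes = c("archaea", "bacteria", "eukaryote",
                                      "plasmid"),
                          n_per_class = 50000, replicates = 100,
                          rng_seed = 1) {
  stopifnot(
    all(classes %in% domain_classes()), length(classes) >= 1,
    n_per_class >= 1, replicates >= 1
  )
  structure(
    list(classes = sort(classes), n_per_class = as.integer(n_per_class),
         replicates = as.integer(replicates),
         rng_seed = as.integer(rng_seed)),
    class = "fusenet_resample_spec"
  )
}

# deterministic per-(replicate, class) seed, independent of class order
subsample_seed <- function(spec, replicate_index, class) {
  spec$rng_seed + 1009L * as.integer(replicate_index) +
    match(class, domain_classes())
}

#' Draw one equal-size gene subset
#'
#' Uniform sampling without replacement within each class, fully
#' reproducible from `(rng_seed, replicate_index)`.
#'
#' @param metadata Metadata tibble.
#' @param spec [resample_spec()].
#' @param replicate_index Replicate number (1-based).
#' @return Sorted character vector of sampled gene ids.
#' @export
subsample <- function(metadata, spec, replicate_index) {
  stopifnot(inherits(spec, "fusenet_resample_spec"))
  picks <- lapply(spec$classes, function(cl) {
    pool <- metadata$gene_id[metadata$domain_class == cl]
    if (length(pool) < spec$n_per_class) {
      abort(sprintf(
        "class '%s' has only %d gene(s); cannot sample %d per class",
        cl, length(pool), spec$n_per_class))
    }
    if (length(pool) == spec$n_per_class) return(pool)
    with_seed(subsample_seed(spec, replicate_index, cl),
              sample(pool, spec$n_per_class))
  })
  sort(unlist(picks))
}

#' Re-analyse the network induced by a gene subset
#'
#' Takes the node-induced subgraph (edges with both endpoints sampled
#' survive, footprints unchanged), re-runs composite detection and
#' classification on it, and tabulates class counts. With an all-vs-all
#' hit table the induced subgraph is exactly what a fresh analysis of the
#' subset would see.
#'
#' @param ssn Full `fusenet_ssn`.
#' @param subset Character vector of gene ids.
#' @param metadata Metadata tibble.
#' @param params [detection_params()].
#' @return Tibble `domain_class`, `gene_class`, `n` (all combinations
#'   present in the subset, zero-filled over the four gene classes).
#' @export
induce_and_detect <- function(ssn, subset, metadata,
                              params = detection_params()) {
  sub <- induce_ssn(ssn, subset)
  det <- detect_composites(sub, params)
  cls <- classify_genes(sub$nodes$gene_id, det$composites, det$components)
  cls |>
    left_join(metadata[c("gene_id", "domain_class")], by = "gene_id") |>
    count(.data$domain_class, .data$gene_class, .drop = FALSE)
}

#' Run the full resampling experiment
#'
#' @param ssn Full `fusenet_ssn`.
#' @param metadata Metadata tibble.
#' @param spec [resample_spec()].
#' @param params [detection_params()].
#' @return Long tibble of class `fusenet_resample`: `replicate`,
#'   `domain_class`, `gene_class`, `n`.
#' @export
run_resampling <- function(ssn, metadata, spec,
                           params = detection_params()) {
  stopifnot(inherits(spec, "fusenet_resample_spec"))
  md <- metadata[metadata$domain_class %in% spec$classes, ]
  reps <- lapply(seq_len(spec$replicates), function(r) {
    subset <- subsample(md, spec, r)
    counts <- induce_and_detect(ssn, subset, md, params)
    counts$replicate <- r
    counts
  })
  out <- relocate(bind_rows(reps), "replicate")
  class(out) <- c("fusenet_resample", class(out))
  attr(out, "spec") <- spec
  out
}

#' Summarise replicate class counts
#'
#' @param replicates Tibble from [run_resampling()] (long format).
#' @param spec The [resample_spec()] used (taken from the attribute when
#'   omitted).
#' @return List of class `fusenet_resample_summary` with `by_class`
#'   (mean/sd/min/max count per genome class and remodelling class) and
#'   `overall` (mean composite count per replicate and mean composite
#'   percentage of the sampled total).
#' @export
summarize_replicates <- function(replicates, spec = NULL) {
  spec <- spec %||% attr(replicates, "spec")
  by_class <- replicates |>
    group_by(.data$domain_class, .data$gene_class) |>
    summarise(
      mean = mean(.data$n), sd = sd(.data$n),
      min = min(.data$n), max = max(.data$n),
      .groups = "drop"
    )
  per_rep <- replicates |>
    group_by(.data$replicate) |>
    summarise(
      n_composite = sum(.data$n[.data$gene_class %in%
                                  c("nested_composite",
                                    "strict_composite")]),
      n_total = sum(.data$n),
      .groups = "drop"
    )
  overall <- tibble(
    n_replicates = nrow(per_rep),
    mean_composite_n = mean(per_rep$n_composite),
    mean_composite_pct = round_half_up(
      100 * mean(per_rep$n_composite / per_rep$n_total), 2),
    sd_composite_n = sd(per_rep$n_composite)
  )
  structure(list(by_class = by_class, overall = overall, spec = spec),
            class = "fusenet_resample_summary")
}

#' @export
print.fusenet_resample_summary <- function(x, ...) {
  ov <- x$overall
  cat(sprintf(
    "Resampling summary over %d replicate(s): mean %.1f composite genes per replicate (%.2f%% of sampled genes)\n",
    ov$n_replicates, ov$mean_composite_n, ov$mean_composite_pct))
  print(x$by_class)
  invisible(x)
}

#' @export
tidy.fusenet_resample_summary <- function(x, ...) x$by_class

#' @export
glance.fusenet_resample_summary <- function(x, ...) x$overall
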