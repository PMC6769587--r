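#' Configuration for the synthetic fusion benchmark generator
#'
#' Generates gene sets with known fusion ground truth: component families
#' of mutually homologous full-length genes, composite genes concatenating
#' segments from two unrelated families, nested composites fusing an
#' existing composite with a third family, genome-class labels, functional
#' category letters, and a matching 12-column homology hit table - so every
#' pipeline stage is testable without downloads or an aligner.
#'
#' Default class allocations and per-class fusion probabilities emulate the
#' relative composite rates observed across the three cellular domains and
#' the two mobile-element classes in large-scale surveys (eukaryotes
#' highest at roughly 23%, bacteria and plasmids near 15%, archaea near
#' 13%, viruses lowest near 5%), at a desk-scale total of 8,500 genes.
#'
#' @param n_genes_per_class Named integer vector (names from
#'   [domain_classes()]): genes generated per class.
#' @param fusion_prob Named numeric vector: per-class probability that a
#'   gene is generated as a composite. The generating eukaryote-vs-
#'   prokaryote odds ratio is determined by these values (see
#'   [generating_odds_ratio()]).
#' @param n_families Number of component families the non-composite genes
#'   are spread over (family sizes emerge from uniform assignment). The
#'   default gives a mean family size near 3.5, in line with the family
#'   granularity of large protein similarity networks; families never
#'   drawn by a composite supply the non-remodelled gene pool.
#' @param gene_length_mean,gene_length_sd,gene_length_min Archetype length
#'   distribution (amino acids); lengths are normal draws rounded and
#'   clipped from below.
#' @param nested_fraction Probability that a composite is built by fusing
#'   an existing composite with a third family (nested composite) rather
#'   than two plain families.
#' @param segment_min Minimum contributed segment length. The default 41 =
#'   minimum alignment length (20) + allowed component overlap (20) + 1
#'   guarantees each segment is long enough to survive hit filtering and to
#'   keep abutting footprints within the overlap tolerance.
#' @param genomes_per_class Genomes each class's genes are spread over.
#' @param annotation_rate Fraction of genes carrying a category annotation.
#' @param category_alphabet Category letters to draw from (default: the 24
#'   COG letters A-Z without R and X).
#' @param category_count_probs Probabilities of a gene carrying 1, 2, 3,
#'   ... letters.
#' @param footprint_jitter Noise: alignment endpoints shifted by a uniform
#'   integer in `[-jitter, jitter]` residues.
#' @param spurious_edge_rate Expected spurious (non-homologous) hits per
#'   gene.
#' @param dropout_rate Probability that a true hit is dropped.
#' @param substitution_rate Per-residue substitution rate for FASTA
#'   emission (no indels, keeping coordinates exact).
#' @param rng_seed Master seed; all generator stages derive from it.
#' @return List of class `fusenet_genconfig`.
#' @export
generator_config <- function(
    n_genes_per_class = c(eukaryote = 2000, bacteria = 2000,
                          archaea = 2000, plasmid = 2000, virus = 500),
    fusion_prob = c(eukaryote = 0.2266, bacteria = 0.1476,
                    archaea = 0.1278, plasmid = 0.1469, virus = 0.0482),
    n_families = 2000,
    gene_length_mean = 350, gene_length_sd = 75, gene_length_min = 120,
    nested_fraction = 0.25,
    segment_min = 41,
    genomes_per_class = 5,
    annotation_rate = 0.9,
    category_alphabet = setdiff(LETTERS, c("R", "X")),
    category_count_probs = c(0.7, 0.2, 0.1),
    footprint_jitter = 0,
    spurious_edge_rate = 0,
    dropout_rate = 0,
    substitution_rate = 0.05,
    rng_seed = 1) {
  stopifnot(
    all(names(n_genes_per_class) %in% domain_classes()),
    all(n_genes_per_class >= 0),
    all(names(n_genes_per_class) %in% names(fusion_prob)),
    all(fusion_prob >= 0 & fusion_prob <= 1),
    n_families >= 2,
    gene_length_min >= 2 * segment_min,
    nested_fraction >= 0, nested_fraction <= 1,
    segment_min >= 1,
    annotation_rate >= 0, annotation_rate <= 1,
    footprint_jitter >= 0, spurious_edge_rate >= 0,
    dropout_rate >= 0, dropout_rate <= 1,
    abs(sum(category_count_probs) - 1) < 1e-8
  )
  structure(
    list(
      n_genes_per_class = n_genes_per_class,
      fusion_prob = fusion_prob[names(n_genes_per_class)],
      n_families = as.integer(n_families),
      gene_length_mean = gene_length_mean,
      gene_length_sd = gene_length_sd,
      gene_length_min = gene_length_min,
      nested_fraction = nested_fraction,
      segment_min = as.integer(segment_min),
      genomes_per_class = as.integer(genomes_per_class),
      annotation_rate = annotation_rate,
      category_alphabet = category_alphabet,
      category_count_probs = category_count_probs,
      footprint_jitter = footprint_jitter,
      spurious_edge_rate = spurious_edge_rate,
      dropout_rate = dropout_rate,
      substitution_rate = substitution_rate,
      rng_seed = as.integer(rng_seed)
    ),
    class = "fusenet_genconfig"
  )
}

#' Odds ratio implied by the configured fusion probabilities
#'
#' The eukaryote-vs-prokaryote odds ratio the generator engineers:
#' `(p_e / (1 - p_e)) / (p_p / (1 - p_p))`, where `p_p` is the gene-count-
#' weighted prokaryote (archaea + bacteria) fusion probability.
#'
#' @param config [generator_config()].
#' @return The generating odds ratio.
#' @export
generating_odds_ratio <- function(config) {
  p_e <- config$fusion_prob[["eukaryote"]]
  prok <- intersect(c("archaea", "bacteria"),
                    names(config$n_genes_per_class))
  w <- config$n_genes_per_class[prok]
  p_p <- sum(config$fusion_prob[prok] * w) / sum(w)
  (p_e / (1 - p_e)) / (p_p / (1 - p_p))
}

#' Generate the component-family backbone
#'
#' Draws every gene with its genome-class label and composite flag, builds
#' component families from the non-composite genes (full-length mutual
#' homologs sharing a family archetype length), and leaves composites as
#' placeholders for [generate_composites()].
#'
#' @param config [generator_config()].
#' @return List with `genes` (tibble: `gene_id`, `genome_id`,
#'   `domain_class`, `is_composite`, `family_id`, `length`), `families`
#'   (tibble: `family_id`, `archetype_length`) and `config`.
#' @export
generate_components <- function(config) {
  stopifnot(inherits(config, "fusenet_genconfig"))
  with_seed(config$rng_seed, {
    classes <- names(config$n_genes_per_class)
    genes <- list_rbind(map(classes, function(cl) {
      n <- config$n_genes_per_class[[cl]]
      if (n == 0) return(NULL)
      tibble(
        gene_id = sprintf("%s_%05d", cl, seq_len(n)),
        genome_id = sprintf("%s_genome%d", cl,
                            sample.int(config$genomes_per_class, n,
                                       replace = TRUE)),
        domain_class = cl,
        is_composite = runif(n) < config$fusion_prob[[cl]]
      )
    }))
    families <- tibble(
      family_id = sprintf("FAM%04d", seq_len(config$n_families)),
      archetype_length = pmax(
        config$gene_length_min,
        round(stats::rnorm(config$n_families, config$gene_length_mean,
                           config$gene_length_sd))
      )
    )
    genes$family_id <- NA_character_
    n_nc <- sum(!genes$is_composite)
    genes$family_id[!genes$is_composite] <-
      families$family_id[sample.int(config$n_families, n_nc,
                                    replace = TRUE)]
    genes$length <- NA_real_
    genes$length[!genes$is_composite] <-
      families$archetype_length[match(genes$family_id[!genes$is_composite],
                                      families$family_id)]
    list(genes = genes, families = families, config = config)
  })
}

#' Build composite genes over a component backbone
#'
#' Each plain composite concatenates a segment from each of two distinct
#' component families, tiling the gene without overlap. Segment lengths are
#' at least `segment_min` and at most three times each other, so no single
#' segment reaches the 80% mutual-coverage threshold that would merge the
#' composite into a component family. A nested composite fuses one
#' previously built composite (kept full length) with a segment from a
#' family the parent composite has no homology link to. Ground-truth
#' classes follow the same set algebra as the detector: composites are the
#' generated composite genes, components are all members of every family
#' used by a composite plus composites reused as fusion partners, and
#' nested = composite intersect component.
#'
#' @param components Output of [generate_components()].
#' @return List of class `fusenet_sim` (without hits/annotations yet):
#'   `genes`, `families`, `provenance` (tibble: `composite`,
#'   `segment_index`, `source_type` family/composite, `source_id`,
#'   `comp_start`, `comp_end`, `seg_len`), `truth` (tibble: `gene_id`,
#'   `true_class`), `config`.
#' @export
generate_composites <- function(components) {
  config <- components$config
  genes <- components$genes
  families <- components$families
  fam_len <- setNames(families$archetype_length, families$family_id)
  member_counts <- table(genes$family_id[!genes$is_composite])
  populated <- names(member_counts)
  if (length(populated) < 2 && any(genes$is_composite)) {
    abort("need at least two populated component families to build composites")
  }

  comp_ids <- sort(genes$gene_id[genes$is_composite])
  gene_len <- setNames(genes$length, genes$gene_id)
  linked <- list()       # composite -> families it has direct hits to
  used_as_component <- character(0)
  used_families <- character(0)
  prov <- vector("list", length(comp_ids))

  with_seed(config$rng_seed + 1L, {
    smin <- config$segment_min
    draw_seg <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)
    for (i in seq_along(comp_ids)) {
      cid <- comp_ids[i]
      built <- FALSE
      prior <- comp_ids[seq_len(i - 1)][!is.na(gene_len[comp_ids[seq_len(i - 1)]])]
      if (length(prior) > 0 && runif(1) < config$nested_fraction) {
        parent <- sample(prior, 1)
        l_a <- gene_len[[parent]]
        lo_e <- max(smin, floor(l_a / 4) + 1)
        cand <- setdiff(populated, linked[[parent]])
        cand <- cand[fam_len[cand] >= lo_e]
        if (length(cand) > 0) {
          fam_e <- if (length(cand) == 1) cand else sample(cand, 1)
          hi_e <- min(fam_len[[fam_e]], 4 * l_a - 1)
          k_e <- draw_seg(lo_e, hi_e)
          gene_len[[cid]] <- l_a + k_e
          prov[[i]] <- tibble(
            composite = cid,
            segment_index = 1:2,
            source_type = c("composite", "family"),
            source_id = c(parent, fam_e),
            comp_start = c(1, l_a + 1),
            comp_end = c(l_a, l_a + k_e),
            seg_len = c(l_a, k_e)
          )
          linked[[cid]] <- fam_e
          used_as_component <- c(used_as_component, parent)
          used_families <- c(used_families, fam_e)
          built <- TRUE
        }
      }
      if (!built) {
        fams <- sample(populated, 2)
        l1 <- fam_len[[fams[1]]]
        l2 <- fam_len[[fams[2]]]
        k1 <- draw_seg(smin, l1)
        k1 <- min(k1, 3L * l2)
        k2 <- draw_seg(max(smin, ceiling(k1 / 3)), min(l2, 3L * k1))
        gene_len[[cid]] <- k1 + k2
        prov[[i]] <- tibble(
          composite = cid,
          segment_index = 1:2,
          source_type = "family",
          source_id = fams,
          comp_start = c(1, k1 + 1),
          comp_end = c(k1, k1 + k2),
          seg_len = c(k1, k2)
        )
        linked[[cid]] <- fams
        used_families <- c(used_families, fams)
      }
    }
  })

  genes$length <- as.numeric(gene_len[genes$gene_id])
  provenance <- list_rbind(prov) %||%
    tibble(composite = character(), segment_index = integer(),
           source_type = character(), source_id = character(),
           comp_start = numeric(), comp_end = numeric(),
           seg_len = numeric())

  composite_set <- comp_ids
  component_set <- sort(unique(c(
    genes$gene_id[!genes$is_composite &
                    genes$family_id %in% unique(used_families)],
    unique(used_as_component)
  )))
  truth <- classify_genes(genes$gene_id, composite_set, component_set)
  names(truth)[names(truth) == "gene_class"] <- "true_class"

  structure(
    list(genes = genes, families = families, provenance = provenance,
         truth = truth, config = config),
    class = "fusenet_sim"
  )
}

# category annotations for a simulated gene set
generate_annotations <- function(sim) {
  config <- sim$config
  with_seed(config$rng_seed + 2L, {
    genes <- sim$genes$gene_id
    annotated <- runif(length(genes)) < config$annotation_rate
    ids <- genes[annotated]
    n_letters <- sample.int(length(config$category_count_probs),
                            length(ids), replace = TRUE,
                            prob = config$category_count_probs)
    letters <- map_chr(n_letters, function(k) {
      paste(sort(sample(config$category_alphabet, k)), collapse = "")
    })
    tibble(gene_id = ids, cog_letters = letters)
  })
}

#' Emit the homology hit table for a simulated gene set
#'
#' Direct, aligner-free emission in valid 12-column BLAST tabular form:
#' full-length hits within every component family; composite-component
#' hits whose footprints on the composite equal the true provenance
#' segments (plus configured jitter) and cover the segment prefix of the
#' component archetype; a full-length link from each nested composite to
#' its parent composite; spurious hits between random pairs at the
#' configured rate; and dropout removing true hits at the configured rate.
#' Identities and E-values are drawn from ranges that pass the default
#' filters, so at zero noise detection recovers the ground truth exactly.
#'
#' @param sim A `fusenet_sim` from [generate_composites()] or
#'   [simulate_gene_set()].
#' @return Hit tibble in [read_blast_tab()] layout.
#' @export
emit_hits <- function(sim) {
  stopifnot(inherits(sim, "fusenet_sim"))
  config <- sim$config
  genes <- sim$genes
  gene_len <- setNames(genes$length, genes$gene_id)
  members_by_family <- split(genes$gene_id[!genes$is_composite],
                             genes$family_id[!genes$is_composite])

  with_seed(config$rng_seed + 7919L, {
    rows <- list()

    # within-family full-length hits (one direction per unordered pair)
    fam_rows <- list_rbind(map(names(members_by_family), function(f) {
      m <- sort(members_by_family[[f]])
      if (length(m) < 2) return(NULL)
      pr <- combn(m, 2)
      len <- gene_len[[m[1]]]
      tibble(query_id = pr[1, ], subject_id = pr[2, ],
             q_start = 1, q_end = len, s_start = 1, s_end = len,
             aln_length = len)
    }))
    if (!is.null(fam_rows) && nrow(fam_rows) > 0) {
      fam_rows$percent_identity <- round(runif(nrow(fam_rows), 85, 99), 1)
      fam_rows$evalue <- 10^runif(nrow(fam_rows), -170, -30)
      rows$family <- fam_rows
    }

    # composite -> component hits (one per composite x family member, plus
    # one per nested parent link)
    if (nrow(sim$provenance) > 0) {
      comp_rows <- list_rbind(pmap(sim$provenance, function(
          composite, segment_index, source_type, source_id,
          comp_start, comp_end, seg_len) {
        if (source_type == "family") {
          targets <- members_by_family[[source_id]]
          if (is.null(targets)) return(NULL)
          tibble(query_id = composite, subject_id = sort(targets),
                 q_start = comp_start, q_end = comp_end,
                 s_start = 1, s_end = seg_len, aln_length = seg_len)
        } else {
          tibble(query_id = composite, subject_id = source_id,
                 q_start = comp_start, q_end = comp_end,
                 s_start = 1, s_end = seg_len, aln_length = seg_len)
        }
      }))
      if (!is.null(comp_rows) && nrow(comp_rows) > 0) {
        comp_rows$percent_identity <- round(runif(nrow(comp_rows), 40, 90), 1)
        comp_rows$evalue <- 10^runif(nrow(comp_rows), -120, -15)
        if (config$footprint_jitter > 0) {
          j <- config$footprint_jitter
          n <- nrow(comp_rows)
          jit <- function(x) x + sample(seq(-j, j), n, replace = TRUE)
          ql <- gene_len[comp_rows$query_id]
          sl <- gene_len[comp_rows$subject_id]
          comp_rows$q_start <- pmax(1, pmin(jit(comp_rows$q_start), ql))
          comp_rows$q_end <- pmax(comp_rows$q_start,
                                  pmin(jit(comp_rows$q_end), ql))
          comp_rows$s_start <- pmax(1, pmin(jit(comp_rows$s_start), sl))
          comp_rows$s_end <- pmax(comp_rows$s_start,
                                  pmin(jit(comp_rows$s_end), sl))
          comp_rows$aln_length <- comp_rows$q_end - comp_rows$q_start + 1
        }
        rows$composite <- comp_rows
      }
    }

    true_hits <- list_rbind(rows)
    if (is.null(true_hits)) {
      true_hits <- tibble(query_id = character(), subject_id = character(),
                          q_start = numeric(), q_end = numeric(),
                          s_start = numeric(), s_end = numeric(),
                          aln_length = numeric(),
                          percent_identity = numeric(), evalue = numeric())
    }
    if (config$dropout_rate > 0 && nrow(true_hits) > 0) {
      true_hits <- true_hits[runif(nrow(true_hits)) >= config$dropout_rate, ]
    }

    # spurious hits between random pairs
    n_sp <- if (config$spurious_edge_rate > 0) {
      rpois(1, config$spurious_edge_rate * nrow(genes))
    } else 0
    if (n_sp > 0) {
      qi <- sample(genes$gene_id, n_sp, replace = TRUE)
      si <- sample(genes$gene_id, n_sp, replace = TRUE)
      keep <- qi != si
      qi <- qi[keep]; si <- si[keep]
      if (length(qi) > 0) {
        span <- sample(30:120, length(qi), replace = TRUE)
        ql <- gene_len[qi]; sl <- gene_len[si]
        span_q <- pmin(span, ql); span_s <- pmin(span, sl)
        qs <- map_dbl(ql - span_q + 1, ~ sample.int(.x, 1))
        ss <- map_dbl(sl - span_s + 1, ~ sample.int(.x, 1))
        sp_rows <- tibble(
          query_id = qi, subject_id = si,
          q_start = qs, q_end = qs + span_q - 1,
          s_start = ss, s_end = ss + span_s - 1,
          aln_length = span_q,
          percent_identity = round(runif(length(qi), 30, 60), 1),
          evalue = 10^runif(length(qi), -30, -6)
        )
        true_hits <- bind_rows(true_hits, sp_rows)
      }
    }

    hits <- true_hits
    hits$mismatches <- round(hits$aln_length *
                               (1 - hits$percent_identity / 100))
    hits$gap_opens <- 0
    hits$bitscore <- round(hits$aln_length * 1.9, 1)
    hits$self_hit <- FALSE
    hits[c(blast_columns(), "self_hit")]
  })
}

#' Generate a complete synthetic dataset with known fusion ground truth
#'
#' Convenience wrapper: [generate_components()], [generate_composites()],
#' category annotations and [emit_hits()], all derived deterministically
#' from the config's seed.
#'
#' @param config [generator_config()].
#' @return A `fusenet_sim` with elements `genes`, `families`,
#'   `provenance`, `truth`, `annotations`, `hits`, `config`.
#' @export
simulate_gene_set <- function(config = generator_config()) {
  sim <- generate_composites(generate_components(config))
  sim$annotations <- generate_annotations(sim)
  sim$hits <- emit_hits(sim)
  sim
}

#' @export
print.fusenet_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic gene set: %d genes (%d composite in truth), %d families",
    nrow(x$genes), sum(x$genes$is_composite), x$config$n_families))
  if (!is.null(x$hits)) cat(sprintf(", %d hits", nrow(x$hits)))
  cat("\n")
  invisible(x)
}

#' Metadata table of a simulated gene set
#'
#' @param sim A `fusenet_sim`.
#' @return Tibble `gene_id`, `genome_id`, `domain_class` as produced by
#'   [read_metadata()].
#' @export
sim_metadata <- function(sim) {
  sim$genes[c("gene_id", "genome_id", "domain_class")]
}

#' Score predicted remodelling classes against ground truth
#'
#' Composite-detection precision and recall (composite = nested or strict
#' composite) plus the full 4x4 confusion matrix.
#'
#' @param predicted Tibble `gene_id`, `gene_class` from
#'   [classify_genes()].
#' @param truth Tibble `gene_id`, `true_class` (e.g. `sim$truth`).
#' @return List of class `fusenet_recovery`: `precision`, `recall`,
#'   `confusion` (truth in rows, prediction in columns), `n_genes`.
#' @export
score_recovery <- function(predicted, truth) {
  if (!setequal(predicted$gene_id, truth$gene_id)) {
    abort("predicted and truth gene sets differ")
  }
  j <- inner_join(truth, predicted, by = "gene_id")
  comp_lvls <- c("nested_composite", "strict_composite")
  true_pos <- j$true_class %in% comp_lvls & j$gene_class %in% comp_lvls
  n_pred <- sum(j$gene_class %in% comp_lvls)
  n_true <- sum(j$true_class %in% comp_lvls)
  confusion <- table(
    truth = factor(j$true_class, levels = gene_classes()),
    predicted = factor(j$gene_class, levels = gene_classes())
  )
  structure(
    list(
      precision = if (n_pred > 0) sum(true_pos) / n_pred else NA_real_,
      recall = if (n_true > 0) sum(true_pos) / n_true else NA_real_,
      confusion = confusion,
      n_genes = nrow(j)
    ),
    class = "fusenet_recovery"
  )
}

#' @export
print.fusenet_recovery <- function(x, ...) {
  cat(sprintf(
    "Composite recovery on %d genes: precision %.3f, recall %.3f\n",
    x$n_genes, x$precision, x$recall))
  print(x$confusion)
  invisible(x)
}

#' Write a synthetic dataset to disk in pipeline-ready formats
#'
#' Emits `hits.tsv` (12-column BLAST tabular), `metadata.tsv`,
#' `annotations.tsv` (emapper-style, `#`-prefixed header), `truth.tsv`,
#' and optionally `genes.fasta` with per-family archetype sequences
#' mutated per gene (synthetic sequences; no indels, so coordinates stay
#' exact). All files are consumable unchanged by the corresponding
#' readers.
#'
#' @param sim A `fusenet_sim` from [simulate_gene_set()].
#' @param dir Output directory (created if needed).
#' @param fasta Also write sequences (requires the Biostrings package).
#' @return Named vector of file paths, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir, fasta = FALSE) {
  stopifnot(inherits(sim, "fusenet_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(
    hits = file.path(dir, "hits.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_blast_tab(sim$hits, files[["hits"]])
  readr::write_tsv(sim_metadata(sim), files[["metadata"]],
                   progress = FALSE)
  readr::write_lines("#query\tCOG_category", files[["annotations"]])
  readr::write_tsv(sim$annotations, files[["annotations"]], append = TRUE,
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(sim$truth, files[["truth"]], progress = FALSE)
  if (fasta) {
    files[["fasta"]] <- file.path(dir, "genes.fasta")
    write_synthetic_fasta(sim, files[["fasta"]])
  }
  invisible(files)
}

# synthetic amino-acid sequences: a random archetype per family, per-gene
# substitutions, composite sequences concatenated from source prefixes
write_synthetic_fasta <- function(sim, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("FASTA emission requires the Biostrings package")
  }
  config <- sim$config
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(config$rng_seed + 5L, {
    arch <- map(setNames(sim$families$archetype_length,
                         sim$families$family_id),
                ~ sample(aa, .x, replace = TRUE))
    mutate_seq <- function(s) {
      flip <- runif(length(s)) < config$substitution_rate
      s[flip] <- sample(aa, sum(flip), replace = TRUE)
      s
    }
    comp_seq <- new.env(parent = emptyenv())
    build_composite <- function(cid) {
      if (!is.null(comp_seq[[cid]])) return(comp_seq[[cid]])
      segs <- sim$provenance[sim$provenance$composite == cid, ]
      parts <- pmap(segs, function(composite, segment_index, source_type,
                                   source_id, comp_start, comp_end,
                                   seg_len) {
        if (source_type == "family") {
          mutate_seq(arch[[source_id]][seq_len(seg_len)])
        } else {
          build_composite(source_id)[seq_len(seg_len)]
        }
      })
      comp_seq[[cid]] <- unlist(parts)
      comp_seq[[cid]]
    }
    seqs <- map_chr(seq_len(nrow(sim$genes)), function(i) {
      g <- sim$genes[i, ]
      if (g$is_composite) {
        paste(build_composite(g$gene_id), collapse = "")
      } else {
        paste(mutate_seq(arch[[g$family_id]]), collapse = "")
      }
    })
  })
  set <- Biostrings::AAStringSet(setNames(seqs, sim$genes$gene_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
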