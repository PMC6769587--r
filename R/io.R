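blast_columns <- function() {
  c("query_id", "subject_id", "percent_identity", "aln_length",
    "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
    "evalue", "bitscore")
}

#' Read an all-vs-all homology hit table (BLAST tabular, 12 columns)
#'
#' Parses standard `-outfmt 6` output (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Coordinates are kept
#' 1-based and inclusive exactly as BLAST reports them. Self-hits
#' (query equal to subject) are returned but flagged in the `self_hit`
#' column; they never become network edges downstream. Reverse-orientation
#' coordinates (start greater than end) are rejected: inputs are proteins.
#'
#' @param path Path to a tab-separated 12-column hit table without header.
#' @return A tibble with one row per hit: `query_id`, `subject_id`,
#'   `percent_identity`, `aln_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`, `self_hit`.
#'   An empty file yields an empty tibble with these columns.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) abort(paste0("hit table not found: ", path))
  empty <- as_tibble(setNames(
    c(replicate(2, character(), simplify = FALSE),
      replicate(10, numeric(), simplify = FALSE)),
    blast_columns()
  ))
  empty$self_hit <- logical()
  if (file.size(path) == 0) return(empty)

  hits <- readr::read_tsv(
    path,
    col_names = blast_columns(),
    col_types = readr::cols(
      query_id = readr::col_character(),
      subject_id = readr::col_character(),
      percent_identity = readr::col_double(),
      aln_length = readr::col_double(),
      mismatches = readr::col_double(),
      gap_opens = readr::col_double(),
      q_start = readr::col_double(),
      q_end = readr::col_double(),
      s_start = readr::col_double(),
      s_end = readr::col_double(),
      evalue = readr::col_double(),
      bitscore = readr::col_double()
    ),
    progress = FALSE
  )
  probs <- readr::problems(hits)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "malformed hit table %s: %d problem(s), first at line %d (%s)",
      path, nrow(probs), probs$row[1], probs$expected[1]
    ))
  }
  num_cols <- c("percent_identity", "q_start", "q_end", "s_start", "s_end",
                "evalue")
  bad_na <- which(Reduce(`|`, lapply(hits[num_cols], is.na)))
  if (length(bad_na) > 0) {
    abort(sprintf("non-numeric or missing field(s) at line(s) %s of %s",
                  paste(head(bad_na, 5), collapse = ", "), path))
  }
  bad_rev <- which(hits$q_start > hits$q_end | hits$s_start > hits$s_end)
  if (length(bad_rev) > 0) {
    abort(sprintf(
      "reverse-orientation coordinates (start > end) at line(s) %s of %s; protein alignments must have start <= end",
      paste(head(bad_rev, 5), collapse = ", "), path))
  }
  bad_low <- which(hits$q_start < 1 | hits$s_start < 1)
  if (length(bad_low) > 0) {
    abort(sprintf("coordinates below 1 at line(s) %s of %s",
                  paste(head(bad_low, 5), collapse = ", "), path))
  }
  hits$self_hit <- hits$query_id == hits$subject_id
  hits
}

#' Write a hit table in 12-column BLAST tabular layout
#'
#' Inverse of [read_blast_tab()]; numeric fields are written with
#' shortest-round-trip formatting so that parsing the file back reproduces
#' every retained field exactly.
#'
#' @param hits Tibble as returned by [read_blast_tab()] (a `self_hit`
#'   column, if present, is dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  readr::write_tsv(hits[blast_columns()], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read gene metadata (gene, genome, genome class)
#'
#' @param path TSV with header columns `gene_id`, `genome_id`,
#'   `domain_class`. The class must be one of [domain_classes()].
#' @return Tibble with those three columns, one row per gene.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("gene_id", "genome_id", "domain_class")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  md <- md[need]
  dup <- md$gene_id[duplicated(md$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene_id in metadata: ",
                 paste(head(unique(dup), 5), collapse = ", ")))
  }
  bad <- setdiff(unique(md$domain_class), domain_classes())
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown domain_class value(s): %s. Allowed values are: %s",
      paste(bad, collapse = ", "),
      paste(domain_classes(), collapse = ", ")
    ))
  }
  md
}

#' Read emapper-style functional annotations
#'
#' Extracts one COG category letter string per gene from an annotation
#' table. Lines starting with `#` are treated as comments, except that a
#' leading `#`-prefixed header naming the columns (as eggNOG-mapper writes,
#' e.g. `#query ...`) is used for column names when `cog_column` is given by
#' name. Category letters R ("general function prediction") and X are not
#' part of the 24-category scheme used downstream; by default they are
#' dropped from the letter string with a warning. A gene whose letters are
#' all dropped, or whose category field is empty or `-`, is omitted and
#' treated as unannotated downstream.
#'
#' @param path Annotation TSV.
#' @param cog_column Column holding the COG letter string: a column name
#'   (requires a header line) or a 1-based column index.
#' @param gene_column Column holding the gene id (name or index).
#' @param on_excluded What to do when R or X is encountered: `"warn"`
#'   (drop the letter, warn once), `"keep"`, or `"error"`.
#' @return Tibble with columns `gene_id`, `cog_letters`.
#' @export
read_annotations <- function(path, cog_column = "COG_category",
                             gene_column = "query",
                             on_excluded = c("warn", "keep", "error")) {
  on_excluded <- arg_match(on_excluded)
  lines <- readr::read_lines(path, progress = FALSE)
  is_comment <- startsWith(lines, "#")
  header <- NULL
  if (any(is_comment)) {
    hdr_candidates <- lines[is_comment]
    header <- sub("^#", "", hdr_candidates[length(hdr_candidates)])
  }
  data_lines <- lines[!is_comment & nzchar(lines)]
  by_name <- is.character(cog_column)
  if (by_name) {
    if (!is_comment[1] && length(lines) > 0) {
      # plain header line, not #-prefixed
      header <- data_lines[1]
      data_lines <- data_lines[-1]
    }
    if (is.null(header)) {
      abort("cog_column given by name but the file has no header line")
    }
    txt <- paste(c(header, data_lines), collapse = "\n")
    tab <- readr::read_tsv(I(txt), col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    for (col in c(gene_column, cog_column)) {
      if (!col %in% names(tab)) {
        abort(paste0("annotation column not found: ", col))
      }
    }
    ann <- tibble(gene_id = tab[[gene_column]],
                  cog_letters = tab[[cog_column]])
  } else {
    txt <- paste(data_lines, collapse = "\n")
    tab <- readr::read_tsv(I(txt), col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    ann <- tibble(gene_id = tab[[gene_column]],
                  cog_letters = tab[[cog_column]])
  }
  ann <- ann[!is.na(ann$cog_letters) & ann$cog_letters != "" &
               ann$cog_letters != "-", ]
  letters_ok <- grepl("^[A-Z]+$", ann$cog_letters)
  if (any(!letters_ok)) {
    abort(sprintf(
      "invalid COG category string(s): %s (letters A-Z expected)",
      paste(head(unique(ann$cog_letters[!letters_ok]), 5), collapse = ", ")))
  }
  has_dup <- vapply(strsplit(ann$cog_letters, ""), anyDuplicated,
                    integer(1)) > 0
  if (any(has_dup)) {
    abort(sprintf("duplicated letters within a category string: %s",
                  paste(head(ann$cog_letters[has_dup], 5), collapse = ", ")))
  }
  has_excluded <- grepl("[RX]", ann$cog_letters)
  if (any(has_excluded)) {
    if (on_excluded == "error") {
      abort("categories R/X encountered; they are outside the 24-category scheme")
    }
    if (on_excluded == "warn") {
      warn(sprintf(
        "%d annotation(s) contained category R or X; those letters were dropped",
        sum(has_excluded)))
      ann$cog_letters <- gsub("[RX]", "", ann$cog_letters)
      ann <- ann[nzchar(ann$cog_letters), ]
    }
  }
  ann
}

#' Export a sequence similarity network to GraphML and CSV
#'
#' Writes `path.graphml` plus a `path.nodes.csv` / `path.edges.csv` pair
#' loadable by common graph GUIs. Node attributes carry `domain_class` and,
#' when supplied, the remodelling class and family assignment.
#'
#' @param ssn A network built by [build_ssn()].
#' @param path Output path prefix (extensions are appended).
#' @param classification Optional tibble (`gene_id`, `gene_class`).
#' @param families Optional tibble (`gene_id`, `family_id`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_network <- function(ssn, path, classification = NULL,
                          families = NULL) {
  stopifnot(inherits(ssn, "fusenet_ssn"))
  nodes <- ssn$nodes
  if (!is.null(classification)) {
    nodes <- left_join(nodes, classification[c("gene_id", "gene_class")],
                       by = "gene_id")
  }
  if (!is.null(families)) {
    nodes <- left_join(nodes, families[c("gene_id", "family_id")],
                       by = "gene_id")
  }
  edges <- ssn$edges
  edge_df <- tibble(
    source = edges$gene1, target = edges$gene2,
    best_identity = edges$best_identity, best_evalue = edges$best_evalue
  )
  g <- igraph::graph_from_data_frame(
    edge_df, directed = FALSE,
    vertices = as.data.frame(nodes)
  )
  files <- c(
    graphml = paste0(path, ".graphml"),
    nodes = paste0(path, ".nodes.csv"),
    edges = paste0(path, ".edges.csv")
  )
  igraph::write_graph(g, files[["graphml"]], format = "graphml")
  readr::write_csv(nodes, files[["nodes"]], progress = FALSE)
  readr::write_csv(edge_df, files[["edges"]], progress = FALSE)
  invisible(files)
}

#' Read back a network exported by [write_network()]
#'
#' Parses the CSV pair; intended for round-trip checks and lightweight
#' re-loading of node/edge sets (footprints are not serialised).
#'
#' @param path The path prefix used when writing.
#' @return List with tibbles `nodes` and `edges`.
#' @export
read_network <- function(path) {
  list(
    nodes = readr::read_csv(paste0(path, ".nodes.csv"),
                            col_types = readr::cols(), progress = FALSE),
    edges = readr::read_csv(paste0(path, ".edges.csv"),
                            col_types = readr::cols(), progress = FALSE)
  )
}

#' Genes referenced by hits but absent from the metadata
#'
#' The pipeline never silently drops named genes: any gene id appearing in a
#' hit table without a metadata row is reported here.
#'
#' @param hits Hit tibble.
#' @param metadata Metadata tibble.
#' @return Character vector (possibly empty) of gene ids lacking metadata.
#' @export
missing_metadata <- function(hits, metadata) {
  sort(setdiff(unique(c(hits$query_id, hits$subject_id)),
               metadata$gene_id))
}
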