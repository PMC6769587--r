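#' Detection parameters for composite-gene identification
#'
#' Bundles the thresholds applied when filtering homology hits, building the
#' sequence similarity network (SSN), assigning families and certifying
#' non-transitive triplets.
#'
#' @param max_evalue Maximum BLAST E-value for a hit to be retained.
#' @param min_identity Minimum percent identity (0-100) for a hit.
#' @param min_alignment_length Minimum alignment length on the query, in
#'   residues.
#' @param max_component_overlap Maximum number of residues the footprints of
#'   two components may share on a composite candidate. The default of 20
#'   residues tolerates short overlaps between otherwise disjoint component
#'   alignments, limiting false-negative composite calls.
#' @param family_min_coverage Fraction (0-1) of BOTH genes' lengths that an
#'   edge's merged footprint must cover for the edge to count towards family
#'   assignment.
#'
#' @return A list of class `fusenet_params`.
#' @export
#' @examples
#' detection_params()
#' detection_params(min_identity = 40)
detection_params <- function(max_evalue = 1e-5,
                             min_identity = 30,
                             min_alignment_length = 20,
                             max_component_overlap = 20,
                             family_min_coverage = 0.8) {
  stopifnot(
    is.numeric(max_evalue), length(max_evalue) == 1, max_evalue >= 0,
    is.numeric(min_identity), length(min_identity) == 1,
    min_identity >= 0, min_identity <= 100,
    is.numeric(min_alignment_length), min_alignment_length >= 0,
    is.numeric(max_component_overlap), max_component_overlap >= 0,
    is.numeric(family_min_coverage),
    family_min_coverage >= 0, family_min_coverage <= 1
  )
  structure(
    list(
      max_evalue = max_evalue,
      min_identity = min_identity,
      min_alignment_length = min_alignment_length,
      max_component_overlap = max_component_overlap,
      family_min_coverage = family_min_coverage
    ),
    class = "fusenet_params"
  )
}

#' @export
print.fusenet_params <- function(x, ...) {
  cat("Composite detection parameters\n")
  cat(sprintf("  max E-value:            %g\n", x$max_evalue))
  cat(sprintf("  min identity:           %g%%\n", x$min_identity))
  cat(sprintf("  min alignment length:   %g aa\n", x$min_alignment_length))
  cat(sprintf("  max component overlap:  %g aa\n", x$max_component_overlap))
  cat(sprintf("  family min coverage:    %g\n", x$family_min_coverage))
  invisible(x)
}

#' Overlap between two closed residue intervals
#'
#' Intervals are 1-based and inclusive on both ends, matching BLAST tabular
#' coordinates, so `[10, 20]` vs `[10, 20]` overlap by 11 residues.
#'
#' @param i1,i2 Numeric vectors of length 2, `c(start, end)`.
#' @return Number of shared residues (0 if disjoint).
#' @export
#' @examples
#' interval_overlap(c(1, 100), c(90, 150)) # 11
#' interval_overlap(c(1, 50), c(60, 100))  # 0
interval_overlap <- function(i1, i2) {
  stopifnot(length(i1) == 2, length(i2) == 2, i1[1] <= i1[2], i2[1] <= i2[2])
  overlap_len(i1[1], i1[2], i2[1], i2[2])
}

# vectorised inclusive-interval overlap
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

# merge a set of 1-based inclusive intervals into a disjoint sorted union;
# m is a 2-column matrix (start, end)
merge_intervals <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 2)
  if (nrow(m) <= 1) return(m)
  o <- order(m[, 1], m[, 2])
  m <- m[o, , drop = FALSE]
  out_s <- m[1, 1]
  out_e <- m[1, 2]
  res <- list()
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out_e + 1) {          # adjacent residues merge too
      out_e <- max(out_e, m[i, 2])
    } else {
      res[[length(res) + 1]] <- c(out_s, out_e)
      out_s <- m[i, 1]
      out_e <- m[i, 2]
    }
  }
  res[[length(res) + 1]] <- c(out_s, out_e)
  do.call(rbind, res)
}

# total residues covered by a merged interval matrix
covered_length <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(0L)
  sum(m[, 2] - m[, 1] + 1)
}

# round half away from zero, as used for reported percentages
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
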