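#' Expand multi-letter category annotations into gene-category incidence
#'
#' A gene annotated "ABC" is counted once in each of A, B and C; categories
#' are not de-duplicated across genes and no gene-level collapsing is done.
#' Unannotated genes contribute to no category.
#'
#' @param annotations Tibble `gene_id`, `cog_letters`
#'   (see [read_annotations()]).
#' @return Tibble `gene_id`, `category`, one row per (gene, letter).
#' @export
#' @examples
#' expand_categories(tibble::tibble(gene_id = "g1", cog_letters = "ABC"))
expand_categories <- function(annotations) {
  annotations |>
    mutate(category = strsplit(.data$cog_letters, "")) |>
    select("gene_id", "category") |>
    unnest("category") |>
    arrange(.data$gene_id, .data$category)
}

#' Build the 2x2 composite-by-origin contingency table for one category
#'
#' Cell definitions: `a` composite eukaryote genes, `b` non-composite
#' eukaryote genes, `c` composite prokaryote genes, `d` non-composite
#' prokaryote genes, restricted to genes carrying the category. Composite
#' means nested or strict composite; prokaryote means archaea or bacteria;
#' viruses and plasmids are excluded.
#'
#' @param category Single COG letter.
#' @param classification Tibble from [classify_genes()].
#' @param metadata Metadata tibble.
#' @param incidence Tibble from [expand_categories()].
#' @return One-row tibble `category`, `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(category, classification, metadata,
                              incidence) {
  tab <- contingency_all(classification, metadata, incidence)
  out <- tab[tab$category == category, ]
  if (nrow(out) == 0) {
    out <- tibble(category = category, a = 0L, b = 0L, c = 0L, d = 0L)
  }
  out
}

# all-category contingency tables in one pass
contingency_all <- function(classification, metadata, incidence) {
  base <- classification |>
    inner_join(metadata[c("gene_id", "domain_class")], by = "gene_id") |>
    filter(.data$domain_class %in% c("eukaryote", "archaea", "bacteria")) |>
    mutate(
      origin = if_else(.data$domain_class == "eukaryote",
                       "eukaryote", "prokaryote"),
      composite = .data$gene_class %in% c("nested_composite",
                                          "strict_composite")
    ) |>
    inner_join(incidence, by = "gene_id",
               relationship = "many-to-many")
  base |>
    count(.data$category, .data$origin, .data$composite) |>
    mutate(cell = dplyr::case_when(
      .data$origin == "eukaryote" & .data$composite ~ "a",
      .data$origin == "eukaryote" & !.data$composite ~ "b",
      .data$origin == "prokaryote" & .data$composite ~ "c",
      .data$origin == "prokaryote" & !.data$composite ~ "d"
    )) |>
    select("category", "cell", "n") |>
    pivot_wider(names_from = "cell", values_from = "n", values_fill = 0L) |>
    (\(x) {
      for (cl in c("a", "b", "c", "d")) if (!cl %in% names(x)) x[[cl]] <- 0L
      x
    })() |>
    select("category", "a", "b", "c", "d") |>
    arrange(.data$category)
}

#' Odds ratio of a 2x2 table
#'
#' `OR = (a * d) / (b * c)`: the odds of being composite for a eukaryote
#' gene relative to a prokaryote gene. Any zero cell makes the ratio (and
#' its log-scale standard error) undefined; such tables are skipped rather
#' than continuity-corrected, matching the treatment of categories with no
#' prokaryote composite at all.
#'
#' @param a,b,c,d Non-negative counts (vectorised).
#' @return The odds ratio, or `NA` where any cell is zero.
#' @export
#' @examples
#' odds_ratio(20, 80, 10, 90) # 2.25
odds_ratio <- function(a, b, c, d) {
  ifelse(a > 0 & b > 0 & c > 0 & d > 0, (a * d) / (b * c), NA_real_)
}

#' Woolf confidence interval for an odds ratio
#'
#' `exp(ln(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`: the asymptotic
#' log-scale interval with the Woolf standard error. All cells must be
#' positive; zero-cell tables are skipped upstream.
#'
#' @param a,b,c,d Positive counts (vectorised).
#' @param z Standard-normal quantile (1.96 for an uncorrected 95%
#'   interval; see [bonferroni_z()] for the corrected quantile).
#' @return Tibble `ci_low`, `ci_high` (NA where any cell is zero).
#' @export
or_confidence_interval <- function(a, b, c, d, z = 1.96) {
  stopifnot(z > 0)
  or <- odds_ratio(a, b, c, d)
  se <- ifelse(is.na(or), NA_real_, sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  tibble(
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se)
  )
}

#' Bonferroni-style corrected significance level and CI quantile
#'
#' The familywise level `alpha` is divided over the two tails of `n_tests`
#' tests: `alpha_corrected = alpha / (2 * n_tests)`. The CI quantile is the
#' standard-normal quantile at cumulative probability
#' `1 - alpha_corrected`. Under the default `"table"` convention the
#' corrected level is first rounded to three decimals, reproducing a
#' standard-normal-table lookup: for alpha = 0.05 over 24 tests the level
#' rounds to 0.1% and the quantile is 3.09 (to two decimals). The
#' `"exact"` convention uses the unrounded level (3.08 for the same case).
#'
#' @param alpha Familywise significance level (0 < alpha < 1).
#' @param n_tests Number of tests N (>= 1).
#' @param convention `"table"` (default) or `"exact"`.
#' @return List `alpha_corrected` (unrounded), `z`.
#' @export
#' @examples
#' bonferroni_z(0.05, 24) # z ~ 3.09
#' bonferroni_z(0.05, 1)  # z ~ 1.96
bonferroni_z <- function(alpha = 0.05, n_tests = 24,
                         convention = c("table", "exact")) {
  convention <- arg_match(convention)
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  if (!is.numeric(n_tests) || n_tests < 1) {
    abort("n_tests must be a positive integer")
  }
  alpha_corrected <- alpha / (2 * n_tests)
  level <- alpha_corrected
  if (convention == "table") {
    rounded <- round(alpha_corrected, 3)
    if (rounded > 0) level <- rounded
  }
  list(alpha_corrected = alpha_corrected, z = qnorm(1 - level))
}

#' Per-category odds-ratio enrichment of composites in eukaryotes
#'
#' For every functional category present in the annotations, builds the
#' 2x2 composite-by-origin table, computes the odds ratio and its corrected
#' Woolf confidence interval, and calls a category significant when the
#' interval excludes 1. Categories with any zero cell are reported but
#' skipped (no OR), as when no prokaryote composite exists in a category.
#' By default `n_tests` is the number of non-skipped categories.
#'
#' @param classification Tibble from [classify_genes()].
#' @param metadata Metadata tibble.
#' @param annotations Tibble `gene_id`, `cog_letters`.
#' @param alpha Familywise significance level.
#' @param n_tests Override for the Bonferroni N (default: number of
#'   categories actually tested).
#' @param convention Quantile convention, see [bonferroni_z()].
#' @return Object of class `fusenet_enrichment`; use [tidy()] for the
#'   per-category table and [glance()] for the test-wide summary.
#' @export
run_enrichment <- function(classification, metadata, annotations,
                           alpha = 0.05, n_tests = NULL,
                           convention = c("table", "exact")) {
  convention <- arg_match(convention)
  incidence <- expand_categories(annotations)
  tabs <- contingency_all(classification, metadata, incidence)
  if (nrow(tabs) == 0) {
    abort("no annotated genes overlap the classified eukaryote/prokaryote gene set")
  }
  skipped <- tabs$a == 0 | tabs$b == 0 | tabs$c == 0 | tabs$d == 0
  n_tests <- n_tests %||% sum(!skipped)
  corr <- bonferroni_z(alpha, max(n_tests, 1), convention)
  or <- odds_ratio(tabs$a, tabs$b, tabs$c, tabs$d)
  ci <- or_confidence_interval(tabs$a, tabs$b, tabs$c, tabs$d, corr$z)
  results <- tabs |>
    mutate(
      or = or,
      ln_or = log(or),
      standard_error = ifelse(is.na(or), NA_real_,
                              sqrt(1 / .data$a + 1 / .data$b +
                                     1 / .data$c + 1 / .data$d)),
      ci_low = ci$ci_low,
      ci_high = ci$ci_high,
      significant = !is.na(or) & (ci$ci_low > 1 | ci$ci_high < 1),
      skipped = skipped,
      skip_reason = if_else(skipped, "zero_cell", "")
    ) |>
    arrange(.data$category)
  structure(
    list(
      results = results,
      alpha = alpha,
      alpha_corrected = corr$alpha_corrected,
      n_tests = n_tests,
      z = corr$z,
      convention = convention
    ),
    class = "fusenet_enrichment"
  )
}

#' @export
print.fusenet_enrichment <- function(x, ...) {
  cat(sprintf(
    "Odds-ratio enrichment over %d categor%s (%d tested, %d skipped)\n",
    nrow(x$results), if (nrow(x$results) == 1) "y" else "ies",
    sum(!x$results$skipped), sum(x$results$skipped)))
  cat(sprintf(
    "  alpha = %g, corrected level = %.4g, CI quantile z = %.2f\n",
    x$alpha, x$alpha_corrected, x$z))
  cat(sprintf("  %d categor%s significant (CI excludes 1)\n",
              sum(x$results$significant),
              if (sum(x$results$significant) == 1) "y" else "ies"))
  print(select(x$results, "category", "a", "b", "c", "d", "or",
               "ci_low", "ci_high", "significant", "skipped"))
  invisible(x)
}

#' @export
tidy.fusenet_enrichment <- function(x, ...) x$results

#' @export
glance.fusenet_enrichment <- function(x, ...) {
  tibble(
    n_categories = nrow(x$results),
    n_tested = sum(!x$results$skipped),
    n_skipped = sum(x$results$skipped),
    n_significant = sum(x$results$significant),
    alpha = x$alpha,
    alpha_corrected = x$alpha_corrected,
    z = x$z
  )
}

#' Write the per-category odds-ratio table
#'
#' TSV with a comment header recording the correction actually applied, so
#' a run is reconstructible from its output.
#'
#' @param enrichment `fusenet_enrichment` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  hdr <- sprintf(
    "# odds-ratio enrichment: alpha=%g n_tests=%d alpha_corrected=%.6g z=%.4f convention=%s",
    enrichment$alpha, enrichment$n_tests, enrichment$alpha_corrected,
    enrichment$z, enrichment$convention)
  readr::write_lines(hdr, path)
  readr::write_tsv(enrichment$results, path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}
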