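#' Fraction of SpliZsites shared across species
#'
#' A species-A SpliZsite enters the comparison (contributes to I) when
#' its gene has an ortholog with computable SpliZ in species B and its
#' coordinate maps uniquely through the LiftOver-style coordinate map.
#' It is shared when the mapped coordinate is itself a SpliZsite of the
#' orthologous gene in species B.
#'
#' @param sites_a,sites_b SpliZsite tables (`gene`, `chrom`, `pos`), e.g.
#'   from [spliz_sites()].
#' @param map A `coordinate_map` from species A to B.
#' @param computable_genes_b Genes with computable SpliZ in species B
#'   (species-B identifiers).
#' @param orthologs Optional two-column `data.frame` (`gene_a`,
#'   `gene_b`); identity mapping when `NULL`.
#' @return List: `n_shared`, `I` (comparable sites), `fraction`.
#' @export
shared_site_fraction <- function(sites_a, sites_b, map,
                                 computable_genes_b, orthologs = NULL) {
  gene_b <- if (is.null(orthologs)) {
    sites_a$gene
  } else {
    orthologs$gene_b[match(sites_a$gene, orthologs$gene_a)]
  }
  mapped <- map_coordinates(map, sites_a$chrom, sites_a$pos)
  comparable <- !is.na(gene_b) & gene_b %in% computable_genes_b &
    mapped$mapped
  I <- sum(comparable)
  if (I == 0) stop("no comparable SpliZsites", call. = FALSE)
  b_key <- paste(sites_b$gene, sites_b$chrom, sites_b$pos, sep = "\r")
  a_key <- paste(gene_b, mapped$chrom, mapped$pos, sep = "\r")
  n_shared <- sum(comparable & a_key %in% b_key)
  list(n_shared = n_shared, I = I, fraction = n_shared / I)
}

#' Expected shared fraction under the per-gene null
#'
#' If gene i offers N_i distinct candidate splice sites, a SpliZsite
#' placed uniformly at random among them is shared with probability
#' 1/N_i; the expected shared fraction over I compared sites is the mean
#' of 1/N_i.
#'
#' @param N Per-site counts of distinct candidate splice sites in the
#'   corresponding gene (all >= 1).
#' @export
expected_null_fraction <- function(N) {
  if (any(N < 1)) stop("all N_i must be >= 1", call. = FALSE)
  mean(1 / N)
}

#' Binomial test for SpliZsite sharing
#'
#' One-sided upper-tail exact binomial probability of observing at least
#' `n_shared` shared sites out of `I` when each is shared with the mean
#' null probability `expected_fraction`. An approximation: the true
#' per-site probabilities 1/N_i vary, but their mean drives the test.
#'
#' @param n_shared,I Observed shared count and comparison size.
#' @param expected_fraction Null success probability in (0, 1).
#' @export
conservation_binomial_test <- function(n_shared, I, expected_fraction) {
  stopifnot(expected_fraction > 0, expected_fraction < 1)
  if (n_shared > I) stop("n_shared exceeds I", call. = FALSE)
  if (n_shared == 0) return(1)
  stats::pbinom(n_shared - 1, I, expected_fraction, lower.tail = FALSE)
}

#' Enrichment of genes significant in all three species
#'
#' Under the null of no conservation, a gene is significant in all three
#' species with probability `p_all = p_human * p_lemur * p_mouse`, where
#' each `p_species` is the fraction of that species' testable genes
#' (computable SpliZ in at least 20 cells of some cell type) ever called
#' significant. The p-value for observing at least `x` triple-significant
#' genes out of `n` is computed as `1 - binom_cdf(x, n, p_all)` — the
#' strict upper tail P(X > x), exactly as printed in the source formula;
#' set `inclusive = TRUE` for P(X >= x). The variant used is recorded in
#' the output.
#'
#' @param x Observed number of genes significant in all three species.
#' @param n Total genes testable in all three species.
#' @param p_species Numeric length-3 vector of per-species significance
#'   rates.
#' @param inclusive Use the inclusive tail P(X >= x).
#' @return List of class `enrichment_result`: `p_species`, `p_all`, `n`,
#'   `x`, `p_value`, `tail`.
#' @export
three_species_enrichment <- function(x, n, p_species, inclusive = FALSE) {
  stopifnot(length(p_species) == 3, all(p_species >= 0 & p_species <= 1))
  if (x > n) stop("x exceeds n", call. = FALSE)
  p_all <- prod(p_species)
  p_value <- if (inclusive) {
    if (x == 0) 1 else
      stats::pbinom(x - 1, n, p_all, lower.tail = FALSE)
  } else {
    stats::pbinom(x, n, p_all, lower.tail = FALSE)
  }
  structure(list(p_species = p_species, p_all = p_all, n = n, x = x,
                 p_value = p_value,
                 tail = if (inclusive) "at_least_x" else "greater_than_x"),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Three-species enrichment: x = %d of n = %d, p_all = %.3g, p = %.3g (%s)\n",
    x$x, x$n, x$p_all, x$p_value, x$tail))
  invisible(x)
}

#' @rdname three_species_enrichment
#' @param n_significant,n_testable Counts defining a per-species
#'   significance rate.
#' @export
species_significance_rate <- function(n_significant, n_testable) {
  stopifnot(n_testable > 0, n_significant >= 0,
            n_significant <= n_testable)
  n_significant / n_testable
}
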