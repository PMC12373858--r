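# Hypergeometric over-representation machinery shared by pathway
# enrichment, domain-centric GO and cancer-gene-set crossover.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` containing `K` successes.  Computed through the stable
#' log-space routines underlying [stats::phyper()].
#'
#' @param k Observed successes in the draw.
#' @param K Successes in the universe (term size).
#' @param n Draw size (query size).
#' @param N Universe size.
#' @return The upper-tail probability; 1 when `k = 0`.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop("require 0 <= k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; input order
#' preserved.
#'
#' @param pvalues Numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a gene query against gene sets
#'
#' Each set is intersected with the universe before testing; sets with no
#' overlap with the query (k = 0) are excluded from testing and from the
#' BH denominator.  One hypergeometric upper-tail p-value per tested set,
#' BH-adjusted across tested sets.
#'
#' @param query Character vector of query genes (intersected with the
#'   universe).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector, the sampling universe.
#' @param alpha FDR significance threshold (default 0.05).
#' @return Data frame sorted by p: `term`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`.
#' @export
ora <- function(query, gene_sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(query, set))
    if (k == 0L) return(NULL)
    data.frame(term = nm, k = k, K = length(set), n = length(query),
               N = length(universe),
               p = hypergeom_upper(k, length(set), length(query),
                                   length(universe)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, NA)]
  if (length(rows) == 0L)
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Domain-centric term enrichment
#'
#' Identical statistics to [ora()] with protein domains as the sampling
#' unit and ontology-style terms as the sets: tests whether domains
#' impacted by alternative splicing over-represent particular functional
#' terms.
#'
#' @param impacted_domains Character vector of impacted domain names.
#' @param domain_to_term Data frame with columns `domain` and `term`.
#' @param domain_universe Character vector of all considered domains.
#' @param alpha FDR threshold (default 0.05).
#' @return Data frame as in [ora()].
#' @export
dcgo_style_enrich <- function(impacted_domains, domain_to_term,
                              domain_universe, alpha = 0.05) {
  if (length(impacted_domains) == 0L)
    return(ora(character(), list(), domain_universe, alpha))
  sets <- split(as.character(domain_to_term$domain),
                as.character(domain_to_term$term))
  ora(impacted_domains, sets, domain_universe, alpha)
}

#' Crossover of query genes against curated gene sets
#'
#' For each curated set reports the overlap count, the fraction of the set
#' covered by the query, and a hypergeometric upper-tail p-value.
#'
#' @param query_genes Character vector (e.g. genes with differentially
#'   expressed isoforms).
#' @param curated_sets Named list of character vectors.
#' @param universe Character vector; defaults to the union of the query
#'   and all set members.
#' @return Data frame: `set`, `set_size`, `overlap`, `overlap_fraction`,
#'   `p`.
#' @export
crossover <- function(query_genes, curated_sets, universe = NULL) {
  query_genes <- unique(query_genes)
  if (is.null(universe))
    universe <- unique(c(query_genes, unlist(curated_sets)))
  q <- intersect(query_genes, universe)
  out <- do.call(rbind, lapply(names(curated_sets), function(nm) {
    set <- intersect(unique(curated_sets[[nm]]), universe)
    k <- length(intersect(q, set))
    data.frame(set = nm, set_size = length(set), overlap = k,
               overlap_fraction = if (length(set)) k / length(set) else NA_real_,
               p = if (k == 0L) 1 else
                 hypergeom_upper(k, length(set), length(q), length(universe)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
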