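# RNA-binding-protein regulator screen: binding-site overlap with a target
# gene locus, then expression correlation between candidate RBPs and the
# gene's isoforms.

#' RBPs with binding sites overlapping a gene locus
#'
#' Half-open interval intersection against the whole gene span (no
#' proximity filter: distal sites within the locus count).  With
#' `strand_mode = "strict"` only sites on the gene's strand (or unstranded
#' `"."` sites) are counted.
#'
#' @param gene A [gene_model()] (supplies chrom, span and strand).
#' @param sites Binding-site data frame from [read_bed_sites()].
#' @param strand_mode `"ignore"` (default) or `"strict"`.
#' @return Data frame: `rbp_name`, `n_sites`, sorted by `n_sites`
#'   descending then name; candidates have at least one overlapping site.
#' @export
overlapping_rbps <- function(gene, sites, strand_mode = c("ignore", "strict")) {
  strand_mode <- match.arg(strand_mode)
  span <- gene_span(gene)
  ok <- sites$chrom == gene$chrom &
    sites$start < span[["end"]] & sites$end > span[["start"]]
  if (strand_mode == "strict")
    ok <- ok & (sites$strand == gene$strand | sites$strand == ".")
  hits <- sites[ok, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(rbp_name = character(), n_sites = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(hits$rbp_name)
  out <- data.frame(rbp_name = names(tab), n_sites = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_sites, out$rbp_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation matrix between RBP and isoform expression
#'
#' Pearson correlation per (RBP, isoform) combination.  With
#' `scope = "all_samples"` raw TPM vectors across all samples are
#' correlated; with `scope = "per_pair_log2fc"` the per-pair log2
#' fold-change vectors are used instead.
#'
#' @param expr An [expr_matrix()].
#' @param rbp_isoforms Named character vector: RBP name -> its isoform id
#'   in `expr`.
#' @param target_isoforms Character vector of target-gene isoform ids.
#' @param scope `"all_samples"` (default) or `"per_pair_log2fc"`.
#' @param pairs Required for `scope = "per_pair_log2fc"`.
#' @param pseudocount TPM pseudocount for the log2FC scope.
#' @return Data frame: `rbp_name`, `isoform_id`, `r`, `p_value`, `n`.
#' @export
rbp_isoform_correlation <- function(expr, rbp_isoforms, target_isoforms,
                                    scope = c("all_samples",
                                              "per_pair_log2fc"),
                                    pairs = NULL, pseudocount = 0.1) {
  scope <- match.arg(scope)
  if (scope == "all_samples") {
    mat <- expr$tpm
  } else {
    if (is.null(pairs)) stop("pairs required for per_pair_log2fc scope")
    mat <- log2fc_matrix(expr, pairs, pseudocount)
  }
  if (ncol(mat) < 3L) stop("need >= 3 samples for correlation")
  out <- list()
  for (rn in names(rbp_isoforms)) {
    rv <- mat[rbp_isoforms[[rn]], ]
    for (iso in target_isoforms) {
      iv <- mat[iso, ]
      if (stats::sd(rv) == 0 || stats::sd(iv) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          rbp_name = rn, isoform_id = iso, r = NA_real_,
          p_value = NA_real_, n = length(iv), stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(rv, iv, method = "pearson")
      out[[length(out) + 1L]] <- data.frame(
        rbp_name = rn, isoform_id = iso, r = unname(ct$estimate),
        p_value = ct$p.value, n = length(iv), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank RBP candidates by correlation strength
#'
#' Keeps RBPs whose correlation passes `|r| >= min_abs_r` and
#' `p <= max_p` for at least one isoform, ranked by maximum `|r|`
#' descending, ties broken by name.
#'
#' @param correlations Data frame from [rbp_isoform_correlation()].
#' @param min_abs_r Minimum absolute correlation (default 0.3).
#' @param max_p Maximum correlation p-value (default 0.05).
#' @return Data frame: `rbp_name`, `max_abs_r`, `best_isoform`,
#'   `best_p_value`, `n_passing`.
#' @export
rank_rbp_candidates <- function(correlations, min_abs_r = 0.3,
                                max_p = 0.05) {
  ok <- !is.na(correlations$r) & abs(correlations$r) >= min_abs_r &
    correlations$p_value <= max_p
  hits <- correlations[ok, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(rbp_name = character(), max_abs_r = numeric(),
                      best_isoform = character(), best_p_value = numeric(),
                      n_passing = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(hits, hits$rbp_name), function(h) {
    best <- which.max(abs(h$r))
    data.frame(rbp_name = h$rbp_name[1L], max_abs_r = abs(h$r[best]),
               best_isoform = h$isoform_id[best],
               best_p_value = h$p_value[best], n_passing = nrow(h),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$max_abs_r, out$rbp_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen candidate RBP regulators of one gene
#'
#' Combines binding-site overlap with expression correlation: RBPs with at
#' least one site in the gene locus are correlated with the gene's
#' isoforms and ranked.
#'
#' @param gene A [gene_model()] (the splicing target).
#' @param sites Binding-site data frame.
#' @param expr An [expr_matrix()].
#' @param rbp_isoforms Named character vector, RBP name -> isoform id.
#' @param strand_mode Passed to [overlapping_rbps()].
#' @param min_abs_r,max_p Passed to [rank_rbp_candidates()].
#' @param scope,pairs Passed to [rbp_isoform_correlation()].
#' @return List: `overlaps`, `correlations`, `ranked`.
#' @export
rbp_screen <- function(gene, sites, expr, rbp_isoforms,
                       strand_mode = "ignore", min_abs_r = 0.3,
                       max_p = 0.05, scope = "all_samples", pairs = NULL) {
  ov <- overlapping_rbps(gene, sites, strand_mode)
  cand <- intersect(ov$rbp_name, names(rbp_isoforms))
  target_iso <- intersect(names(gene$transcripts), rownames(expr$tpm))
  if (length(cand) == 0L || length(target_iso) == 0L)
    return(list(overlaps = ov,
                correlations = data.frame(), ranked = data.frame()))
  cors <- rbp_isoform_correlation(expr, rbp_isoforms[cand], target_iso,
                                  scope = scope, pairs = pairs)
  list(overlaps = ov, correlations = cors,
       ranked = rank_rbp_candidates(cors, min_abs_r, max_p))
}
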