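# Reciprocal within-gene isoform switch detection and the fold-change /
# dPSI correlation used to tie a switch to a specific exon.

#' Count reciprocal directional calls for an isoform pair
#'
#' Counts the patient-matched pairs in which the putative up isoform has an
#' up call and the putative down isoform a down call in the same pair.
#'
#' @param up_isoform,down_isoform Isoform ids.
#' @param dei_calls Data frame from [call_dei()].
#' @param pairs Data frame from [make_pairs()].
#' @return List: `n_reciprocal_pairs`, `n_pairs`, `percentage`
#'   (via [percent_recurrence()]).
#' @export
reciprocal_recurrence <- function(up_isoform, down_isoform, dei_calls,
                                  pairs) {
  up_pairs <- dei_calls$pair_id[dei_calls$isoform_id == up_isoform &
                                  dei_calls$direction == "up"]
  dn_pairs <- dei_calls$pair_id[dei_calls$isoform_id == down_isoform &
                                  dei_calls$direction == "down"]
  n <- length(intersect(up_pairs, dn_pairs))
  list(n_reciprocal_pairs = n, n_pairs = nrow(pairs),
       percentage = percent_recurrence(n, nrow(pairs)))
}

#' Correlation-based switch candidates within one gene
#'
#' For every ordered pair of the gene's isoforms, computes the Pearson
#' correlation of the two per-pair log2 fold-change vectors and emits
#' candidates with `r < 0`, `|r| >= min_abs_r` and `p <= max_p`.  Isoform
#' pairs with a constant log2FC vector (undefined correlation) are skipped
#' with a recorded reason.
#'
#' @param gene_id Gene to scan.
#' @param lfc log2 fold-change matrix from [log2fc_matrix()].
#' @param gene_map Named character vector, isoform -> gene.
#' @param dei_calls Data frame from [call_dei()].
#' @param pairs Data frame from [make_pairs()].
#' @param min_abs_r Minimum |r| (default 0.5).
#' @param max_p Maximum correlation p-value (default 0.05).
#' @return List with `candidates` (data frame: `gene_id`, `up_isoform`,
#'   `down_isoform`, `pearson_r`, `p_value`, `n_reciprocal_pairs`,
#'   `percentage`) and `skipped` (data frame of isoform pairs with
#'   undefined correlation).
#' @export
switch_candidates <- function(gene_id, lfc, gene_map, dei_calls, pairs,
                              min_abs_r = 0.5, max_p = 0.05) {
  iso <- names(gene_map)[gene_map == gene_id]
  iso <- intersect(iso, rownames(lfc))
  cand <- list(); skip <- list()
  if (length(iso) >= 2L && ncol(lfc) >= 3L) {
    combs <- utils::combn(sort(iso), 2L)
    for (cix in seq_len(ncol(combs))) {
      a <- combs[1L, cix]; b <- combs[2L, cix]
      va <- lfc[a, ]; vb <- lfc[b, ]
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
        skip[[length(skip) + 1L]] <- data.frame(
          gene_id = gene_id, isoform_a = a, isoform_b = b,
          reason = "constant log2FC vector", stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(va, vb, method = "pearson")
      r <- unname(ct$estimate)
      if (!(r < 0 && abs(r) >= min_abs_r && ct$p.value <= max_p)) next
      # orient by the dominant reciprocal direction
      fwd <- reciprocal_recurrence(a, b, dei_calls, pairs)
      rev <- reciprocal_recurrence(b, a, dei_calls, pairs)
      if (rev$n_reciprocal_pairs > fwd$n_reciprocal_pairs) {
        tmp <- a; a <- b; b <- tmp; fwd <- rev
      }
      cand[[length(cand) + 1L]] <- data.frame(
        gene_id = gene_id, up_isoform = a, down_isoform = b,
        pearson_r = r, p_value = ct$p.value,
        n_reciprocal_pairs = fwd$n_reciprocal_pairs,
        percentage = fwd$percentage, stringsAsFactors = FALSE)
    }
  }
  list(candidates = if (length(cand)) do.call(rbind, cand) else
    data.frame(gene_id = character(), up_isoform = character(),
               down_isoform = character(), pearson_r = numeric(),
               p_value = numeric(), n_reciprocal_pairs = integer(),
               percentage = numeric(), stringsAsFactors = FALSE),
    skipped = if (length(skip)) do.call(rbind, skip) else
      data.frame(gene_id = character(), isoform_a = character(),
                 isoform_b = character(), reason = character(),
                 stringsAsFactors = FALSE))
}

#' Detect reciprocal isoform switches across all genes
#'
#' The pipeline-level switch detector.  For every within-gene isoform pair
#' it counts reciprocal co-occurring directional calls in both
#' orientations; a switch is called when the net reciprocal count
#' (dominant orientation minus the reverse) reaches
#' `min_reciprocal_frac` of the matched pairs, and the directional shift
#' is statistically supported: per-patient mean log2FC (aggregated within
#' patient to respect the shared-baseline dependence of a patient's pairs)
#' must test above zero for the up isoform and below zero for the down
#' isoform (one-sided t, `p <= dir_alpha`) when at least three patients
#' are available.  The per-pair log2FC Pearson correlation is attached as
#' supporting evidence.  Requiring net directional co-occurrence (rather
#' than anti-correlation alone) rejects anti-correlated isoform pairs
#' produced by symmetric noise, which flip direction from pair to pair.
#'
#' @param expr An [expr_matrix()].
#' @param pairs Data frame from [make_pairs()].
#' @param dei_calls Data frame from [call_dei()]; computed from `expr` and
#'   `pairs` when omitted.
#' @param min_reciprocal_frac Minimum net reciprocal fraction of pairs
#'   (default 0.25).
#' @param dir_alpha One-sided significance level of the per-patient
#'   directional shift tests (default 0.05).
#' @param tpm_min,fc_cutoff,pseudocount Passed to [call_dei()] when
#'   `dei_calls` is omitted.
#' @return Data frame: `gene_id`, `up_isoform`, `down_isoform`,
#'   `n_reciprocal_pairs`, `n_reverse_pairs`, `net_reciprocal`,
#'   `percentage`, `pearson_r`, `p_value`, sorted by `net_reciprocal`
#'   descending then gene id.
#' @export
detect_switches <- function(expr, pairs, dei_calls = NULL,
                            min_reciprocal_frac = 0.25, tpm_min = 10,
                            fc_cutoff = 0.2, pseudocount = 0.1,
                            dir_alpha = 0.05) {
  if (is.null(dei_calls))
    dei_calls <- call_dei(expr, pairs, tpm_min, fc_cutoff, pseudocount)
  n_pairs <- nrow(pairs)
  if (n_pairs == 0L || nrow(dei_calls) == 0L)
    return(data.frame(gene_id = character(), up_isoform = character(),
                      down_isoform = character(),
                      n_reciprocal_pairs = integer(),
                      n_reverse_pairs = integer(),
                      net_reciprocal = integer(), percentage = numeric(),
                      pearson_r = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  lfc <- log2fc_matrix(expr, pairs, pseudocount)
  pat <- factor(pairs$patient_id)
  n_patients <- nlevels(pat)
  # per-patient mean log2FC (rows: isoforms), one-sided shift test
  pat_mean <- t(apply(lfc, 1L, function(v) tapply(v, pat, mean)))
  dir_p <- function(iso, side) {
    if (n_patients < 3L) return(0)     # too few patients: gate inactive
    v <- pat_mean[iso, ]
    m <- mean(v); s <- stats::sd(v)
    t_stat <- if (s == 0) (if (m == 0) 0 else sign(m) * 1e8)
              else m / (s / sqrt(n_patients))
    stats::pt(side * t_stat, df = n_patients - 1L, lower.tail = FALSE)
  }
  iso_called <- unique(dei_calls$isoform_id)
  # up/down call incidence matrices over pairs
  pair_lv <- pairs$pair_id
  upm <- matrix(FALSE, length(iso_called), n_pairs,
                dimnames = list(iso_called, pair_lv))
  dnm <- upm
  up <- dei_calls[dei_calls$direction == "up", ]
  dn <- dei_calls[dei_calls$direction == "down", ]
  upm[cbind(up$isoform_id, up$pair_id)] <- TRUE
  dnm[cbind(dn$isoform_id, dn$pair_id)] <- TRUE

  out <- list()
  genes <- unique(expr$isoform_to_gene[iso_called])
  for (g in genes) {
    iso <- intersect(iso_called,
                     names(expr$isoform_to_gene)[expr$isoform_to_gene == g])
    if (length(iso) < 2L) next
    combs <- utils::combn(sort(iso), 2L)
    for (cix in seq_len(ncol(combs))) {
      a <- combs[1L, cix]; b <- combs[2L, cix]
      n_ab <- sum(upm[a, ] & dnm[b, ])   # a up, b down
      n_ba <- sum(upm[b, ] & dnm[a, ])
      if (n_ab >= n_ba) { upx <- a; dnx <- b; nf <- n_ab; nr <- n_ba }
      else { upx <- b; dnx <- a; nf <- n_ba; nr <- n_ab }
      net <- nf - nr
      if (net < min_reciprocal_frac * n_pairs) next
      if (dir_p(upx, 1) > dir_alpha || dir_p(dnx, -1) > dir_alpha) next
      r <- p <- NA_real_
      if (stats::sd(lfc[a, ]) > 0 && stats::sd(lfc[b, ]) > 0 &&
          n_pairs >= 3L) {
        ct <- stats::cor.test(lfc[a, ], lfc[b, ], method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, up_isoform = upx, down_isoform = dnx,
        n_reciprocal_pairs = nf, n_reverse_pairs = nr,
        net_reciprocal = net,
        percentage = percent_recurrence(nf, n_pairs),
        pearson_r = r, p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), up_isoform = character(),
                      down_isoform = character(),
                      n_reciprocal_pairs = integer(),
                      n_reverse_pairs = integer(),
                      net_reciprocal = integer(), percentage = numeric(),
                      pearson_r = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  out <- out[order(-out$net_reciprocal, out$gene_id, out$up_isoform), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between log2FC and dPSI vectors
#'
#' Two-sided p-value from the t distribution with `n - 2` degrees of
#' freedom; incomplete observations are pairwise-deleted.
#'
#' @param log2fc_vector,dpsi_vector Equal-length numeric vectors.
#' @return List: `r`, `p_value`, `n`.
#' @export
correlate_fc_dpsi <- function(log2fc_vector, dpsi_vector) {
  if (length(log2fc_vector) != length(dpsi_vector))
    stop("vectors must have equal length")
  ok <- is.finite(log2fc_vector) & is.finite(dpsi_vector)
  x <- log2fc_vector[ok]; y <- dpsi_vector[ok]
  if (length(x) < 3L) stop("fewer than 3 complete pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
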