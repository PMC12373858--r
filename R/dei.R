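# Per-pair differential isoform calling, recurrence ranking, concordance
# filtering, sharing and diversity summaries.

#' Build patient-matched Baseline/DP comparison pairs
#'
#' One pair per DP sample, matched to its patient's unique Baseline sample.
#'
#' @param sheet A [sample_sheet()].
#' @return Data frame with columns `pair_id`, `patient_id`,
#'   `baseline_sample`, `dp_sample`; zero rows if the sheet has no DP
#'   samples.
#' @export
make_pairs <- function(sheet) {
  sheet <- sample_sheet(sheet)
  dp <- sheet[sheet$condition == "DP", , drop = FALSE]
  if (nrow(dp) == 0L)
    return(data.frame(pair_id = character(), patient_id = character(),
                      baseline_sample = character(), dp_sample = character(),
                      stringsAsFactors = FALSE))
  base <- sheet[sheet$condition == "Baseline", , drop = FALSE]
  bmap <- stats::setNames(base$sample_id, base$patient_id)
  data.frame(pair_id = dp$sample_id,
             patient_id = dp$patient_id,
             baseline_sample = unname(bmap[dp$patient_id]),
             dp_sample = dp$sample_id,
             stringsAsFactors = FALSE)
}

#' Call differentially expressed isoforms for all pairs
#'
#' An isoform is evaluated in a pair only if its raw TPM reaches `tpm_min`
#' in at least one of the two samples.  The fold change is
#' `(TPM_DP + pseudocount) / (TPM_Baseline + pseudocount)`; a call is
#' emitted iff `|1 - FC| > fc_cutoff` (asymmetric on the raw FC scale:
#' FC < 1 - fc_cutoff or FC > 1 + fc_cutoff).  With `pseudocount = 0` and a
#' zero baseline, `FC = Inf` is treated as an up call.
#'
#' @param expr An [expr_matrix()].
#' @param pairs Data frame from [make_pairs()].
#' @param tpm_min Minimum TPM in at least one sample of the pair (default
#'   10).
#' @param fc_cutoff Fold-change cutoff on the `|1 - FC|` scale (default
#'   0.2).
#' @param pseudocount TPM added to numerator and denominator (default 0.1).
#' @return Data frame of calls: `isoform_id`, `pair_id`, `fc`, `log2fc`,
#'   `direction` (`"up"`/`"down"`).
#' @export
call_dei <- function(expr, pairs, tpm_min = 10, fc_cutoff = 0.2,
                     pseudocount = 0.1) {
  stopifnot(inherits(expr, "expr_matrix"))
  miss <- setdiff(c(pairs$baseline_sample, pairs$dp_sample),
                  colnames(expr$tpm))
  if (length(miss))
    stop("pair sample(s) absent from expression matrix: ",
         paste(unique(miss), collapse = ", "))
  if (nrow(pairs) == 0L)
    return(data.frame(isoform_id = character(), pair_id = character(),
                      fc = numeric(), log2fc = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  B <- expr$tpm[, pairs$baseline_sample, drop = FALSE]
  D <- expr$tpm[, pairs$dp_sample, drop = FALSE]
  fc <- (D + pseudocount) / (B + pseudocount)
  called <- (pmax(B, D) >= tpm_min) & (abs(1 - fc) > fc_cutoff)
  idx <- which(called, arr.ind = TRUE)
  out <- data.frame(isoform_id = rownames(expr$tpm)[idx[, 1L]],
                    pair_id = pairs$pair_id[idx[, 2L]],
                    fc = fc[idx], log2fc = log2(fc[idx]),
                    direction = ifelse(fc[idx] > 1, "up", "down"),
                    stringsAsFactors = FALSE)
  out[order(out$isoform_id, out$pair_id), , drop = FALSE]
}

#' Call differentially expressed isoforms for a single pair
#'
#' Single-pair convenience wrapper around [call_dei()].
#'
#' @inheritParams call_dei
#' @param pair One-row data frame (or list) with `pair_id`,
#'   `baseline_sample`, `dp_sample`.
#' @return Data frame of calls for this pair.
#' @export
call_dei_pair <- function(expr, pair, tpm_min = 10, fc_cutoff = 0.2,
                          pseudocount = 0.1) {
  pair <- as.data.frame(pair, stringsAsFactors = FALSE)
  call_dei(expr, pair[1L, , drop = FALSE], tpm_min = tpm_min,
           fc_cutoff = fc_cutoff, pseudocount = pseudocount)
}

#' Per-pair log2 fold-change matrix
#'
#' @inheritParams call_dei
#' @return Numeric matrix, isoforms x pairs, of
#'   `log2((TPM_DP + pseudocount) / (TPM_Baseline + pseudocount))`.
#' @export
log2fc_matrix <- function(expr, pairs, pseudocount = 0.1) {
  B <- expr$tpm[, pairs$baseline_sample, drop = FALSE]
  D <- expr$tpm[, pairs$dp_sample, drop = FALSE]
  lfc <- log2((D + pseudocount) / (B + pseudocount))
  colnames(lfc) <- pairs$pair_id
  lfc
}

#' Rank isoforms by recurrence of directional calls
#'
#' Counts per isoform how many pairs yielded an up call and a down call,
#' and ranks by `max(n_up, n_down)` (frequency of abnormal expression)
#' descending, ties broken by concordance (`n_up - n_down`) descending,
#' then by isoform id.
#'
#' @param calls Data frame from [call_dei()].
#' @param pairs Data frame from [make_pairs()].
#' @param isoform_ids Optional character vector of isoforms to report
#'   (defaults to isoforms appearing in `calls`); isoforms with no calls
#'   get zero counts.
#' @return Data frame: `isoform_id`, `n_up`, `n_down`, `n_pairs`,
#'   `concordance`, `recurrence`.
#' @export
recurrence <- function(calls, pairs, isoform_ids = NULL) {
  if (is.null(isoform_ids)) isoform_ids <- sort(unique(calls$isoform_id))
  up <- table(factor(calls$isoform_id[calls$direction == "up"],
                     levels = isoform_ids))
  dn <- table(factor(calls$isoform_id[calls$direction == "down"],
                     levels = isoform_ids))
  out <- data.frame(isoform_id = isoform_ids,
                    n_up = as.integer(up), n_down = as.integer(dn),
                    n_pairs = nrow(pairs), stringsAsFactors = FALSE)
  out$concordance <- out$n_up - out$n_down
  out$recurrence <- pmax(out$n_up, out$n_down)
  out <- out[order(-out$recurrence, -out$concordance, out$isoform_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concordance filter on recurrence records
#'
#' Retains isoforms whose up- and down-call counts differ by strictly more
#' than `min_diff`.
#'
#' @param records Data frame from [recurrence()].
#' @param min_diff Minimum absolute difference, strict (default 6).
#' @return Filtered records.
#' @export
concordance_filter <- function(records, min_diff = 6) {
  records[abs(records$n_up - records$n_down) > min_diff, , drop = FALSE]
}

#' Cumulative recurrence curve
#'
#' For each recurrence threshold `k` from 0 to the maximum observed,
#' counts the isoforms whose `max(n_up, n_down)` is at least `k`.
#'
#' @param records Data frame from [recurrence()].
#' @return Data frame with columns `k` and `n_isoforms`; the value at
#'   `k = 0` equals the total number of isoforms.
#' @export
cumulative_recurrence_curve <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(k = 0L, n_isoforms = 0L))
  r <- records$recurrence
  ks <- 0:max(r)
  data.frame(k = ks,
             n_isoforms = vapply(ks, function(k) sum(r >= k), 0L))
}

#' Isoform sharing between Baseline and DP groups
#'
#' An isoform is "present" in a group when its TPM reaches `presence_tpm`
#' in at least one sample of the group.
#'
#' @param expr An [expr_matrix()].
#' @param sheet A [sample_sheet()].
#' @param presence_tpm Presence threshold in TPM (default 1).
#' @return List: `n_baseline_only`, `n_dp_only`, `n_shared`,
#'   `shared_fraction` (shared / total detected).
#' @export
sharing_stats <- function(expr, sheet, presence_tpm = 1) {
  sheet <- sample_sheet(sheet)
  bs <- sheet$sample_id[sheet$condition == "Baseline"]
  ds <- sheet$sample_id[sheet$condition == "DP"]
  in_b <- rowSums(expr$tpm[, bs, drop = FALSE] >= presence_tpm) > 0L
  in_d <- rowSums(expr$tpm[, ds, drop = FALSE] >= presence_tpm) > 0L
  n_shared <- sum(in_b & in_d)
  n_b <- sum(in_b & !in_d)
  n_d <- sum(!in_b & in_d)
  total <- n_shared + n_b + n_d
  list(n_baseline_only = n_b, n_dp_only = n_d, n_shared = n_shared,
       shared_fraction = if (total > 0L) n_shared / total else NA_real_)
}

#' Per-gene, per-sample isoform diversity
#'
#' Normalized Shannon entropy of the Laplace-smoothed isoform relative
#' abundances of each gene:
#' `H = -sum(p_i * log2(p_i)) / log2(m)` for a gene with `m > 1` isoforms,
#' where `p_i = (tpm_i + pseudocount) / sum(tpm + pseudocount)`.
#' Single-isoform genes are reported as missing.
#'
#' @param expr An [expr_matrix()].
#' @param pseudocount Laplace smoothing TPM added per isoform (default
#'   0.1).
#' @return Data frame: `gene_id`, `sample_id`, `n_isoforms`, `entropy`.
#' @export
isoform_diversity <- function(expr, pseudocount = 0.1) {
  genes <- split(rownames(expr$tpm), expr$isoform_to_gene)
  out <- lapply(names(genes), function(g) {
    iso <- genes[[g]]
    m <- length(iso)
    if (m < 2L)
      return(data.frame(gene_id = g, sample_id = colnames(expr$tpm),
                        n_isoforms = m, entropy = NA_real_,
                        stringsAsFactors = FALSE))
    x <- expr$tpm[iso, , drop = FALSE] + pseudocount
    p <- sweep(x, 2L, colSums(x), "/")
    plogp <- ifelse(p > 0, p * log2(p), 0)
    H <- -colSums(plogp) / log2(m)
    data.frame(gene_id = g, sample_id = colnames(expr$tpm),
               n_isoforms = m, entropy = unname(H), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare isoform diversity between altered and non-altered genes
#'
#' Wilcoxon rank-sum test on per-gene mean entropy between genes harboring
#' differential splicing events and the remaining genes.
#'
#' @param diversity Data frame from [isoform_diversity()].
#' @param altered_genes Character vector of genes with differential
#'   splicing events.
#' @return List: `statistic`, `p_value`, `median_altered`,
#'   `median_non_altered`, `n_altered`, `n_non_altered`.
#' @export
diversity_test <- function(diversity, altered_genes) {
  d <- diversity[!is.na(diversity$entropy), , drop = FALSE]
  gmean <- tapply(d$entropy, d$gene_id, mean)
  alt <- gmean[names(gmean) %in% altered_genes]
  non <- gmean[!names(gmean) %in% altered_genes]
  if (length(alt) == 0L || length(non) == 0L)
    stop("both altered and non-altered groups must be non-empty")
  wt <- stats::wilcox.test(alt, non)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_altered = stats::median(alt),
       median_non_altered = stats::median(non),
       n_altered = length(alt), n_non_altered = length(non))
}

#' Paired t-test on log2 TPM of one isoform across matched pairs
#'
#' Classical paired t-test on `log2(TPM + pseudocount)` differences
#' (DP minus Baseline).  With zero-variance non-zero differences the t
#' statistic is capped at a large finite value (1e8) and the p-value
#' underflows to 0; identical vectors give `t = 0, p = 1`.
#'
#' @param expr An [expr_matrix()].
#' @param isoform_id Isoform to test.
#' @param pairs Data frame from [make_pairs()] (needs >= 2 pairs).
#' @param pseudocount TPM pseudocount (default 0.1).
#' @return List: `t`, `p_value`, `df`, `mean_diff`.
#' @export
paired_group_test <- function(expr, isoform_id, pairs, pseudocount = 0.1) {
  if (nrow(pairs) < 2L) stop("need >= 2 pairs for a paired t-test")
  b <- log2(expr$tpm[isoform_id, pairs$baseline_sample] + pseudocount)
  d <- log2(expr$tpm[isoform_id, pairs$dp_sample] + pseudocount)
  diffs <- d - b
  n <- length(diffs)
  s <- stats::sd(diffs)
  m <- mean(diffs)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * 1e8
  } else {
    t_stat <- m / (s / sqrt(n))
  }
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  list(t = t_stat, p_value = p, df = n - 1L, mean_diff = m)
}
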