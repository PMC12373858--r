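# Classification of canonical alternative-splicing events (SE, A5SS, A3SS,
# RI, MXE) from transcript structures, and abundance-based PSI testing.
# Events are defined purely from exon coordinates; flank matching requires
# exact coordinate identity.  PSI is computed from isoform TPM, not from
# junction reads.

.ex_key <- function(m) paste(m[, 1L], m[, 2L], sep = "-")

# does transcript exon matrix `ex` contain `chain` (k x 2) as consecutive
# exons with identical coordinates?
.has_chain <- function(ex, chain) {
  idx <- match(.ex_key(chain), .ex_key(ex))
  if (anyNA(idx)) return(FALSE)
  all(diff(idx) == 1L)
}

.has_exon <- function(ex, exon) any(ex[, 1L] == exon[1L] & ex[, 2L] == exon[2L])

#' Classify alternative-splicing events of one gene
#'
#' Scans all transcript pairs of a gene for the five canonical event
#' patterns:
#' \describe{
#'   \item{SE}{a cassette exon present in one transcript and absent in the
#'     other, with both flanking exons shared at identical coordinates and
#'     adjacent in the skipping form.}
#'   \item{RI}{a single exon `[a,d)` in one transcript versus exons
#'     `[a,b)`, `[c,d)` with `b < c` in the other.}
#'   \item{A5SS/A3SS}{two exons sharing one boundary and differing at the
#'     other, anchored by an identical flanking exon on the differing side;
#'     whether the shifted boundary is the donor (5') or acceptor (3') side
#'     depends on strand.}
#'   \item{MXE}{exons X and Y between identical shared flanks where each
#'     transcript contains exactly one of X, Y and no transcript of the
#'     gene contains both.}
#' }
#' Events are deduplicated by (mode, coordinates); isoform support sets
#' contain every gene transcript consistent with each form.
#'
#' @param gene A [gene_model()].
#' @return Data frame with columns `event_id`, `gene_id`, `mode`, `chrom`,
#'   `strand`, `coordinates` (mode-specific, `;`-separated intervals) and
#'   list columns `inclusion_isoforms`, `exclusion_isoforms`.  Empty for
#'   single-transcript genes.
#' @export
classify_events <- function(gene) {
  txs <- gene$transcripts
  empty <- data.frame(event_id = character(), gene_id = character(),
                      mode = character(), chrom = character(),
                      strand = character(), coordinates = character(),
                      stringsAsFactors = FALSE)
  empty$inclusion_isoforms <- list()
  empty$exclusion_isoforms <- list()
  if (length(txs) < 2L) return(empty)
  exl <- lapply(txs, `[[`, "exons")
  ids <- names(txs)
  strand <- gene$strand
  span <- gene_span(gene)

  events <- new.env(parent = emptyenv())
  add_event <- function(mode, coords, incl_chain, excl_chain) {
    key <- paste(mode, paste(coords, collapse = ";"), sep = "|")
    if (!is.null(events[[key]])) return(invisible())
    incl <- ids[vapply(exl, .has_chain, NA, chain = incl_chain)]
    excl <- ids[vapply(exl, .has_chain, NA, chain = excl_chain)]
    excl <- setdiff(excl, incl)
    if (length(incl) == 0L || length(excl) == 0L) return(invisible())
    events[[key]] <- list(mode = mode,
                          coordinates = paste(coords, collapse = ";"),
                          inclusion = sort(incl), exclusion = sort(excl))
    invisible()
  }
  ival <- function(x) sprintf("[%d,%d)", as.integer(x[1L]), as.integer(x[2L]))

  for (a in seq_along(exl)) for (b in seq_along(exl)) {
    if (a == b) next
    A <- exl[[a]]; B <- exl[[b]]
    nA <- nrow(A)

    # SE: internal exon of A absent from B, flanks shared and adjacent in B
    if (nA >= 3L) for (i in 2:(nA - 1L)) {
      cas <- A[i, ]; f1 <- A[i - 1L, ]; f2 <- A[i + 1L, ]
      if (!.has_exon(B, cas) && .has_chain(B, rbind(f1, f2)))
        add_event("SE", c(ival(f1), ival(cas), ival(f2)),
                  incl_chain = rbind(f1, cas, f2),
                  excl_chain = rbind(f1, f2))
    }

    # RI: exon [a,d) in A vs consecutive [a,b), [c,d) in B
    for (i in seq_len(nA)) {
      e <- A[i, ]
      if (nrow(B) < 2L) next
      for (j in seq_len(nrow(B) - 1L)) {
        if (B[j, 1L] == e[1L] && B[j + 1L, 2L] == e[2L] &&
            B[j, 2L] < B[j + 1L, 1L])
          add_event("RI", c(ival(e), ival(B[j, ]), ival(B[j + 1L, ])),
                    incl_chain = rbind(e),
                    excl_chain = rbind(B[j, ], B[j + 1L, ]))
      }
    }

    # A5SS / A3SS: shared boundary on one side, shifted on the other,
    # anchored by an identical adjacent flank on the shifted side
    for (i in seq_len(nA)) for (j in seq_len(nrow(B))) {
      e1 <- A[i, ]; e2 <- B[j, ]
      # shared start, differing end -> flank must follow both exons
      if (e1[1L] == e2[1L] && e1[2L] != e2[2L] &&
          i < nA && j < nrow(B)) {
        fA <- A[i + 1L, ]; fB <- B[j + 1L, ]
        if (all(fA == fB)) {
          long <- if (e1[2L] > e2[2L]) e1 else e2
          short <- if (e1[2L] > e2[2L]) e2 else e1
          mode <- if (strand == "+") "A5SS" else "A3SS"
          add_event(mode, c(ival(long), ival(short), ival(fA)),
                    incl_chain = rbind(long, fA),
                    excl_chain = rbind(short, fA))
        }
      }
      # shared end, differing start -> flank must precede both exons
      if (e1[2L] == e2[2L] && e1[1L] != e2[1L] && i > 1L && j > 1L) {
        fA <- A[i - 1L, ]; fB <- B[j - 1L, ]
        if (all(fA == fB)) {
          long <- if (e1[1L] < e2[1L]) e1 else e2
          short <- if (e1[1L] < e2[1L]) e2 else e1
          mode <- if (strand == "+") "A3SS" else "A5SS"
          add_event(mode, c(ival(long), ival(short), ival(fA)),
                    incl_chain = rbind(fA, long),
                    excl_chain = rbind(fA, short))
        }
      }
    }

    # MXE: flanked exons X (in A) and Y (in B), no transcript has both
    if (nA >= 3L) for (i in 2:(nA - 1L)) {
      X <- A[i, ]; f1 <- A[i - 1L, ]; f2 <- A[i + 1L, ]
      nB <- nrow(B)
      if (nB < 3L) next
      for (j in 2:(nB - 1L)) {
        Y <- B[j, ]
        if (all(Y == X)) next
        if (!all(B[j - 1L, ] == f1) || !all(B[j + 1L, ] == f2)) next
        both <- vapply(exl, function(ex)
          .has_exon(ex, X) && .has_exon(ex, Y), NA)
        if (any(both)) next
        lo <- if (X[1L] < Y[1L] || (X[1L] == Y[1L] && X[2L] < Y[2L])) X else Y
        hi <- if (identical(unname(lo), unname(X))) Y else X
        add_event("MXE", c(ival(f1), ival(lo), ival(hi), ival(f2)),
                  incl_chain = rbind(f1, lo, f2),
                  excl_chain = rbind(f1, hi, f2))
      }
    }
  }

  keys <- sort(ls(events))
  if (length(keys) == 0L) return(empty)
  evs <- lapply(keys, function(k) events[[k]])
  out <- data.frame(
    event_id = paste0(gene$gene_id, ".ev", seq_along(keys)),
    gene_id = gene$gene_id,
    mode = vapply(evs, `[[`, "", "mode"),
    chrom = gene$chrom, strand = strand,
    coordinates = vapply(evs, `[[`, "", "coordinates"),
    stringsAsFactors = FALSE)
  out$inclusion_isoforms <- lapply(evs, `[[`, "inclusion")
  out$exclusion_isoforms <- lapply(evs, `[[`, "exclusion")
  rownames(out) <- NULL
  out
}

#' Classify events for every gene of an annotation
#' @param annotation Named list of gene models.
#' @return Row-bound event data frame across genes.
#' @export
classify_events_all <- function(annotation) {
  out <- do.call(rbind, lapply(annotation, classify_events))
  rownames(out) <- NULL
  out
}

#' Per-sample percent-spliced-in of an event
#'
#' `psi = sum(TPM inclusion isoforms) / sum(TPM of inclusion and exclusion
#' isoforms)`; missing (NA) when the total is zero.  Isoforms absent from
#' the expression matrix are ignored.
#'
#' @param event One event (a one-row slice of [classify_events()] output,
#'   or a list with `event_id`, `inclusion_isoforms`,
#'   `exclusion_isoforms`).
#' @param expr An [expr_matrix()].
#' @return Data frame: `event_id`, `sample_id`, `psi`, `inclusion_tpm`,
#'   `total_tpm`.
#' @export
compute_psi <- function(event, expr) {
  incl <- unlist(event$inclusion_isoforms)
  excl <- unlist(event$exclusion_isoforms)
  incl <- intersect(incl, rownames(expr$tpm))
  excl <- intersect(excl, rownames(expr$tpm))
  if (length(incl) == 0L && length(excl) == 0L)
    stop("event isoforms absent from expression matrix: ", event$event_id)
  itpm <- colSums(expr$tpm[incl, , drop = FALSE])
  ttpm <- itpm + colSums(expr$tpm[setdiff(excl, incl), , drop = FALSE])
  psi <- ifelse(ttpm > 0, itpm / ttpm, NA_real_)
  data.frame(event_id = as.character(event$event_id)[1L],
             sample_id = colnames(expr$tpm),
             psi = unname(psi), inclusion_tpm = unname(itpm),
             total_tpm = unname(ttpm), stringsAsFactors = FALSE)
}

#' PSI for every event of an event table
#' @param events Data frame from [classify_events_all()].
#' @param expr An [expr_matrix()].
#' @return Long data frame of per-sample PSI values.
#' @export
compute_psi_all <- function(events, expr) {
  out <- do.call(rbind, lapply(seq_len(nrow(events)), function(i)
    compute_psi(events[i, ], expr)))
  rownames(out) <- NULL
  out
}

#' Ad-hoc PSI of one exon within a gene
#'
#' Fraction of the gene's total TPM carried by transcripts containing the
#' exact exon interval -- the "percentage of mRNA containing the exon
#' relative to the total gene mRNA".
#'
#' @param gene A [gene_model()].
#' @param exon Numeric `c(start, end)`, 0-based half-open.
#' @param expr An [expr_matrix()].
#' @return Named numeric vector of per-sample PSI (NA where the gene is
#'   unexpressed).
#' @export
exon_psi <- function(gene, exon, expr) {
  ids <- intersect(names(gene$transcripts), rownames(expr$tpm))
  if (length(ids) == 0L) stop("no transcripts of ", gene$gene_id,
                              " in expression matrix")
  has <- vapply(gene$transcripts[ids], function(tx)
    .has_exon(tx$exons, exon), NA)
  itpm <- colSums(expr$tpm[ids[has], , drop = FALSE])
  ttpm <- colSums(expr$tpm[ids, , drop = FALSE])
  ifelse(ttpm > 0, itpm / ttpm, NA_real_)
}

#' Test events for differential PSI across matched pairs
#'
#' Per-pair `dPSI = PSI_DP - PSI_Baseline`; events with at least
#' `min_pairs` informative pairs get a paired t-test against 0, BH
#' adjustment across tested events, and a significance flag
#' `|mean dPSI| > dpsi_min & q < fdr_alpha`.  Events with fewer
#' informative pairs are reported untested (`tested = FALSE`, NA
#' statistics) rather than assigned p = 1.
#'
#' @param psis Long PSI data frame from [compute_psi_all()].
#' @param pairs Data frame from [make_pairs()].
#' @param dpsi_min Minimum absolute mean dPSI (default 0.1).
#' @param fdr_alpha FDR threshold (default 0.05).
#' @param min_pairs Minimum informative pairs to test (default 3).
#' @return Data frame: `event_id`, `n_pairs_used`, `mean_dpsi`, `t`,
#'   `p_value`, `q_value`, `tested`, `significant`.
#' @export
test_events <- function(psis, pairs, dpsi_min = 0.1, fdr_alpha = 0.05,
                        min_pairs = 3L) {
  psi_mat <- tapply(psis$psi, list(psis$event_id, psis$sample_id),
                    function(x) x[1L])
  res <- lapply(rownames(psi_mat), function(ev) {
    d <- psi_mat[ev, pairs$dp_sample] - psi_mat[ev, pairs$baseline_sample]
    d <- d[!is.na(d)]
    n <- length(d)
    if (n < min_pairs)
      return(data.frame(event_id = ev, n_pairs_used = n,
                        mean_dpsi = if (n > 0L) mean(d) else NA_real_,
                        t = NA_real_, p_value = NA_real_,
                        tested = FALSE, stringsAsFactors = FALSE))
    m <- mean(d); s <- stats::sd(d)
    t_stat <- if (s == 0) (if (m == 0) 0 else sign(m) * 1e8)
              else m / (s / sqrt(n))
    data.frame(event_id = ev, n_pairs_used = n, mean_dpsi = m, t = t_stat,
               p_value = 2 * stats::pt(-abs(t_stat), df = n - 1L),
               tested = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  out$q_value[out$tested] <- bh_fdr(out$p_value[out$tested])
  out$significant <- out$tested & !is.na(out$q_value) &
    abs(out$mean_dpsi) > dpsi_min & out$q_value < fdr_alpha
  rownames(out) <- NULL
  out
}

#' Distribution of event modes
#'
#' @param x Event data frame (optionally pre-filtered, e.g. to significant
#'   events); needs a `mode` column.
#' @return Named numeric vector of proportions over the modes present
#'   (sums to 1); empty for empty input.
#' @export
event_mode_distribution <- function(x) {
  if (NROW(x) == 0L) return(stats::setNames(numeric(), character()))
  tab <- table(x$mode)
  p <- as.numeric(tab) / sum(tab)
  stats::setNames(p, names(tab))
}
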