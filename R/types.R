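# ---- transcript / gene models --------------------------------------------

#' Construct a transcript model
#'
#' Transcript structures are stored with 0-based half-open exon intervals
#' sorted by start; GTF input/output converts at the boundary.
#'
#' @param transcript_id,gene_id Character identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix of `[start, end)` intervals.
#' @param cds Optional two-column matrix of CDS intervals, same convention.
#' @param biotype Transcript biotype, e.g. `"protein_coding"`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL, biotype = "protein_coding") {
  exons <- .as_interval_matrix(exons)
  if (nrow(exons) == 0L)
    stop("transcript '", transcript_id, "' has zero exons")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  .check_intervals(exons, transcript_id)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  if (!is.null(cds)) {
    cds <- .as_interval_matrix(cds)
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    .check_intervals(cds, paste0(transcript_id, " (CDS)"))
  }
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom), strand = strand,
         exons = exons, cds = cds, biotype = as.character(biotype)),
    class = "transcript_model")
}

.as_interval_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("interval matrix must have two columns")
  storage.mode(x) <- "double"
  dimnames(x) <- list(NULL, c("start", "end"))
  x
}

.check_intervals <- function(m, what) {
  if (any(m[, 2L] <= m[, 1L]))
    stop("invalid interval (start >= end) in ", what)
  if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L]))
    stop("overlapping or unsorted intervals in ", what)
  invisible(m)
}

#' Construct a gene model from transcript models
#'
#' @param transcripts List of [transcript_model()] objects sharing one
#'   `gene_id`, `chrom` and `strand`.
#' @return An object of class `gene_model` with elements `gene_id`, `chrom`,
#'   `strand` and a named list `transcripts`.
#' @export
gene_model <- function(transcripts) {
  stopifnot(length(transcripts) >= 1L)
  gid <- unique(vapply(transcripts, `[[`, "", "gene_id"))
  chrom <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strand <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(gid) != 1L || length(chrom) != 1L || length(strand) != 1L)
    stop("transcripts of one gene must share gene_id, chrom and strand")
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(list(gene_id = gid, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

#' Genomic span of a gene model
#' @param gene A `gene_model`.
#' @return Numeric `c(start, end)`, 0-based half-open.
#' @export
gene_span <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
  c(start = min(ex[, 1L]), end = max(ex[, 2L]))
}

#' Map isoforms to genes for an annotation
#' @param annotation Named list of `gene_model`s.
#' @return Named character vector, `transcript_id -> gene_id`.
#' @export
isoform_gene_map <- function(annotation) {
  out <- unlist(lapply(annotation, function(g) {
    stats::setNames(rep(g$gene_id, length(g$transcripts)),
                    names(g$transcripts))
  }), use.names = TRUE)
  names(out) <- sub("^[^.]*\\.", "", names(out))
  tx <- unlist(lapply(annotation, function(g) names(g$transcripts)))
  stats::setNames(as.character(out), tx)
}

# ---- expression matrix ----------------------------------------------------

#' Construct an isoform-by-sample TPM matrix
#'
#' @param tpm Numeric matrix, rows isoforms, columns samples; all entries
#'   finite and non-negative.
#' @param isoform_to_gene Named character vector mapping every row name to a
#'   gene identifier.
#' @return Object of class `expr_matrix` (list with `tpm`,
#'   `isoform_to_gene`).
#' @export
expr_matrix <- function(tpm, isoform_to_gene) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop("tpm matrix needs isoform row names and sample column names")
  if (anyDuplicated(rownames(tpm)))
    stop("duplicated isoform ids: ",
         paste(unique(rownames(tpm)[duplicated(rownames(tpm))]), collapse = ", "))
  if (anyDuplicated(colnames(tpm))) stop("duplicated sample ids")
  if (any(!is.finite(tpm))) stop("TPM values must be finite (no NA/Inf)")
  if (any(tpm < 0)) stop("negative TPM values are not allowed")
  orphan <- setdiff(rownames(tpm), names(isoform_to_gene))
  if (length(orphan))
    stop("isoforms missing from gene map: ", paste(orphan, collapse = ", "))
  structure(list(tpm = tpm,
                 isoform_to_gene = isoform_to_gene[rownames(tpm)]),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$tpm), "isoforms x", ncol(x$tpm), "samples;",
      length(unique(x$isoform_to_gene)), "genes\n")
  invisible(x)
}

# ---- sample sheet ---------------------------------------------------------

#' Construct and validate a sample sheet
#'
#' Each row describes one biopsy.  Conditions are `"Baseline"` or `"DP"`
#' (disease progression); every patient contributing a DP sample must have
#' exactly one Baseline sample.
#'
#' @param df Data frame with columns `sample_id`, `patient_id`, `condition`.
#' @return The validated data frame with class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "patient_id", "condition")
  if (!all(need %in% names(df)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  for (j in need) df[[j]] <- as.character(df[[j]])
  bad <- setdiff(unique(df$condition), c("Baseline", "DP"))
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample ids in sample sheet")
  nb <- table(df$patient_id[df$condition == "Baseline"])
  dp_pat <- unique(df$patient_id[df$condition == "DP"])
  miss <- dp_pat[!(dp_pat %in% names(nb)) | nb[dp_pat] != 1L]
  miss <- miss[!is.na(miss)]
  if (length(miss))
    stop("DP patient(s) without exactly one Baseline sample: ",
         paste(miss, collapse = ", "))
  class(df) <- c("sample_sheet", "data.frame")
  df
}
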