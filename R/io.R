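# Readers/writers for the external formats the pipeline touches.  All
# genomic intervals are converted to 0-based half-open coordinates at the
# boundary; GTF and BED conventions are handled here and nowhere else.

#' Read transcript models from a GTF file
#'
#' Parses exon (and optionally CDS) features of a Gencode-dialect GTF into
#' gene models.  GTF 1-based inclusive coordinates are converted to internal
#' 0-based half-open intervals; exons are sorted by start.  Unknown
#' attributes are ignored.
#'
#' @param path Path to a GTF file.
#' @return Named list of [gene_model()] objects (names are gene ids).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) stop("no exon features in GTF: ", path)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id) || is.null(mc$transcript_id) ||
      anyNA(mc$gene_id) || anyNA(mc$transcript_id))
    stop("GTF features must carry gene_id and transcript_id attributes")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,     # to 0-based half-open
    end   = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    gene_id = as.character(mc$gene_id),
    transcript_id = as.character(mc$transcript_id),
    biotype = if (!is.null(mc$transcript_biotype))
      as.character(mc$transcript_biotype) else "protein_coding",
    stringsAsFactors = FALSE)
  df$biotype[is.na(df$biotype)] <- "protein_coding"
  genes <- split(df, df$gene_id)
  ann <- lapply(genes, function(gd) {
    txs <- split(gd, gd$transcript_id)
    gene_model(lapply(txs, function(td) {
      ex <- td[td$type == "exon", , drop = FALSE]
      if (nrow(ex) == 0L)
        stop("transcript '", td$transcript_id[1L], "' has zero exon features")
      cd <- td[td$type == "CDS", , drop = FALSE]
      transcript_model(
        transcript_id = td$transcript_id[1L], gene_id = td$gene_id[1L],
        chrom = td$chrom[1L], strand = td$strand[1L],
        exons = cbind(ex$start, ex$end),
        cds = if (nrow(cd)) cbind(cd$start, cd$end) else NULL,
        biotype = td$biotype[1L])
    }))
  })
  ann[order(names(ann))]
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: internal 0-based half-open exon/CDS intervals
#' are emitted as 1-based inclusive GTF features.
#'
#' @param annotation Named list of gene models.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  rows <- list()
  for (g in annotation) {
    for (tx in g$transcripts) {
      feat <- function(m, type) data.frame(
        chrom = tx$chrom, start = m[, 1L] + 1, end = m[, 2L],
        strand = tx$strand, type = type,
        phase = if (type == "CDS") 0L else NA_integer_,
        gene_id = tx$gene_id, transcript_id = tx$transcript_id,
        transcript_biotype = tx$biotype, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- feat(tx$exons, "exon")
      if (!is.null(tx$cds))
        rows[[length(rows) + 1L]] <- feat(tx$cds, "CDS")
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, phase = df$phase, gene_id = df$gene_id,
    transcript_id = df$transcript_id,
    transcript_biotype = df$transcript_biotype)
  S4Vectors::mcols(gr)$source <- "spliceswitch"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read an isoform-by-sample TPM matrix from TSV
#'
#' Expects a header row of sample ids with the first column holding isoform
#' ids.  Negative, missing, or non-numeric values and duplicated isoform
#' rows are rejected.
#'
#' @param path Path to the TSV file.
#' @param gene_map Named character vector mapping isoform ids to gene ids;
#'   isoforms absent from the map are an error.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, gene_map) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs isoform_id + >=1 sample column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated isoform row(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric TPM values in ", path)
  if (anyNA(m)) stop("missing TPM values in ", path)
  rownames(m) <- ids
  expr_matrix(m, gene_map)
}

#' Write an expression matrix to TSV
#' @param expr An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(isoform_id = rownames(expr$tpm), expr$tpm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Columns: `sample_id`, `patient_id`, `condition` (Baseline/DP).
#' @param path Path to the TSV file.
#' @return A validated [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sample_sheet(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Write a sample sheet to TSV
#' @param sheet A `sample_sheet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (`name<TAB>description<TAB>member...`).
#' @return Named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line with empty gene set: ", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description column.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = names(sets)) {
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), description, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read RBP binding sites from a BED6-like file
#'
#' BED intervals are kept 0-based half-open.  Column 4 holds the RBP name;
#' an optional seventh column names the target gene.
#'
#' @param path Path to a tab-separated BED file.
#' @return Data frame with columns `rbp_name`, `chrom`, `start`, `end`,
#'   `strand`, `target_gene`.
#' @export
read_bed_sites <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("need >=6 BED columns (chrom start end name score strand)")
  out <- data.frame(rbp_name = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    start = as.numeric(df[[2L]]), end = as.numeric(df[[3L]]),
                    strand = as.character(df[[6L]]),
                    target_gene = if (ncol(df) >= 7L)
                      as.character(df[[7L]]) else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("BED interval with start >= end")
  if (any(!out$strand %in% c("+", "-", ".")))
    stop("BED strand must be one of '+', '-', '.'")
  out
}

#' Write RBP binding sites as BED6(+1)
#' @param sites Data frame as returned by [read_bed_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_sites <- function(sites, path) {
  df <- data.frame(sites$chrom, format(sites$start, scientific = FALSE, trim = TRUE),
                   format(sites$end, scientific = FALSE, trim = TRUE),
                   sites$rbp_name, 0L, sites$strand,
                   stringsAsFactors = FALSE)
  if (!all(is.na(sites$target_gene))) df$target <- sites$target_gene
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (any(Biostrings::width(aa) == 0L))
    stop("empty sequence(s) in FASTA: ",
         paste(names(aa)[Biostrings::width(aa) == 0L], collapse = ", "))
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' Write protein sequences to FASTA
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read a protein domain table
#'
#' TSV with columns `protein_id`, `domain_name`, `start_aa`, `end_aa`
#' (1-based inclusive residue indices).
#'
#' @param path Path to the TSV file.
#' @return Validated data frame of domain annotations.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("domain table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_name", "start_aa", "end_aa")
  if (!all(need %in% names(df)))
    stop("domain table needs columns: ", paste(need, collapse = ", "))
  if (any(df$start_aa < 1L) || any(df$end_aa < df$start_aa))
    stop("domain intervals must satisfy 1 <= start_aa <= end_aa")
  df[need]
}

#' Write a protein domain table
#' @param domains Data frame with `protein_id`, `domain_name`, `start_aa`,
#'   `end_aa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  utils::write.table(domains, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
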