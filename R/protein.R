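# Protein-level consequence annotation: principal isoform selection,
# alignment-based isoform protein diffs, and domain impact.

#' Pick the principal isoform of a gene
#'
#' Uses an APPRIS-style principal table when provided; otherwise falls
#' back to the longest CDS, ties broken by longest transcript, then by
#' lexicographically smallest transcript id.
#'
#' @param gene A [gene_model()].
#' @param principal_table Optional data frame with columns `gene_id`,
#'   `transcript_id` marking principals.
#' @return The principal transcript id.
#' @export
principal_isoform <- function(gene, principal_table = NULL) {
  if (!is.null(principal_table)) {
    hit <- principal_table$transcript_id[
      principal_table$gene_id == gene$gene_id]
    hit <- intersect(hit, names(gene$transcripts))
    if (length(hit)) return(hit[1L])
  }
  len <- function(m) if (is.null(m)) 0 else sum(m[, 2L] - m[, 1L])
  cds_len <- vapply(gene$transcripts, function(tx) len(tx$cds), 0)
  tx_len <- vapply(gene$transcripts, function(tx) len(tx$exons), 0)
  ids <- names(gene$transcripts)
  ord <- order(-cds_len, -tx_len, ids)
  ids[ord[1L]]
}

#' Protein difference between principal and alternative isoform
#'
#' Global pairwise alignment (BLOSUM62 substitution scores, affine gaps)
#' of the two protein sequences; contiguous gap runs are reported as
#' deletion/insertion segments (1-based inclusive residue intervals on the
#' principal and alternative respectively) and mismatch runs as
#' substitutions.  The `frameshift` flag is raised when the alternative is
#' not reconstructable from the principal by removing/adding contiguous
#' blocks alone (i.e. when substitution runs are present).
#'
#' @param principal_seq,alternative_seq Non-empty amino-acid strings.
#' @param gap_opening,gap_extension Affine gap penalties (defaults 10 and
#'   0.5).
#' @return List of class `protein_diff`: `principal_length`,
#'   `alternative_length`, `segments` (data frame: `kind`,
#'   `principal_start`, `principal_end`, `alt_start`, `alt_end`,
#'   `length`), `frameshift`.
#' @export
diff_protein <- function(principal_seq, alternative_seq, gap_opening = 10,
                         gap_extension = 0.5) {
  if (!nzchar(principal_seq) || !nzchar(alternative_seq))
    stop("protein sequences must be non-empty")
  sm <- .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(alternative_seq),
    Biostrings::AAString(principal_seq),
    substitutionMatrix = sm, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  alt_al <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  pri_al <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  kind <- ifelse(alt_al == "-", "deletion",
                 ifelse(pri_al == "-", "insertion",
                        ifelse(alt_al == pri_al, "match", "substitution")))
  ppos <- cumsum(pri_al != "-")
  apos <- cumsum(alt_al != "-")
  r <- rle(kind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (i in seq_along(r$values)) {
    kv <- r$values[i]
    if (kv == "match") next
    s <- starts[i]; e <- ends[i]
    segs[[length(segs) + 1L]] <- data.frame(
      kind = kv,
      principal_start = if (kv == "insertion") NA_integer_ else ppos[s],
      principal_end = if (kv == "insertion") NA_integer_ else ppos[e],
      alt_start = if (kv == "deletion") NA_integer_ else apos[s],
      alt_end = if (kv == "deletion") NA_integer_ else apos[e],
      length = e - s + 1L, stringsAsFactors = FALSE)
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(kind = character(), principal_start = integer(),
               principal_end = integer(), alt_start = integer(),
               alt_end = integer(), length = integer(),
               stringsAsFactors = FALSE)
  structure(list(principal_length = nchar(principal_seq),
                 alternative_length = nchar(alternative_seq),
                 segments = segments,
                 frameshift = any(segments$kind == "substitution")),
            class = "protein_diff")
}

# BLOSUM62 without loading the data set into the user's global env
.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Reconstruct the alternative protein from a diff
#'
#' Applies the reported deletion and insertion segments to the principal
#' sequence; only defined when `frameshift` is `FALSE`.
#'
#' @param diff A `protein_diff`.
#' @param principal_seq The principal protein sequence.
#' @param alternative_seq The alternative protein sequence (source of
#'   inserted residues).
#' @return The reconstructed alternative sequence.
#' @export
apply_protein_diff <- function(diff, principal_seq, alternative_seq) {
  if (diff$frameshift)
    stop("reconstruction undefined when frameshift is TRUE")
  pri <- strsplit(principal_seq, "")[[1L]]
  alt <- strsplit(alternative_seq, "")[[1L]]
  keep <- rep(TRUE, length(pri))
  del <- diff$segments[diff$segments$kind == "deletion", , drop = FALSE]
  for (i in seq_len(nrow(del)))
    keep[del$principal_start[i]:del$principal_end[i]] <- FALSE
  out <- pri[keep]
  ins <- diff$segments[diff$segments$kind == "insertion", , drop = FALSE]
  # insert by alternative coordinates, left to right
  ins <- ins[order(ins$alt_start), , drop = FALSE]
  for (i in seq_len(nrow(ins))) {
    at <- ins$alt_start[i]
    out <- append(out, alt[ins$alt_start[i]:ins$alt_end[i]], after = at - 1L)
  }
  paste(out, collapse = "")
}

#' Domain impact of a protein diff
#'
#' For each annotated domain on the principal protein, counts the residues
#' removed by deletion segments.  Status is `lost` when the whole domain
#' is removed, `intact` when untouched, `truncated` otherwise.  A
#' frameshift forces every domain starting at or after the first altered
#' residue to `lost`.
#'
#' @param diff A `protein_diff` from [diff_protein()].
#' @param domains Data frame with `domain_name`, `start_aa`, `end_aa`
#'   (1-based inclusive, on the principal protein).
#' @return Data frame: `domain_name`, `start_aa`, `end_aa`, `overlap_aa`,
#'   `status`.
#' @export
domain_impact <- function(diff, domains) {
  del <- diff$segments[diff$segments$kind == "deletion", , drop = FALSE]
  fs_from <- if (diff$frameshift && nrow(diff$segments))
    min(diff$segments$principal_start, na.rm = TRUE) else Inf
  out <- do.call(rbind, lapply(seq_len(nrow(domains)), function(i) {
    s <- domains$start_aa[i]; e <- domains$end_aa[i]
    dlen <- e - s + 1L
    removed <- rep(FALSE, dlen)
    for (j in seq_len(nrow(del))) {
      lo <- max(s, del$principal_start[j]); hi <- min(e, del$principal_end[j])
      if (lo <= hi) removed[(lo - s + 1L):(hi - s + 1L)] <- TRUE
    }
    ov <- sum(removed)
    status <- if (s >= fs_from || ov == dlen) "lost"
              else if (ov == 0L) "intact" else "truncated"
    if (status == "lost") ov <- dlen
    data.frame(domain_name = domains$domain_name[i], start_aa = s,
               end_aa = e, overlap_aa = ov, status = status,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(domain_name = character(), start_aa = integer(),
                      end_aa = integer(), overlap_aa = integer(),
                      status = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Functional screening of retained differential isoforms
#'
#' The data-mining funnel applied after recurrence ranking and concordance
#' filtering: (1) keep protein-coding isoforms; (2) keep isoforms whose
#' protein diff against the gene's principal isoform loses or truncates at
#' least one annotated domain; (3) attach gene-set memberships; rank by
#' recurrence then concordance.  Principal isoforms themselves are not
#' screened (their diff is empty).
#'
#' @param records Recurrence records (after [concordance_filter()]).
#' @param annotation Named list of gene models.
#' @param proteins Named character vector of protein sequences by
#'   transcript id.
#' @param domains Data frame with `protein_id`, `domain_name`, `start_aa`,
#'   `end_aa` (principal-protein coordinates).
#' @param gene_sets Named list of gene sets (for the crossover column).
#' @param principal_table Optional APPRIS-style principal table.
#' @return Data frame: `isoform_id`, `gene_id`, `principal_isoform`,
#'   `recurrence`, `concordance`, `n_domains_lost`, `n_domains_truncated`,
#'   `gene_sets` (comma-separated memberships).
#' @export
functional_screen <- function(records, annotation, proteins, domains,
                              gene_sets = list(), principal_table = NULL) {
  gmap <- isoform_gene_map(annotation)
  out <- list()
  for (i in seq_len(nrow(records))) {
    iso <- records$isoform_id[i]
    g <- gmap[[iso]]
    if (is.null(g) || is.na(g)) next
    gene <- annotation[[g]]
    tx <- gene$transcripts[[iso]]
    # stage 1: protein-coding only
    if (tx$biotype != "protein_coding" || is.null(proteins[[iso]])) next
    pid <- principal_isoform(gene, principal_table)
    if (pid == iso) next
    if (is.null(proteins[[pid]])) next
    dm <- domains[domains$protein_id == pid, , drop = FALSE]
    if (nrow(dm) == 0L) next
    dif <- diff_protein(proteins[[pid]], proteins[[iso]])
    imp <- domain_impact(dif, dm)
    # stage 2: must disrupt at least one domain
    if (!any(imp$status %in% c("lost", "truncated"))) next
    memb <- names(gene_sets)[vapply(gene_sets, function(s) g %in% s, NA)]
    out[[length(out) + 1L]] <- data.frame(
      isoform_id = iso, gene_id = g, principal_isoform = pid,
      recurrence = records$recurrence[i],
      concordance = records$concordance[i],
      n_domains_lost = sum(imp$status == "lost"),
      n_domains_truncated = sum(imp$status == "truncated"),
      gene_sets = paste(memb, collapse = ","), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(isoform_id = character(), gene_id = character(),
                      principal_isoform = character(),
                      recurrence = integer(), concordance = integer(),
                      n_domains_lost = integer(),
                      n_domains_truncated = integer(),
                      gene_sets = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  out <- out[order(-out$recurrence, -abs(out$concordance), out$isoform_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
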