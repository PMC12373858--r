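# Ground-truthed synthetic cohort generator.  Emulates the matched-pair
# study design: ~21 patients each with one pre-treatment (Baseline) biopsy
# and 1-3 disease-progression (DP) biopsies (44 DP total), multi-isoform
# genes, a programmed reciprocal exon-skip switch in a subset of genes, a
# driver RNA-binding protein whose expression tracks switch manifestation,
# log-normal abundance noise, and decoy genes (including anti-correlated
# isoform pairs driven by pure noise) for false-positive control.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

# sample from the elements of x (safe for length-1 x)
.pick <- function(x, n = 1L, replace = FALSE) x[sample.int(length(x), n, replace = replace)]

#' Simulation configuration
#'
#' All abundance parameters are on the natural-log scale; TPM noise is
#' multiplicative log-normal.  Fractions are in `[0, 1]`.
#'
#' @param n_patients Number of patients (each contributes one Baseline).
#' @param n_dp Total number of DP biopsies across patients.
#' @param dp_per_patient Integer range of DP biopsies allowed per patient.
#' @param n_genes Number of simulated genes (switch + decoy).
#' @param isoforms_per_gene Integer range of isoforms per decoy gene.
#' @param switch_gene_fraction Fraction of genes carrying a programmed
#'   reciprocal exon-skip switch.
#' @param switch_penetrance Fraction of DP samples in which each switch
#'   manifests; every switch gene manifests in exactly
#'   `round(switch_penetrance * n_dp)` DP samples.
#' @param effect_size Multiplicative fold applied on manifestation: the
#'   exon-inclusion isoform is multiplied by `effect_size`, the skip
#'   isoform divided by it, before noise.
#' @param baseline_log_tpm_mean,baseline_log_tpm_sd Mean/sd of the
#'   per-isoform log-normal baseline abundance (natural log of TPM).
#' @param switch_tpm_range TPM range (log-uniform) for the baseline means of
#'   the two programmed switch isoforms; keeps planted switches above the
#'   expression floor at which isoform-level analysis is meaningful.
#' @param noise_sd Log-scale sd of per-sample multiplicative noise.
#' @param rbp_coupling Strength in `[0, 1]` coupling the driver RBP's
#'   expression to switch manifestation through a shared per-sample latent
#'   factor.
#' @param anti_corr_fraction Fraction of decoy genes given an
#'   anti-correlated isoform pair (shared noise factor with opposite sign).
#' @param cassette_aa Length in amino acids of the in-frame cassette-exon
#'   peptide (43 aa, i.e. a 129-nt exon, by default).
#' @param n_rbps Number of RBP genes (first one is the planted driver).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 21, n_dp = 44, dp_per_patient = c(1, 3),
                       n_genes = 400, isoforms_per_gene = c(2, 5),
                       switch_gene_fraction = 0.1, switch_penetrance = 0.5,
                       effect_size = 4,
                       baseline_log_tpm_mean = 4, baseline_log_tpm_sd = 1,
                       switch_tpm_range = c(20, 200),
                       noise_sd = 0.25, rbp_coupling = 0.8,
                       anti_corr_fraction = 0.1,
                       cassette_aa = 43, n_rbps = 6, seed = 1) {
  cfg <- list(n_patients = n_patients, n_dp = n_dp,
              dp_per_patient = dp_per_patient, n_genes = n_genes,
              isoforms_per_gene = isoforms_per_gene,
              switch_gene_fraction = switch_gene_fraction,
              switch_penetrance = switch_penetrance,
              effect_size = effect_size,
              baseline_log_tpm_mean = baseline_log_tpm_mean,
              baseline_log_tpm_sd = baseline_log_tpm_sd,
              switch_tpm_range = switch_tpm_range,
              noise_sd = noise_sd, rbp_coupling = rbp_coupling,
              anti_corr_fraction = anti_corr_fraction,
              cassette_aa = cassette_aa, n_rbps = n_rbps,
              seed = as.integer(seed))
  frac <- c(switch_gene_fraction, switch_penetrance, rbp_coupling,
            anti_corr_fraction)
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
  if (effect_size <= 1) stop("effect_size must be > 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (switch_gene_fraction > 0 && max(isoforms_per_gene) < 2)
    stop("switch genes need isoforms_per_gene to allow >= 2 isoforms")
  if (n_dp < n_patients * min(dp_per_patient) ||
      n_dp > n_patients * max(dp_per_patient))
    stop("n_dp unreachable with given dp_per_patient range")
  class(cfg) <- "sim_config"
  cfg
}

# random exon chain on the codon (3-nt) grid; all lengths multiples of 3
.exon_chain <- function(n_ex, base) {
  lens <- 3 * sample(30:100, n_ex, replace = TRUE)
  introns <- 3 * sample(30:400, max(n_ex - 1, 0), replace = TRUE)
  starts <- base + cumsum(c(0, lens[-n_ex] + introns))
  cbind(start = starts, end = starts + lens)
}

.derive_se <- function(ex) {
  if (nrow(ex) < 3L) return(NULL)
  j <- .pick(2:(nrow(ex) - 1L))
  ex[-j, , drop = FALSE]
}

.derive_ri <- function(ex) {
  if (nrow(ex) < 2L) return(NULL)
  j <- .pick(seq_len(nrow(ex) - 1L))
  merged <- c(ex[j, 1L], ex[j + 1L, 2L])
  rbind(ex[seq_len(j - 1L), , drop = FALSE], merged,
        ex[setdiff(seq_len(nrow(ex)), seq_len(j + 1L)), , drop = FALSE])
}

# shift the end of exon j (donor side on '+'); keeps a >= 3 nt intron
.derive_end_shift <- function(ex) {
  if (nrow(ex) < 2L) return(NULL)
  j <- .pick(seq_len(nrow(ex) - 1L))
  room_out <- (ex[j + 1L, 1L] - 3 - ex[j, 2L]) / 3
  room_in <- (ex[j, 2L] - ex[j, 1L] - 3) / 3
  deltas <- c(if (room_out >= 1) 3 * seq_len(min(room_out, 15)),
              if (room_in >= 1) -3 * seq_len(min(room_in, 15)))
  if (!length(deltas)) return(NULL)
  ex[j, 2L] <- ex[j, 2L] + .pick(deltas)
  ex
}

# shift the start of exon j (acceptor side on '+')
.derive_start_shift <- function(ex) {
  if (nrow(ex) < 2L) return(NULL)
  j <- .pick(2:nrow(ex))
  room_out <- (ex[j, 1L] - ex[j - 1L, 2L] - 3) / 3
  room_in <- (ex[j, 2L] - ex[j, 1L] - 3) / 3
  deltas <- c(if (room_out >= 1) -3 * seq_len(min(room_out, 15)),
              if (room_in >= 1) 3 * seq_len(min(room_in, 15)))
  if (!length(deltas)) return(NULL)
  ex[j, 1L] <- ex[j, 1L] + .pick(deltas)
  ex
}

# replace an internal exon by a new exon within a flanking intron
.derive_mxe <- function(ex) {
  if (nrow(ex) < 3L) return(NULL)
  for (j in .pick(2:(nrow(ex) - 1L), nrow(ex) - 2L)) {
    len <- 3 * sample(20:40, 1L)
    right_room <- ex[j + 1L, 1L] - ex[j, 2L] - 6
    left_room <- ex[j, 1L] - ex[j - 1L, 2L] - 6
    if (right_room >= len) {
      newx <- c(ex[j, 2L] + 3, ex[j, 2L] + 3 + len)
    } else if (left_room >= len) {
      newx <- c(ex[j, 1L] - 3 - len, ex[j, 1L] - 3)
    } else next
    out <- ex
    out[j, ] <- newx
    return(out[order(out[, 1L]), , drop = FALSE])
  }
  NULL
}

#' Simulate gene annotation, proteins and domain intervals
#'
#' Each switch gene gets two protein-coding isoforms identical except for
#' one in-frame cassette exon (129 nt = 43 aa by default), with a protein
#' domain interval overlapping the encoded peptide so that skipping
#' truncates the domain -- the architecture of a kinase activation-loop
#' cassette.  Decoy genes get 2-5 isoforms whose structures exercise all
#' five canonical event modes.  Proteins are read off a per-gene random
#' codon sequence so that isoform protein differences mirror exon
#' differences exactly.
#'
#' @param config A [sim_config()].
#' @return List with elements `annotation` (named list of gene models),
#'   `proteins` (named character, by transcript id), `domains` (data frame),
#'   `switch_genes`, `switch_isoforms` (data frame: gene_id,
#'   inclusion_isoform, skip_isoform), `skipped_exons` (data frame),
#'   `driver_rbp`, `rbp_genes`, `sites` (binding-site data frame),
#'   `gene_sets` (named list).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_switch <- round(config$n_genes * config$switch_gene_fraction)
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  switch_genes <- gene_ids[seq_len(n_switch)]
  cassette_nt <- 3 * config$cassette_aa

  annotation <- list()
  proteins <- character()
  domains <- list()
  switch_iso <- list()
  skipped <- list()

  for (i in seq_len(config$n_genes)) {
    gid <- gene_ids[i]
    chrom <- paste0("chr", ((i - 1L) %% 22L) + 1L)
    base <- 3 * (1e4 + ((i - 1L) %/% 22L) * 2e5)   # codon-grid gene start
    strand <- sample(c("+", "-"), 1L)
    is_switch <- gid %in% switch_genes

    if (is_switch) {
      n_ex <- sample(4:7, 1L)
      ex <- .exon_chain(n_ex, base)
      j <- .pick(2:(n_ex - 1L))
      ex[j, 2L] <- ex[j, 1L] + cassette_nt      # cassette exon, in-frame
      exlist <- list(ex, ex[-j, , drop = FALSE])
      names(exlist) <- paste0(gid, c(".t1", ".t2"))
      skipped[[gid]] <- data.frame(gene_id = gid, chrom = chrom,
                                   start = ex[j, 1L], end = ex[j, 2L],
                                   stringsAsFactors = FALSE)
      biotypes <- c("protein_coding", "protein_coding")
    } else {
      n_iso <- sample(config$isoforms_per_gene[1L]:config$isoforms_per_gene[2L], 1L)
      ex <- .exon_chain(sample(3:8, 1L), base)
      exlist <- list(ex)
      modes <- c("se", "ri", "end", "start", "mxe")
      while (length(exlist) < n_iso) {
        d <- switch(sample(modes, 1L),
                    se = .derive_se(ex), ri = .derive_ri(ex),
                    end = .derive_end_shift(ex), start = .derive_start_shift(ex),
                    mxe = .derive_mxe(ex))
        if (is.null(d)) next
        if (any(vapply(exlist, function(e) identical(unname(e), unname(d)), NA)))
          next
        exlist[[length(exlist) + 1L]] <- d
      }
      names(exlist) <- paste0(gid, ".t", seq_along(exlist))
      biotypes <- rep("protein_coding", n_iso)
      if (n_iso > 2L && stats::runif(1) < 0.2)
        biotypes[n_iso] <- "lncRNA"     # non-coding decoy isoform
    }

    # per-gene codon sequence; isoform proteins read off exon codons
    span_end <- max(vapply(exlist, function(e) max(e[, 2L]), 0))
    aa_vec <- sample(.AA20, (span_end - base) / 3, replace = TRUE)
    txs <- vector("list", length(exlist))
    for (k in seq_along(exlist)) {
      e <- exlist[[k]]
      coding <- biotypes[k] == "protein_coding"
      txs[[k]] <- transcript_model(names(exlist)[k], gid, chrom, strand, e,
                                   cds = if (coding) e else NULL,
                                   biotype = biotypes[k])
      if (coding) {
        idx <- unlist(lapply(seq_len(nrow(e)), function(r)
          seq((e[r, 1L] - base) / 3 + 1L, (e[r, 2L] - base) / 3)))
        if (strand == "-") idx <- rev(idx)
        proteins[[names(exlist)[k]]] <- paste(aa_vec[idx], collapse = "")
      }
    }
    annotation[[gid]] <- gene_model(txs)

    # domains on the principal (longest-CDS) isoform's protein
    coding_ids <- names(exlist)[biotypes == "protein_coding"]
    if (length(coding_ids)) {
      pid <- principal_isoform(annotation[[gid]])
      plen <- nchar(proteins[[pid]])
      if (is_switch) {
        # protein positions of the cassette codons within the principal
        e <- exlist[[1L]]
        idx <- unlist(lapply(seq_len(nrow(e)), function(r)
          seq((e[r, 1L] - base) / 3 + 1L, (e[r, 2L] - base) / 3)))
        if (strand == "-") idx <- rev(idx)
        cass <- skipped[[gid]]
        cas_idx <- seq((cass$start - base) / 3 + 1L, (cass$end - base) / 3)
        pos <- sort(match(cas_idx, idx))
        domains[[length(domains) + 1L]] <- data.frame(
          protein_id = pid, domain_name = "Kinase_dom",
          start_aa = max(1L, min(pos) - 10L),
          end_aa = min(plen, max(pos) + 7L), stringsAsFactors = FALSE)
        incl <- names(exlist)[1L]
        skp <- names(exlist)[2L]
        switch_iso[[gid]] <- data.frame(
          gene_id = gid, inclusion_isoform = incl, skip_isoform = skp,
          stringsAsFactors = FALSE)
      } else if (plen > 30L) {
        for (d in seq_len(sample(1:2, 1L))) {
          s <- sample(seq_len(plen - 20L), 1L)
          domains[[length(domains) + 1L]] <- data.frame(
            protein_id = pid,
            domain_name = sprintf("Dom_%s_%d", gid, d),
            start_aa = s, end_aa = min(plen, s + sample(15:60, 1L)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  # RBP genes: single-isoform, first is the planted driver
  rbp_genes <- sprintf("RBP%02d", seq_len(config$n_rbps))
  target <- if (length(switch_genes)) switch_genes[1L] else gene_ids[1L]
  for (j in seq_along(rbp_genes)) {
    rid <- rbp_genes[j]
    base <- 3 * (1e4 + 3e7 + j * 2e5)
    ex <- .exon_chain(sample(3:5, 1L), base)
    tx <- transcript_model(paste0(rid, ".t1"), rid, "chr23p", "+", ex,
                           cds = ex, biotype = "protein_coding")
    annotation[[rid]] <- gene_model(list(tx))
    aa_vec <- sample(.AA20, (max(ex[, 2L]) - base) / 3, replace = TRUE)
    idx <- unlist(lapply(seq_len(nrow(ex)), function(r)
      seq((ex[r, 1L] - base) / 3 + 1L, (ex[r, 2L] - base) / 3)))
    proteins[[paste0(rid, ".t1")]] <- paste(aa_vec[idx], collapse = "")
  }

  # binding sites: every RBP has >= 1 site in the target switch-gene locus
  # (the expression-correlation stage, not site overlap, discriminates the
  # driver); plus background sites elsewhere
  tspan <- gene_span(annotation[[target]])
  tchrom <- annotation[[target]]$chrom
  tstrand <- annotation[[target]]$strand
  sites <- list()
  for (j in seq_along(rbp_genes)) {
    n_in <- if (j == 1L) 2L else sample(1:2, 1L)
    for (s in seq_len(n_in)) {
      st <- sample(seq(tspan[1L], tspan[2L] - 20L), 1L)
      sites[[length(sites) + 1L]] <- data.frame(
        rbp_name = rbp_genes[j], chrom = tchrom, start = st, end = st + 20L,
        strand = tstrand, target_gene = target, stringsAsFactors = FALSE)
    }
    og <- sample(setdiff(gene_ids, target), 1L)
    osp <- gene_span(annotation[[og]])
    st <- sample(seq(osp[1L], osp[2L] - 20L), 1L)
    sites[[length(sites) + 1L]] <- data.frame(
      rbp_name = rbp_genes[j], chrom = annotation[[og]]$chrom,
      start = st, end = st + 20L, strand = annotation[[og]]$strand,
      target_gene = og, stringsAsFactors = FALSE)
  }

  nonswitch <- setdiff(gene_ids, switch_genes)
  gene_sets <- list(
    switch_program = unique(c(switch_genes,
                              .pick(nonswitch, min(10L, length(nonswitch))))))
  for (k in 1:4)
    gene_sets[[sprintf("pathway_%d", k)]] <-
      .pick(gene_ids, min(40L, length(gene_ids)))

  list(annotation = annotation, proteins = proteins,
       domains = do.call(rbind, domains),
       switch_genes = switch_genes,
       switch_isoforms = do.call(rbind, switch_iso),
       skipped_exons = do.call(rbind, skipped),
       driver_rbp = rbp_genes[1L], rbp_genes = rbp_genes,
       target_gene = target,
       sites = do.call(rbind, sites), gene_sets = gene_sets)
}

#' Simulate the expression matrix, sample sheet and ground truth
#'
#' Baseline abundances are log-normal per isoform; each manifested
#' (switch gene, DP sample) combination multiplies the inclusion isoform by
#' `effect_size` and divides the skip isoform by it before multiplicative
#' log-normal noise.  Every switch gene manifests in exactly
#' `round(switch_penetrance * n_dp)` DP samples, chosen with weights tied
#' to a per-sample latent factor that also elevates the driver RBP's
#' expression (strength `rbp_coupling`).
#'
#' @param config A [sim_config()].
#' @param ann Result of [simulate_annotation()].
#' @return List with `expr` (an [expr_matrix()]), `sheet`
#'   (a [sample_sheet()]), and `truth` (list: `switch_genes`,
#'   `manifestations` data frame over all (switch gene, DP sample) pairs,
#'   `driver_rbp`, `skipped_exons`, `switch_isoforms`, `latent`).
#' @export
simulate_expression <- function(config, ann) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)

  # sample sheet: 1 Baseline per patient, dp counts in range summing to n_dp
  pats <- sprintf("P%02d", seq_len(config$n_patients))
  lo <- min(config$dp_per_patient); hi <- max(config$dp_per_patient)
  counts <- .pick(lo:hi, config$n_patients, replace = TRUE)
  while (sum(counts) != config$n_dp) {
    i <- sample(config$n_patients, 1L)
    if (sum(counts) > config$n_dp && counts[i] > lo) counts[i] <- counts[i] - 1L
    if (sum(counts) < config$n_dp && counts[i] < hi) counts[i] <- counts[i] + 1L
  }
  sheet <- rbind(
    data.frame(sample_id = paste0(pats, "_B"), patient_id = pats,
               condition = "Baseline", stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_along(pats), function(i)
      if (counts[i] > 0L) data.frame(
        sample_id = paste0(pats[i], "_DP", seq_len(counts[i])),
        patient_id = pats[i], condition = "DP", stringsAsFactors = FALSE))))
  sheet <- sample_sheet(sheet)
  dp_samples <- sheet$sample_id[sheet$condition == "DP"]
  all_samples <- sheet$sample_id

  iso_ids <- unlist(lapply(ann$annotation, function(g) names(g$transcripts)))
  gmap <- isoform_gene_map(ann$annotation)

  # per-isoform baseline means; programmed switch isoforms drawn from a
  # log-uniform range above the analysis' expression floor
  mu <- exp(stats::rnorm(length(iso_ids), config$baseline_log_tpm_mean,
                         config$baseline_log_tpm_sd))
  names(mu) <- iso_ids
  if (!is.null(ann$switch_isoforms)) {
    sw_iso <- c(ann$switch_isoforms$inclusion_isoform,
                ann$switch_isoforms$skip_isoform)
    mu[sw_iso] <- exp(stats::runif(length(sw_iso),
                                   log(config$switch_tpm_range[1L]),
                                   log(config$switch_tpm_range[2L])))
  }

  # latent per-DP-sample switch drive; manifestation = top-k scoring samples
  latent <- stats::rnorm(length(dp_samples))
  names(latent) <- dp_samples
  k_manifest <- round(config$switch_penetrance * length(dp_samples))
  manifest <- matrix(FALSE, nrow = length(ann$switch_genes),
                     ncol = length(dp_samples),
                     dimnames = list(ann$switch_genes, dp_samples))
  for (g in ann$switch_genes) {
    score <- config$rbp_coupling * latent +
      sqrt(max(0, 1 - config$rbp_coupling^2)) * stats::rnorm(length(dp_samples))
    if (k_manifest > 0L)
      manifest[g, order(score, decreasing = TRUE)[seq_len(k_manifest)]] <- TRUE
  }

  # mean matrix: baseline mean everywhere, switch effects in manifested DPs
  m <- matrix(rep(mu, length(all_samples)), nrow = length(iso_ids),
              dimnames = list(iso_ids, all_samples))
  if (!is.null(ann$switch_isoforms)) {
    for (r in seq_len(nrow(ann$switch_isoforms))) {
      g <- ann$switch_isoforms$gene_id[r]
      ds <- dp_samples[manifest[g, ]]
      m[ann$switch_isoforms$inclusion_isoform[r], ds] <-
        m[ann$switch_isoforms$inclusion_isoform[r], ds] * config$effect_size
      m[ann$switch_isoforms$skip_isoform[r], ds] <-
        m[ann$switch_isoforms$skip_isoform[r], ds] / config$effect_size
    }
  }

  # driver RBP tracks the latent switch drive in DP samples
  drv <- paste0(ann$driver_rbp, ".t1")
  m[drv, dp_samples] <- m[drv, dp_samples] *
    exp(config$rbp_coupling * latent)

  # multiplicative log-normal noise
  tpm <- m * exp(matrix(stats::rnorm(length(m), 0, config$noise_sd),
                        nrow = nrow(m)))

  # anti-correlated decoy isoform pairs driven by pure noise
  decoys <- setdiff(names(ann$annotation),
                    c(ann$switch_genes, ann$rbp_genes))
  n_anti <- round(length(decoys) * config$anti_corr_fraction)
  anti_genes <- if (n_anti > 0L) sample(decoys, n_anti) else character()
  for (g in anti_genes) {
    iso <- names(ann$annotation[[g]]$transcripts)
    if (length(iso) < 2L) next
    pairx <- sample(iso, 2L)
    f <- stats::rnorm(length(all_samples), 0, config$noise_sd)
    tpm[pairx[1L], ] <- tpm[pairx[1L], ] * exp(f)
    tpm[pairx[2L], ] <- tpm[pairx[2L], ] * exp(-f)
  }

  manif_df <- expand.grid(gene_id = ann$switch_genes, dp_sample = dp_samples,
                          stringsAsFactors = FALSE)
  manif_df$manifested <- mapply(function(g, s) manifest[g, s],
                                manif_df$gene_id, manif_df$dp_sample)
  manif_df <- manif_df[order(manif_df$gene_id, manif_df$dp_sample), ]
  rownames(manif_df) <- NULL

  list(expr = expr_matrix(tpm, gmap), sheet = sheet,
       truth = list(switch_genes = ann$switch_genes,
                    manifestations = manif_df,
                    driver_rbp = ann$driver_rbp,
                    skipped_exons = ann$skipped_exons,
                    switch_isoforms = ann$switch_isoforms,
                    latent = latent,
                    anti_corr_genes = anti_genes))
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_annotation()] then
#' [simulate_expression()].
#'
#' @param config A [sim_config()].
#' @return List combining both results (annotation bundle plus `expr`,
#'   `sheet`, `truth`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  ann <- simulate_annotation(config)
  ex <- simulate_expression(config, ann)
  c(ann, ex)
}

#' Write a simulated cohort to disk
#'
#' Emits every input format the pipeline reads (GTF, expression TSV, sample
#' sheet, protein FASTA, domain TSV, binding-site BED, GMT) plus ground
#' truth tables documenting every injected switch.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gtf(cohort$annotation, p("annotation.gtf"))
  write_expression_matrix(cohort$expr, p("expression.tsv"))
  write_sample_sheet(cohort$sheet, p("samples.tsv"))
  write_fasta(cohort$proteins, p("proteins.fasta"))
  write_domain_table(cohort$domains, p("domains.tsv"))
  write_bed_sites(cohort$sites, p("rbp_sites.bed"))
  write_gmt(cohort$gene_sets, p("gene_sets.gmt"))
  utils::write.table(cohort$truth$manifestations, p("truth_manifestations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = cohort$truth$switch_genes,
               driver_rbp = cohort$truth$driver_rbp),
    p("truth_switch_genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gtf = p("annotation.gtf"), expression = p("expression.tsv"),
              samples = p("samples.tsv"), proteins = p("proteins.fasta"),
              domains = p("domains.tsv"), sites = p("rbp_sites.bed"),
              gene_sets = p("gene_sets.gmt"),
              truth = p("truth_manifestations.tsv")))
}
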