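# Reciprocal switch detection, fold-change/dPSI correlation, principal
# isoform selection, protein diffs and domain impact.

test_that("reciprocal recurrence is the per-pair call intersection", {
  pairs <- data.frame(pair_id = sprintf("p%02d", 1:44))
  calls <- rbind(
    data.frame(isoform_id = "up", pair_id = sprintf("p%02d", 1:15),
               direction = "up"),
    data.frame(isoform_id = "dn", pair_id = sprintf("p%02d", 3:24),
               direction = "down"))
  r <- reciprocal_recurrence("up", "dn", calls, pairs)
  expect_equal(r$n_reciprocal_pairs, 13L)   # |{3..15}|
  expect_equal(r$percentage, 29.55)
  # disjoint call sets
  calls2 <- calls; calls2$pair_id[calls2$isoform_id == "dn"] <-
    sprintf("p%02d", 21:42)
  expect_equal(reciprocal_recurrence("up", "dn", calls2,
                                     pairs)$n_reciprocal_pairs, 0L)
  # identical call sets of size 5
  calls3 <- rbind(
    data.frame(isoform_id = "up", pair_id = sprintf("p%02d", 1:5),
               direction = "up"),
    data.frame(isoform_id = "dn", pair_id = sprintf("p%02d", 1:5),
               direction = "down"))
  r3 <- reciprocal_recurrence("up", "dn", calls3, pairs)
  expect_equal(r3$n_reciprocal_pairs, 5L)
  expect_equal(r3$percentage, 11.36)
  # bounded by the marginal recurrences
  expect_lte(r$n_reciprocal_pairs, 15L)
  expect_lte(r$n_reciprocal_pairs, 22L)
})

test_that("switch candidates require strong negative correlation", {
  co <- simulate_cohort(sim_config(n_genes = 30, noise_sd = 0.1, seed = 19))
  pairs <- make_pairs(co$sheet)
  calls <- call_dei(co$expr, pairs)
  lfc <- log2fc_matrix(co$expr, pairs)
  sw <- co$truth$switch_isoforms
  for (i in seq_len(min(3, nrow(sw)))) {
    res <- switch_candidates(sw$gene_id[i], lfc, co$expr$isoform_to_gene,
                             calls, pairs)
    expect_equal(nrow(res$candidates), 1L)
    expect_lte(res$candidates$pearson_r, -0.9)
    expect_equal(res$candidates$up_isoform, sw$inclusion_isoform[i])
    expect_equal(res$candidates$down_isoform, sw$skip_isoform[i])
  }
  # independent noise isoforms are not emitted at |r| >= 0.5
  decoy <- setdiff(unique(co$expr$isoform_to_gene),
                   c(co$truth$switch_genes, co$truth$anti_corr_genes,
                     paste0("RBP0", 1:6)))
  n_emitted <- sum(vapply(decoy, function(g)
    nrow(switch_candidates(g, lfc, co$expr$isoform_to_gene, calls,
                           pairs)$candidates), 0L))
  expect_lte(n_emitted, 1L)
  # exactly opposite vectors give r = -1
  lfc2 <- rbind(a = c(1, -2, 3, 0.5), b = -c(1, -2, 3, 0.5))
  colnames(lfc2) <- pairs$pair_id[1:4]
  res2 <- switch_candidates("gx", lfc2, c(a = "gx", b = "gx"), calls[0, ],
                            pairs[1:4, ])
  expect_equal(res2$candidates$pearson_r, -1)
  # constant vectors are skipped with a reason
  lfc3 <- rbind(a = rep(2, 4), b = c(1, 2, 3, 4))
  colnames(lfc3) <- pairs$pair_id[1:4]
  res3 <- switch_candidates("gx", lfc3, c(a = "gx", b = "gx"), calls[0, ],
                            pairs[1:4, ])
  expect_equal(nrow(res3$candidates), 0L)
  expect_match(res3$skipped$reason, "constant")
})

test_that("detector recovers planted switches on the default cohort", {
  co <- simulate_cohort(sim_config(seed = 2))
  pairs <- make_pairs(co$sheet)
  sw <- detect_switches(co$expr, pairs)
  truth <- co$truth$switch_genes
  detected <- unique(sw$gene_id)
  expect_gte(mean(truth %in% detected), 0.9)
  expect_gte(mean(detected %in% truth), 0.9)
  # detected orientation matches the planted inclusion/skip isoforms
  tsw <- co$truth$switch_isoforms
  hits <- merge(sw, tsw, by = "gene_id")
  expect_true(all(hits$up_isoform == hits$inclusion_isoform &
                    hits$down_isoform == hits$skip_isoform))
})

test_that("fc/dPSI correlation matches hand-computed Pearson", {
  r <- correlate_fc_dpsi(c(1, 2, 3), c(1, 2, 2))
  expect_equal(r$r, sqrt(3) / 2, tolerance = 1e-6)
  expect_equal(r$r, 0.8660, tolerance = 1e-4)
  expect_equal(r$n, 3L)
  perfect <- correlate_fc_dpsi(c(0.3, 1.1, 2.2, 4.0), 2 * c(0.3, 1.1, 2.2, 4.0))
  expect_equal(perfect$r, 1)
  expect_error(correlate_fc_dpsi(c(1, NA, NA, 2), c(NA, 1, 2, NA)),
               "fewer than 3")
  # log2FC of the inclusion isoform tracks the cassette dPSI on a cohort
  co <- simulate_cohort(sim_config(n_genes = 30, seed = 23))
  pairs <- make_pairs(co$sheet)
  lfc <- log2fc_matrix(co$expr, pairs)
  sk <- co$truth$skipped_exons[1, ]
  psi <- exon_psi(co$annotation[[sk$gene_id]], c(sk$start, sk$end), co$expr)
  dpsi <- psi[pairs$dp_sample] - psi[pairs$baseline_sample]
  res <- correlate_fc_dpsi(lfc[co$truth$switch_isoforms$inclusion_isoform[1], ],
                           unname(dpsi))
  expect_gt(res$r, 0.4)
  expect_lt(res$p_value, 0.05)
})

test_that("principal isoform prefers table, then CDS length, then id", {
  g <- gene_model(list(
    tx("tB", "g", rbind(c(0, 900)), cds = rbind(c(0, 900))),
    tx("tA", "g", rbind(c(0, 1029)), cds = rbind(c(0, 1029)))))
  expect_equal(principal_isoform(g), "tA")    # longer CDS
  tab <- data.frame(gene_id = "g", transcript_id = "tB")
  expect_equal(principal_isoform(g, tab), "tB")
  # CDS tie -> lexicographically smaller id
  g2 <- gene_model(list(
    tx("tB", "g", rbind(c(0, 900)), cds = rbind(c(0, 900))),
    tx("tA", "g", rbind(c(0, 900)), cds = rbind(c(0, 900)))))
  expect_equal(principal_isoform(g2), "tA")
})

test_that("protein diff reports contiguous in-frame blocks", {
  set.seed(7)
  aa <- paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N",
                       "P","Q","R","S","T","V","W","Y"), 481, TRUE),
              collapse = "")
  # remove a contiguous 43-aa block
  alt <- paste0(substr(aa, 1, 150), substr(aa, 194, 481))
  d <- diff_protein(aa, alt)
  expect_false(d$frameshift)
  expect_equal(nrow(d$segments), 1L)
  expect_equal(d$segments$kind, "deletion")
  expect_equal(d$segments$principal_end - d$segments$principal_start + 1L, 43L)
  # identical sequences -> empty segment list
  expect_equal(nrow(diff_protein(aa, aa)$segments), 0L)
  # N-terminal truncation
  d2 <- diff_protein(aa, substr(aa, 11, 481))
  expect_equal(nrow(d2$segments), 1L)
  expect_equal(c(d2$segments$principal_start, d2$segments$principal_end),
               c(1L, 10L))
  # inverse consistency: applying the diff reconstructs the alternative
  for (alt_seq in list(alt, substr(aa, 11, 481),
                       paste0(substr(aa, 1, 100), "WWWWWW",
                              substr(aa, 101, 481)))) {
    dd <- diff_protein(aa, alt_seq)
    if (!dd$frameshift)
      expect_equal(apply_protein_diff(dd, aa, alt_seq), alt_seq)
  }
})

test_that("domain impact partitions domains by deletion overlap", {
  d <- structure(list(
    principal_length = 300L, alternative_length = 257L,
    segments = data.frame(kind = "deletion", principal_start = 150L,
                          principal_end = 192L, alt_start = NA_integer_,
                          alt_end = NA_integer_, length = 43L),
    frameshift = FALSE), class = "protein_diff")
  doms <- data.frame(domain_name = c("kin", "far", "inside"),
                     start_aa = c(100, 210, 155), end_aa = c(200, 260, 180))
  imp <- domain_impact(d, doms)
  expect_equal(imp$status, c("truncated", "intact", "lost"))
  expect_equal(imp$overlap_aa, c(43L, 0L, 26L))
  expect_true(all(imp$overlap_aa <= imp$end_aa - imp$start_aa + 1L))
  # deletion covering the whole domain
  doms2 <- data.frame(domain_name = "d", start_aa = 100, end_aa = 200)
  d2 <- d; d2$segments$principal_start <- 90L; d2$segments$principal_end <- 210L
  expect_equal(domain_impact(d2, doms2)$status, "lost")
  expect_equal(domain_impact(d2, doms2)$overlap_aa, 101L)
  # frameshift forces downstream domains lost
  d3 <- d; d3$frameshift <- TRUE
  imp3 <- domain_impact(d3, doms)
  expect_equal(imp3$status[imp3$domain_name == "far"], "lost")
})

test_that("functional screen keeps coding domain-disrupting switch isoforms", {
  co <- simulate_cohort(sim_config(n_genes = 40, seed = 29))
  pairs <- make_pairs(co$sheet)
  calls <- call_dei(co$expr, pairs)
  rec <- recurrence(calls, pairs)
  kept <- concordance_filter(rec, 6)
  scr <- functional_screen(kept, co$annotation, co$proteins, co$domains,
                           co$gene_sets)
  # every injected switch's skip isoform survives the funnel
  expect_true(all(co$truth$switch_isoforms$skip_isoform %in% scr$isoform_id))
  # non-coding isoforms never survive stage 1
  gmap <- isoform_gene_map(co$annotation)
  noncoding <- names(gmap)[vapply(names(gmap), function(i)
    co$annotation[[gmap[[i]]]]$transcripts[[i]]$biotype != "protein_coding",
    NA)]
  expect_false(any(noncoding %in% scr$isoform_id))
  # switch genes are annotated as members of the planted program set
  swrows <- scr[scr$gene_id %in% co$truth$switch_genes, ]
  expect_true(all(grepl("switch_program", swrows$gene_sets)))
})
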