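# Event classification against forced examples and the brute-force
# oracle; PSI computation and differential PSI testing.

test_that("cassette exon yields one SE event with correct support sets", {
  ev <- classify_events(toy_gene_se())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$mode, "SE")
  expect_equal(ev$coordinates, "[100,200);[300,400);[500,600)")
  expect_equal(ev$inclusion_isoforms[[1]], "t1")
  expect_equal(ev$exclusion_isoforms[[1]], "t2")
})

test_that("retained intron is recognized from a merged exon", {
  g <- gene_model(list(
    tx("t1", "g", rbind(c(100, 200), c(300, 400))),
    tx("t2", "g", rbind(c(100, 400)))))
  ev <- classify_events(g)
  expect_equal(ev$mode, "RI")
  expect_equal(ev$coordinates, "[100,400);[100,200);[300,400)")
  expect_equal(ev$inclusion_isoforms[[1]], "t2")   # intron retained
})

test_that("donor/acceptor shift naming is strand-aware", {
  mk <- function(strand) gene_model(list(
    tx("t1", "g", rbind(c(100, 250), c(300, 400)), strand),
    tx("t2", "g", rbind(c(100, 200), c(300, 400)), strand)))
  expect_equal(classify_events(mk("+"))$mode, "A5SS")
  expect_equal(classify_events(mk("-"))$mode, "A3SS")
  # mirrored on the acceptor side
  mk2 <- function(strand) gene_model(list(
    tx("t1", "g", rbind(c(100, 200), c(250, 400)), strand),
    tx("t2", "g", rbind(c(100, 200), c(300, 400)), strand)))
  expect_equal(classify_events(mk2("+"))$mode, "A3SS")
  expect_equal(classify_events(mk2("-"))$mode, "A5SS")
})

test_that("mutually exclusive exons require exclusivity across the gene", {
  g <- gene_model(list(
    tx("t1", "g", rbind(c(0, 30), c(60, 90), c(200, 230))),
    tx("t2", "g", rbind(c(0, 30), c(120, 150), c(200, 230)))))
  ev <- classify_events(g)
  expect_equal(ev$mode, "MXE")
  expect_equal(ev$coordinates, "[0,30);[60,90);[120,150);[200,230)")
  # a third transcript containing both middle exons removes the event
  g2 <- gene_model(list(g$transcripts$t1, g$transcripts$t2,
                        tx("t3", "g", rbind(c(0, 30), c(60, 90),
                                            c(120, 150), c(200, 230)))))
  expect_false("MXE" %in% classify_events(g2)$mode)
  # single-transcript gene -> no events, no error
  expect_equal(nrow(classify_events(gene_model(list(g$transcripts$t1)))), 0L)
})

test_that("strand flip swaps A5SS and A3SS and fixes SE/RI/MXE", {
  set.seed(404)
  for (i in 1:40) {
    g <- random_gene(sprintf("g%d", i))
    flipped <- gene_model(lapply(g$transcripts, function(t) {
      t$strand <- if (t$strand == "+") "-" else "+"
      t
    }))
    a <- table(factor(classify_events(g)$mode,
                      levels = c("SE", "A5SS", "A3SS", "RI", "MXE")))
    b <- table(factor(classify_events(flipped)$mode,
                      levels = c("SE", "A5SS", "A3SS", "RI", "MXE")))
    expect_equal(unname(a[c("SE", "RI", "MXE")]),
                 unname(b[c("SE", "RI", "MXE")]))
    expect_equal(unname(a["A5SS"]), unname(b["A3SS"]))
    expect_equal(unname(a["A3SS"]), unname(b["A5SS"]))
  }
})

test_that("PSI is inclusion TPM over total with missing on zero total", {
  g <- toy_gene_se()
  tpm <- rbind(t1 = c(30, 40, 0), t2 = c(10, 0, 0))
  colnames(tpm) <- c("s1", "s2", "s3")
  ex <- expr_matrix(tpm, c(t1 = "g1", t2 = "g1"))
  ev <- classify_events(g)
  psi <- compute_psi(ev[1, ], ex)
  expect_equal(psi$psi, c(0.75, 1, NA))
  expect_equal(psi$inclusion_tpm + c(10, 0, 0), psi$total_tpm)
  # exon-level PSI agrees for the cassette exon
  ep <- exon_psi(g, c(300, 400), ex)
  expect_equal(unname(ep), c(0.75, 1, NA))
})

test_that("PSI stays in [0,1] wherever defined on simulated cohorts", {
  co <- simulate_cohort(sim_config(n_genes = 25, seed = 31))
  ev <- classify_events_all(co$annotation)
  psi <- compute_psi_all(ev, co$expr)
  ok <- !is.na(psi$psi)
  expect_true(all(psi$psi[ok] >= 0 & psi$psi[ok] <= 1))
  expect_true(all(psi$inclusion_tpm[ok] <= psi$total_tpm[ok] + 1e-9))
})

test_that("event testing applies the double significance gate", {
  # three events: real shift, tiny shift with tiny p, zero shift
  sheet <- toy_sheet(5, rep(1, 5))
  pairs <- make_pairs(sheet)
  samples <- c(paste0(sprintf("P%02d", 1:5), "_B"),
               paste0(sprintf("P%02d", 1:5), "_DP1"))
  mk_psi <- function(id, b, d) data.frame(
    event_id = id, sample_id = samples, psi = c(b, d))
  psis <- rbind(
    mk_psi("big", rep(0.2, 5), c(0.62, 0.60, 0.61, 0.63, 0.60)),
    mk_psi("small", rep(0.20, 5), c(0.290, 0.291, 0.290, 0.292, 0.291)),
    mk_psi("null", rep(0.5, 5), rep(0.5, 5)))
  res <- test_events(psis, pairs)
  expect_true(res$significant[res$event_id == "big"])
  # mean dPSI 0.09 < 0.1 fails the magnitude gate despite minute p
  expect_lt(res$q_value[res$event_id == "small"], 0.001)
  expect_false(res$significant[res$event_id == "small"])
  expect_false(res$significant[res$event_id == "null"])
  # fewer than 3 informative pairs -> untested, not p = 1
  psis_na <- mk_psi("thin", c(0.1, 0.1, NA, NA, NA), c(0.9, 0.9, NA, NA, NA))
  res2 <- test_events(psis_na, pairs)
  expect_false(res2$tested)
  expect_true(is.na(res2$p_value))
})

test_that("planted exon-skip switches are significant SE events", {
  co <- simulate_cohort(sim_config(n_genes = 40, noise_sd = 0,
                                   switch_penetrance = 1, seed = 12))
  pairs <- make_pairs(co$sheet)
  ev <- classify_events_all(co$annotation)
  psi <- compute_psi_all(ev, co$expr)
  res <- test_events(psi, pairs)
  sig <- res$event_id[res$significant]
  modes <- ev$mode[match(sig, ev$event_id)]
  expect_true(all(modes == "SE"))
  # every switch gene's cassette event is significant with positive dPSI
  for (i in seq_len(nrow(co$truth$skipped_exons))) {
    sk <- co$truth$skipped_exons[i, ]
    evg <- ev[ev$gene_id == sk$gene_id & ev$mode == "SE", ]
    hit <- grepl(sprintf("[%d,%d)", sk$start, sk$end), evg$coordinates,
                 fixed = TRUE)
    expect_true(any(hit))
    rid <- evg$event_id[hit][1]
    expect_true(res$significant[res$event_id == rid])
    expect_gt(res$mean_dpsi[res$event_id == rid], 0.1)
  }
  # SE is the modal class among significant events
  dist <- event_mode_distribution(ev[ev$event_id %in% sig, ])
  expect_equal(names(dist)[which.max(dist)], "SE")
})

test_that("mode distribution sums to one and handles empty input", {
  d <- event_mode_distribution(data.frame(mode = c("SE", "SE", "SE", "RI")))
  expect_equal(unname(d["SE"]), 0.75)
  expect_equal(unname(d["RI"]), 0.25)
  expect_equal(sum(d), 1)
  expect_length(event_mode_distribution(data.frame(mode = character())), 0)
})

test_that("BH q-values are monotone in p rank", {
  set.seed(1)
  p <- runif(50)
  q <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})
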