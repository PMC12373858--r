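# Differential isoform calling, recurrence ranking, concordance filter,
# sharing, diversity and the paired test.

mk_expr <- function(tpm) {
  gm <- setNames(rep("g1", nrow(tpm)), rownames(tpm))
  expr_matrix(tpm, gm)
}

test_that("pairs are one per DP sample, sharing the patient baseline", {
  sh <- toy_sheet(n_pat = 2, dp = c(1, 3))
  p <- make_pairs(sh)
  expect_equal(nrow(p), 4L)
  expect_equal(sum(p$baseline_sample == "P02_B"), 3L)
  # a valid 21/44 sheet yields 44 pairs
  co <- simulate_cohort(sim_config(n_genes = 5, seed = 1))
  expect_equal(nrow(make_pairs(co$sheet)), 44L)
  # no DP samples -> empty pair list
  base_only <- sample_sheet(data.frame(sample_id = "b", patient_id = "P1",
                                       condition = "Baseline"))
  expect_equal(nrow(make_pairs(base_only)), 0L)
})

test_that("fold-change cutoff |1-FC| > 0.2 is applied on the raw scale", {
  tpm <- rbind(i1 = c(10, 13), i2 = c(10, 11), i3 = c(8, 9), i4 = c(10, 7))
  colnames(tpm) <- c("P01_B", "P01_DP1")
  ex <- mk_expr(tpm)
  p <- make_pairs(toy_sheet(1, 1))
  calls <- call_dei_pair(ex, p, pseudocount = 0)
  expect_equal(calls$isoform_id, c("i1", "i4"))
  expect_equal(calls$direction, c("up", "down"))
  expect_equal(calls$fc[1], 1.3)
  # i2: |1 - 1.1| = 0.1, no call; i3 fails the TPM >= 10 filter entirely
  expect_false("i2" %in% calls$isoform_id)
  expect_false("i3" %in% calls$isoform_id)
  # zero baseline with zero pseudocount is an up call, not an error
  tpm0 <- rbind(i1 = c(0, 15)); colnames(tpm0) <- c("P01_B", "P01_DP1")
  c0 <- call_dei_pair(mk_expr(tpm0), p, pseudocount = 0)
  expect_equal(c0$direction, "up")
  expect_true(is.infinite(c0$fc))
})

test_that("swapping baseline and DP flips every finite-FC call", {
  co <- simulate_cohort(sim_config(n_genes = 25, seed = 5))
  p <- make_pairs(co$sheet)
  fwd <- call_dei(co$expr, p)
  swapped <- p
  swapped$baseline_sample <- p$dp_sample
  swapped$dp_sample <- p$baseline_sample
  rev <- call_dei(co$expr, swapped)
  key <- function(d) paste(d$isoform_id, d$pair_id)
  m <- match(key(fwd), key(rev))
  # the swapped fold change is the exact reciprocal, so any call present
  # in both orientations has the opposite direction
  both <- !is.na(m)
  expect_gt(sum(both), 0)
  expect_true(all(rev$direction[m[both]] != fwd$direction[both]))
  expect_equal(rev$fc[m[both & is.finite(fwd$fc)]],
               1 / fwd$fc[both & is.finite(fwd$fc)])
  # on the raw |1-FC| > 0.2 scale the cutoff is asymmetric: every down
  # call flips to an up call (1/FC > 1.25), while up calls flip exactly
  # when FC > 1/0.8
  dn <- fwd$direction == "down"
  expect_false(anyNA(m[dn]))
  strong_up <- fwd$direction == "up" & fwd$fc > 1 / 0.8
  expect_false(anyNA(m[strong_up]))
  borderline_up <- fwd$direction == "up" & fwd$fc <= 1 / 0.8
  expect_true(all(is.na(m[borderline_up])))
})

test_that("recurrence counts, ordering and tie-breaks are deterministic", {
  calls <- data.frame(
    isoform_id = c(rep("a", 22), rep("b", 3), rep("c", 3)),
    pair_id = c(sprintf("p%02d", 1:22), "p1", "p2", "p3", "p1", "p2", "p3"),
    direction = c(rep("up", 22), rep("down", 3), rep("down", 3)),
    stringsAsFactors = FALSE)
  pairs <- data.frame(pair_id = sprintf("p%02d", 1:44))
  rec <- recurrence(calls, pairs)
  expect_equal(rec$n_up[rec$isoform_id == "a"], 22L)
  expect_equal(rec$concordance, rec$n_up - rec$n_down)
  expect_true(all(rec$n_up + rec$n_down <= rec$n_pairs))
  # b and c tie on counts -> ordered by id
  expect_equal(rec$isoform_id, c("a", "b", "c"))
  # isoform with no calls reports zeros
  rec2 <- recurrence(calls, pairs, isoform_ids = c("a", "b", "c", "z"))
  z <- rec2[rec2$isoform_id == "z", ]
  expect_equal(c(z$n_up, z$n_down, z$concordance), c(0L, 0L, 0L))
})

test_that("concordance filter is strict and monotone in the threshold", {
  rec <- data.frame(isoform_id = c("x", "y", "z"),
                    n_up = c(10, 10, 0), n_down = c(2, 4, 7))
  kept <- concordance_filter(rec, 6)
  expect_setequal(kept$isoform_id, c("x", "z"))   # |6| is not > 6
  loose <- concordance_filter(rec, 0)
  expect_true(all(kept$isoform_id %in% loose$isoform_id))
})

test_that("cumulative recurrence curve matches direct enumeration", {
  rec <- data.frame(isoform_id = c("a", "b", "c"),
                    n_up = c(3, 1, 0), n_down = c(0, 0, 1))
  rec$recurrence <- pmax(rec$n_up, rec$n_down)
  cv <- cumulative_recurrence_curve(rec)
  expect_equal(cv$n_isoforms[cv$k == 0], 3L)
  expect_equal(cv$n_isoforms[cv$k == 1], 3L)
  expect_equal(cv$n_isoforms[cv$k == 2], 1L)
  expect_equal(cv$n_isoforms[cv$k == 3], 1L)
  expect_true(all(diff(cv$n_isoforms) <= 0))
  empty <- cumulative_recurrence_curve(rec[0, ])
  expect_equal(empty$n_isoforms, 0L)
})

test_that("sharing stats partition detected isoforms", {
  sh <- toy_sheet(1, 1)
  tpm <- matrix(0, 10, 2, dimnames = list(paste0("i", 1:10),
                                          c("P01_B", "P01_DP1")))
  tpm[1:9, 1] <- 5          # present in baseline
  tpm[2:9, 2] <- 5          # 8 shared
  tpm[10, 2] <- 5           # DP only
  st <- sharing_stats(mk_expr(tpm), sh, presence_tpm = 1)
  expect_equal(st$n_shared, 8L)
  expect_equal(st$n_baseline_only, 1L)
  expect_equal(st$n_dp_only, 1L)
  expect_equal(st$shared_fraction, 0.8)
  tpm_same <- tpm[, c(1, 1)]
  colnames(tpm_same) <- colnames(tpm)
  ident <- sharing_stats(mk_expr(tpm_same), sh)
  expect_equal(ident$shared_fraction, 1)   # identical groups share all
  disjoint <- sharing_stats(mk_expr(tpm * cbind(rep(1, 10), 0)), sh)
  expect_equal(disjoint$shared_fraction, 0)
})

test_that("normalized Shannon entropy matches hand values", {
  sh <- toy_sheet(1, 1)
  tpm <- rbind(a1 = c(50, 75), a2 = c(50, 25))
  colnames(tpm) <- c("P01_B", "P01_DP1")
  d <- isoform_diversity(mk_expr(tpm), pseudocount = 0)
  expect_equal(d$entropy[d$sample_id == "P01_B"], 1.0)
  expect_equal(d$entropy[d$sample_id == "P01_DP1"], 0.8113, tolerance = 1e-4)
  # dominance -> entropy 0; single-isoform gene -> missing
  tpm2 <- rbind(b1 = c(100), b2 = c(0), c1 = c(7))
  colnames(tpm2) <- "s1"
  gm <- c(b1 = "gb", b2 = "gb", c1 = "gc")
  d2 <- isoform_diversity(expr_matrix(tpm2, gm), pseudocount = 0)
  expect_equal(d2$entropy[d2$gene_id == "gb"], 0)
  expect_true(is.na(d2$entropy[d2$gene_id == "gc"]))
})

test_that("diversity comparison separates balanced from skewed genes", {
  # construct genes with programmed entropy difference: "altered" genes
  # express two isoforms near 50/50 (high entropy), the rest are
  # dominated by one isoform (low entropy)
  set.seed(3)
  n_g <- 30; n_s <- 12
  tpm <- matrix(0, 2 * n_g, n_s)
  rownames(tpm) <- paste0("g", rep(1:n_g, each = 2), ".t", 1:2)
  colnames(tpm) <- paste0("s", 1:n_s)
  gm <- setNames(paste0("g", rep(1:n_g, each = 2)), rownames(tpm))
  for (g in 1:n_g) {
    w <- if (g <= 15) runif(n_s, 0.4, 0.6) else runif(n_s, 0.9, 0.99)
    tot <- runif(n_s, 50, 200)
    tpm[2 * g - 1, ] <- tot * w
    tpm[2 * g, ] <- tot * (1 - w)
  }
  d <- isoform_diversity(expr_matrix(tpm, gm))
  res <- diversity_test(d, paste0("g", 1:15))
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$median_altered, res$median_non_altered)
  expect_error(diversity_test(d, character()), "non-empty")
})

test_that("paired t-test matches the hand-computed statistic", {
  sh <- toy_sheet(1, 4)
  p <- make_pairs(sh)
  base <- 2^c(1, 1, 1, 1)
  dp <- 2^c(2, 3, 4, 5)      # log2 differences 1, 2, 3, 4
  tpm <- rbind(i1 = c(base[1], dp))
  colnames(tpm) <- c("P01_B", paste0("P01_DP", 1:4))
  r <- paired_group_test(mk_expr(tpm), "i1", p, pseudocount = 0)
  expect_equal(r$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-6)
  expect_equal(r$t, 3.873, tolerance = 1e-3)
  # identical vectors -> t = 0, p = 1
  tpm2 <- rbind(i1 = rep(8, 5))
  colnames(tpm2) <- colnames(tpm)
  r2 <- paired_group_test(mk_expr(tpm2), "i1", p)
  expect_equal(r2$t, 0)
  expect_equal(r2$p_value, 1)
  # constant non-zero differences -> large finite t, p ~ 0
  tpm3 <- rbind(i1 = c(2, 8, 8, 8, 8))
  colnames(tpm3) <- colnames(tpm)
  r3 <- paired_group_test(mk_expr(tpm3), "i1", p, pseudocount = 0)
  expect_true(is.finite(r3$t))
  expect_lt(r3$p_value, 1e-12)
})
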