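# Shared fixtures and independent oracles used across the suite.

# ---- tiny hand-built annotation ------------------------------------------

tx <- function(id, gid, exons, strand = "+", chrom = "chr1",
               biotype = "protein_coding", cds = NULL)
  transcript_model(id, gid, chrom, strand, exons, cds = cds,
                   biotype = biotype)

toy_gene_se <- function(strand = "+") {
  gene_model(list(
    tx("t1", "g1", rbind(c(100, 200), c(300, 400), c(500, 600)), strand),
    tx("t2", "g1", rbind(c(100, 200), c(500, 600)), strand)))
}

toy_sheet <- function(n_pat = 2, dp = c(1, 3)) {
  rows <- list()
  for (i in seq_len(n_pat)) {
    p <- sprintf("P%02d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(p, "_B"), patient_id = p, condition = "Baseline")
    for (k in seq_len(dp[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(p, "_DP", k), patient_id = p, condition = "DP")
  }
  sample_sheet(do.call(rbind, rows))
}

toy_expr <- function(tpm, gene_map) expr_matrix(tpm, gene_map)

# ---- brute-force splicing-event oracle -----------------------------------
# Independent enumeration of the five event-mode definitions over all
# transcript pairs, returning a sorted set of "MODE|coordinates" keys in
# the same canonical format as classify_events().

oracle_event_keys <- function(gene) {
  iv <- function(x) sprintf("[%d,%d)", as.integer(x[1]), as.integer(x[2]))
  txs <- lapply(gene$transcripts, `[[`, "exons")
  keyset <- character()
  put <- function(mode, parts)
    keyset <<- union(keyset, paste(mode, paste(parts, collapse = ";"),
                                   sep = "|"))
  same <- function(u, v) u[1] == v[1] && u[2] == v[2]
  has <- function(m, e) {
    for (r in seq_len(nrow(m))) if (same(m[r, ], e)) return(TRUE)
    FALSE
  }
  adjacent <- function(m, e1, e2) {
    # e1 immediately followed by e2 in transcript m
    for (r in seq_len(nrow(m) - 1))
      if (same(m[r, ], e1) && same(m[r + 1, ], e2)) return(TRUE)
    FALSE
  }
  n_tx <- length(txs)
  for (p in seq_len(n_tx)) for (q in seq_len(n_tx)) {
    if (p == q) next
    A <- txs[[p]]; B <- txs[[q]]
    # SE
    if (nrow(A) >= 3) for (i in 2:(nrow(A) - 1)) {
      f1 <- A[i - 1, ]; cs <- A[i, ]; f2 <- A[i + 1, ]
      if (!has(B, cs) && adjacent(B, f1, f2))
        put("SE", c(iv(f1), iv(cs), iv(f2)))
    }
    # RI
    for (i in seq_len(nrow(A))) for (j in seq_len(max(nrow(B) - 1, 0))) {
      if (A[i, 1] == B[j, 1] && A[i, 2] == B[j + 1, 2] &&
          B[j, 2] < B[j + 1, 1])
        put("RI", c(iv(A[i, ]), iv(B[j, ]), iv(B[j + 1, ])))
    }
    # A5SS / A3SS
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      e1 <- A[i, ]; e2 <- B[j, ]
      if (e1[1] == e2[1] && e1[2] != e2[2] && i < nrow(A) && j < nrow(B) &&
          same(A[i + 1, ], B[j + 1, ])) {
        lo <- if (e1[2] > e2[2]) e2 else e1
        hi <- if (e1[2] > e2[2]) e1 else e2
        put(if (gene$strand == "+") "A5SS" else "A3SS",
            c(iv(hi), iv(lo), iv(A[i + 1, ])))
      }
      if (e1[2] == e2[2] && e1[1] != e2[1] && i > 1 && j > 1 &&
          same(A[i - 1, ], B[j - 1, ])) {
        lo <- if (e1[1] < e2[1]) e1 else e2
        hi <- if (e1[1] < e2[1]) e2 else e1
        put(if (gene$strand == "+") "A3SS" else "A5SS",
            c(iv(lo), iv(hi), iv(A[i - 1, ])))
      }
    }
    # MXE
    if (nrow(A) >= 3 && nrow(B) >= 3)
      for (i in 2:(nrow(A) - 1)) for (j in 2:(nrow(B) - 1)) {
        X <- A[i, ]; Y <- B[j, ]
        if (same(X, Y)) next
        if (!same(A[i - 1, ], B[j - 1, ]) || !same(A[i + 1, ], B[j + 1, ]))
          next
        any_both <- FALSE
        for (m in txs) if (has(m, X) && has(m, Y)) { any_both <- TRUE; break }
        if (any_both) next
        first <- if (X[1] < Y[1] || (X[1] == Y[1] && X[2] < Y[2])) X else Y
        second <- if (same(first, X)) Y else X
        put("MXE", c(iv(A[i - 1, ]), iv(first), iv(second), iv(A[i + 1, ])))
      }
  }
  sort(keyset)
}

impl_event_keys <- function(gene) {
  ev <- classify_events(gene)
  sort(paste(ev$mode, ev$coordinates, sep = "|"))
}

# random multi-isoform gene on the codon grid, mixing derived event
# structures and fully random chains
random_gene <- function(gid = "gX", n_iso = sample(2:5, 1),
                        n_ex = sample(3:8, 1)) {
  chain <- function(n) {
    lens <- 3 * sample(10:60, n, replace = TRUE)
    gaps <- 3 * sample(10:80, max(n - 1, 0), replace = TRUE)
    st <- 300 + cumsum(c(0, lens[-n] + gaps))
    cbind(st, st + lens)
  }
  base <- chain(n_ex)
  variants <- list(base)
  tries <- 0
  while (length(variants) < n_iso && tries < 60) {
    tries <- tries + 1
    v <- if (runif(1) < 0.25) chain(sample(3:8, 1)) else {
      b <- variants[[sample.int(length(variants), 1)]]
      op <- sample(5, 1)
      n <- nrow(b)
      if (op == 1 && n >= 3) b[-(1 + sample.int(n - 2, 1)), , drop = FALSE]
      else if (op == 2 && n >= 2) {      # merge two adjacent exons
        j <- sample.int(n - 1, 1)
        rbind(b[seq_len(j - 1), , drop = FALSE],
              c(b[j, 1], b[j + 1, 2]),
              b[setdiff(seq_len(n), seq_len(j + 1)), , drop = FALSE])
      } else if (op == 3 && n >= 2) {    # nudge an end
        j <- sample.int(n - 1, 1)
        d <- 3 * sample(c(-3, -2, -1, 1, 2), 1)
        nb <- b; nb[j, 2] <- nb[j, 2] + d
        if (nb[j, 2] > nb[j, 1] && nb[j, 2] <= nb[j + 1, 1]) nb else NULL
      } else if (op == 4 && n >= 2) {    # nudge a start
        j <- 1 + sample.int(n - 1, 1)
        d <- 3 * sample(c(-2, -1, 1, 2, 3), 1)
        nb <- b; nb[j, 1] <- nb[j, 1] + d
        if (nb[j, 1] < nb[j, 2] && nb[j, 1] >= nb[j - 1, 2]) nb else NULL
      } else if (n >= 3) {               # swap in an alternative exon
        j <- 1 + sample.int(n - 2, 1)
        room <- b[j + 1, 1] - b[j, 2]
        if (room < 12) NULL else {
          len <- 3 * sample.int(max(floor((room - 6) / 3), 1), 1)
          nb <- b; nb[j, ] <- c(b[j, 2] + 3, min(b[j, 2] + 3 + len,
                                                 b[j + 1, 1] - 3))
          if (nb[j, 2] > nb[j, 1]) nb[order(nb[, 1]), , drop = FALSE]
          else NULL
        }
      } else NULL
    }
    if (is.null(v) || nrow(v) == 0) next
    if (any(vapply(variants, function(w) identical(unname(w), unname(v)),
                   NA))) next
    variants[[length(variants) + 1L]] <- v
  }
  strand <- sample(c("+", "-"), 1)
  gene_model(lapply(seq_along(variants), function(k)
    tx(sprintf("%s.t%d", gid, k), gid, variants[[k]], strand)))
}

# ---- enumeration oracle for the hypergeometric tail ----------------------
# P(X >= k) by exhaustive enumeration of all n-subsets of a universe of N
# items whose first K are the successes.

enum_hyper_upper <- function(k, K, n, N) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  subs <- utils::combn(N, n)
  hits <- colSums(subs <= K)
  mean(hits >= k)
}

# ---- textbook BH step-up -------------------------------------------------

textbook_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}
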