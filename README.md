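# spliceswitch

Transcriptome-wide discovery of reciprocal alternative-splicing isoform
switches from patient-matched tumor biopsy cohorts.

## The problem

During acquired resistance to targeted therapy, a gene's total mRNA can
stay flat while its isoform composition flips: one isoform rises while a
sibling isoform falls in the same patient's disease-progression (DP)
biopsy relative to the pre-treatment baseline.  The canonical example is
a kinase whose activation-loop exon is re-included in-frame, restoring
catalytic activity without any change in gene-level expression.  Finding
such switches requires isoform-level, pair-matched analysis:

* per-pair differential isoform calls with fold change
  `FC = (TPM_DP + c) / (TPM_B + c)`, evaluated only where the isoform
  reaches ≥ 10 TPM in at least one sample of the pair, called when
  `|1 − FC| > 0.2`;
* recurrence ranking by `max(n_up, n_down)` over the matched pairs and a
  concordance filter `|n_up − n_down| > 6`;
* classification of canonical splicing events (SE, A5SS, A3SS, RI, MXE)
  from transcript structures, with abundance-based percent-spliced-in
  `Ψ = ΣTPM_inclusion / ΣTPM_total` and the significance gate
  `|ΔΨ| > 0.1`, BH `q < 0.05`;
* reciprocal switch detection by net co-occurrence of opposite
  directional calls within a gene, with patient-level directional
  support tests and Pearson correlation of the per-pair log2FC vectors;
* protein-level consequences: global alignment of each alternative
  isoform against the gene's principal isoform, and the lost /
  truncated / intact status of every annotated protein domain;
* hypergeometric over-representation analysis (pathways, domain-centric
  terms, curated cancer gene sets) and an RNA-binding-protein regulator
  screen (binding-site overlap + expression correlation).

A ground-truthed synthetic cohort generator reproduces the study design
(21 patients, one baseline each, 44 DP biopsies, programmed exon-skip
switches, a coupled driver RBP), so the whole pipeline is testable
without any data download.  See the vignette
(`vignettes/isoform-switch-discovery.Rmd`) for the model, parameter
defaults and design rationale.

## Worked example

```r
library(spliceswitch)

cohort <- simulate_cohort(sim_config(n_genes = 100, seed = 42))
pairs  <- make_pairs(cohort$sheet)            # 44 matched Baseline/DP pairs

calls    <- call_dei(cohort$expr, pairs)      # per-pair differential calls
records  <- recurrence(calls, pairs)          # 339 isoforms with calls
retained <- concordance_filter(records, 6)    # 123 concordant isoforms

switches <- detect_switches(cohort$expr, pairs, calls)
head(switches, 3)
#>   gene_id up_isoform down_isoform n_reciprocal_pairs percentage  pearson_r
#> 1   G0008   G0008.t1     G0008.t2                 28      63.64 -0.7999378
#> 2   G0003   G0003.t1     G0003.t2                 26      59.09 -0.8129816
#> 3   G0002   G0002.t1     G0002.t2                 25      56.82 -0.8859619
```

Each row is a reciprocal switch: in gene G0008 the exon-inclusion
isoform G0008.t1 is up while G0008.t2 (the exon-skip form) is down in
the *same* 28 of 44 pairs (63.64% of DP biopsies), and the two isoforms'
per-pair log2 fold changes are strongly negatively correlated.  Against
the generator's ground truth (10 planted switch genes among 100) this
run recovers every planted switch with no false positives.

Tying the switch to its cassette exon and a candidate regulator:

```r
sk   <- cohort$truth$skipped_exons[1, ]
psi  <- exon_psi(cohort$annotation[[sk$gene_id]], c(sk$start, sk$end),
                 cohort$expr)
lfc  <- log2fc_matrix(cohort$expr, pairs)
correlate_fc_dpsi(lfc[cohort$truth$switch_isoforms$inclusion_isoform[1], ],
                  psi[pairs$dp_sample] - psi[pairs$baseline_sample])
#> r = 0.942, p = 1.47e-21, n = 44   (inclusion log2FC tracks exon dPSI)

rbps <- unique(cohort$sites$rbp_name)
scr  <- rbp_screen(cohort$annotation[[cohort$target_gene]], cohort$sites,
                   cohort$expr, setNames(paste0(rbps, ".t1"), rbps))
head(scr$ranked, 1)
#>   rbp_name max_abs_r best_isoform best_p_value n_passing
#> 1    RBP01 0.5006587     G0001.t2 2.164111e-05         2
```

The top-ranked regulator, RBP01, is exactly the driver the generator
coupled to the switch.  `run_pipeline(pipeline_config(...))` chains all
stages (differential screen → events/PSI → switches → domain impact →
enrichment → RBP screen) and writes every table as TSV plus a
`manifest.json` under the output directory; runs are byte-reproducible
under a fixed seed.

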