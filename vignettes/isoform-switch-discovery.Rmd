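---
title: "Discovering reciprocal isoform switches in matched tumor biopsy cohorts"
author: "spliceswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering reciprocal isoform switches in matched tumor biopsy cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceswitch)
```

## The problem

Targeted-therapy resistance in tumors is usually studied at the gene
expression level, but a gene's total mRNA can stay flat while its isoform
composition changes drastically: one isoform rises while a sibling isoform
of the same gene falls in the same biopsy.  Such *reciprocal splicing
switches* — the textbook case being a kinase that regains its activation
loop (A-loop) when an in-frame cassette exon is re-included — are
invisible to gene-level differential expression and require isoform-level,
patient-matched analysis.

`spliceswitch` implements that analysis as a pipeline over four inputs:
an isoform-by-sample TPM matrix, a transcript annotation (GTF), a sample
sheet pairing each disease-progression (DP) biopsy with its patient's
pre-treatment (Baseline) biopsy, and optional protein/domain/binding-site
annotations.  A ground-truthed synthetic cohort generator stands in for
patient data so that every stage is testable.

## The screening model

For each DP biopsy and its patient-matched Baseline the pipeline computes,
per isoform, the fold change $FC = (T_{DP} + c) / (T_{B} + c)$ with
pseudocount $c$ (default 0.1 TPM).  An isoform is *evaluated* in a pair
only when its raw abundance reaches `tpm_min` (default 10 TPM) in at
least one of the two samples, and *called* when $|1 - FC| > 0.2$.  Note
the cutoff is deliberately applied on the raw FC scale, exactly as the
screening rule defines it: it is asymmetric ($FC > 1.2$ or $FC < 0.8$),
so an up call near the boundary need not survive swapping the roles of
the two samples; the suite tests the exact reciprocal property that does
hold.

Calls are aggregated into per-isoform recurrence records
($n_{up}, n_{down}$ over the 44 pairs of the default design), ranked by
$\max(n_{up}, n_{down})$, and passed through the concordance filter
$|n_{up} - n_{down}| > 6$ (strict), which keeps isoforms that move in a
consistent direction across patients.

## Switch detection

Two detectors are provided, because they answer different questions:

* `switch_candidates()` screens one gene for isoform pairs whose
  per-pair $\log_2 FC$ vectors are strongly negatively correlated
  (Pearson $r < 0$, $|r| \ge 0.5$, $p \le 0.05$ by default).  This
  mirrors the correlation analysis used to describe a switch, but it is
  undefined in the degenerate noise-free, full-penetrance limit, where
  every $\log_2 FC$ vector is constant (such pairs are skipped with a
  recorded reason).

* `detect_switches()` is the pipeline-level caller.  For every
  within-gene isoform pair it counts *reciprocal co-occurring calls* —
  pairs where one isoform has an up call and the other a down call — in
  both orientations, and calls a switch when the net count (dominant
  orientation minus the reverse) reaches `min_reciprocal_frac` (default
  0.25) of the matched pairs **and** the directional shift is supported
  statistically.  The support test aggregates $\log_2 FC$ within patient
  first (a patient's 1–3 DP biopsies share one baseline, so their pairs
  are not independent) and then applies a one-sided t-test across
  patients ($p \le 0.05$) that the up isoform's mean shift is positive
  and the down isoform's negative.  Requiring *net directional*
  co-occurrence distinguishes a true switch from anti-correlated isoform
  pairs produced by symmetric noise, which flip direction from pair to
  pair and net out to zero.

The reported headline number for a switch is the per-pair co-occurrence
percentage: with up calls in 15 of 44 pairs and down calls in 22, an
overlap of 13 joint pairs is reported as 29.55% of DP biopsies.

## Splicing events and PSI

`classify_events()` scans all transcript pairs of a gene for the five
canonical modes — skipped exon (SE), alternative 5'/3' splice site
(A5SS/A3SS, strand-aware), retained intron (RI), and mutually exclusive
exons (MXE) — using exact coordinate identity for flank matching.  Events
are defined purely from transcript structure; percent-spliced-in is
computed from isoform abundances,
$\Psi = \sum \mathrm{TPM}_{incl} / \sum \mathrm{TPM}_{incl \cup excl}$,
not from junction reads.  This is a deliberate divergence from
junction-count tools: the package's substrate is an abundance matrix, and
an abundance-based $\Psi$ makes the event layer exactly consistent with
the isoform layer.  Differential events use the per-pair
$\Delta\Psi = \Psi_{DP} - \Psi_{B}$ with a paired t-test, BH adjustment,
and the double gate $|\overline{\Delta\Psi}| > 0.1$, $q < 0.05$.  Events
with fewer than three informative pairs are reported *untested* rather
than silently assigned $p = 1$.

## Protein consequences

`diff_protein()` globally aligns an alternative isoform's protein against
the gene's principal isoform (BLOSUM62 substitution scores, affine gaps,
opening 10 / extension 0.5) and reports contiguous gap runs as
deletion/insertion segments; a frameshift flag is raised when the
alternative is not reconstructable from the principal by contiguous
blocks alone.  The principal isoform comes from an APPRIS-style table
when supplied, else longest CDS, ties by transcript length then
lexicographic id.  `domain_impact()` intersects deletion segments with
annotated domain intervals: a domain is `lost` when fully removed,
`truncated` when partially removed, `intact` otherwise; a frameshift
forces downstream domains to `lost`.  `functional_screen()` chains the
funnel: protein-coding, domain-disrupting, gene-set-annotated, ranked by
recurrence then concordance.

## Enrichment and the RBP screen

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ computed in log space (via the stable distribution
routines), with sets intersected with the universe and zero-overlap sets
excluded from testing and from the BH denominator.  The default pathway
universe is all genes with at least one expressed isoform in the cohort.
Domain-centric enrichment is the identical statistic with domains as the
sampling unit.

The RBP screen intersects binding sites with the whole target-gene locus
(half-open intervals; adjacent intervals do not overlap; no proximity
filter, since distal sites can still regulate splicing) and then ranks
candidates by the strength of their expression correlation with the
gene's isoforms across all samples (per-pair $\log_2 FC$ correlation is
available as an option).  Defaults: $|r| \ge 0.3$, $p \le 0.05$.

## The synthetic cohort generator

`simulate_cohort()` emulates the matched-pair study design: 21 patients,
one Baseline each, 1–3 DP biopsies per patient totalling 44; 400
multi-isoform genes of which 10% carry a programmed reciprocal exon-skip
switch.  Design choices worth knowing:

* **Switch architecture.**  Each switch gene has an inclusion isoform and
  a skip isoform identical except for one in-frame 129-nt cassette exon
  (43 aa), with a protein domain overlapping the encoded peptide so that
  skipping truncates it — the A-loop architecture.
* **Abundance model.**  Per-isoform baseline means are log-normal
  (meanlog 4, sdlog 1, i.e. a median around 55 TPM); per-sample noise is
  multiplicative log-normal with `noise_sd = 0.25` (natural log).  The
  two programmed switch isoforms draw their means log-uniformly from
  20–200 TPM: a planted switch below the 10-TPM analysis floor would be
  undetectable by construction, and the generator's contract is that its
  ground truth is recoverable in the noise-free limit.
* **Manifestation.**  Each switch gene manifests in exactly
  `round(penetrance * 44)` DP samples (multiplying the inclusion isoform
  by `effect_size` = 4 and dividing the skip isoform by it, before
  noise), so penetrance-based expectations hold exactly rather than in
  expectation.  Which samples manifest is drawn with weights tied to a
  per-sample latent factor.
* **RBP coupling.**  The same latent factor elevates the driver RBP's
  expression in DP samples (strength `rbp_coupling` = 0.8), producing the
  positive RBP–inclusion-isoform correlation the regulator screen
  assumes.  Decoy RBPs get binding sites in the target locus but
  uncoupled expression, so the site-overlap stage alone cannot identify
  the driver.
* **Decoys.**  10% of non-switch genes carry an anti-correlated isoform
  pair driven by pure noise: a shared log-normal factor at the cohort's
  own noise scale applied with opposite signs to two isoforms in *all*
  samples.  These exercise false-positive control: they produce negative
  isoform correlations without a consistent direction of change.
* **Structures.**  All exon boundaries sit on the codon grid and isoform
  proteins are read off a per-gene random codon sequence, so protein
  diffs mirror exon diffs exactly; decoy isoforms are derived from a base
  transcript by random SE/RI/A5SS/A3SS/MXE edits, exercising the
  classifier on every mode.

What the generator does **not** emulate: read-level sampling noise,
isoform misassembly and quantification bias, batch structure, real splice
site sequence, or the paper-scale isoform catalog (~10^5 isoforms).
Passing the recovery tests therefore demonstrates correctness of the
screening logic under the stated generative model, not performance on
real RNA-seq.

## Numerical choices and degenerate inputs

* Percentages print with half-up rounding to two decimals (13/44 →
  29.55).
* Zero baseline TPM with a zero pseudocount yields $FC = \infty$,
  treated as an up call, never a division error.
* Zero-variance paired differences cap the t statistic at a large finite
  value (±1e8) with the p-value underflowing accordingly; identical
  vectors give $t = 0, p = 1$.
* $\Psi$ is reported missing where a gene is unexpressed; missing values
  propagate as "untested", never as NaN arithmetic.
* All orderings break ties deterministically (concordance, then
  lexicographic id), so equal inputs give byte-identical outputs.

## Problem sizes used by the test suite

The suite exercises the classifier-vs-oracle comparison on 1000 random
gene models (2–5 isoforms, 3–8 exons), the hypergeometric tail against
exhaustive enumeration for every parameter combination with universe size
up to 12, BH against the textbook step-up on 1000 random vectors, and
recovery/identifiability on the default 400-gene cohort (one cohort for
detection, 50 replicate cohorts for the driver-RBP screen).  These sizes
were chosen to give tight statistical evidence while keeping a full run
in the low minutes on one core.

## Known limitations

* Event classification requires exact flank coordinates; fuzzy flank
  matching across assembly artifacts is out of scope.
* The $\Delta\Psi$ test is a paired t-test on abundance-derived PSI, not
  a junction-count likelihood model; with few informative pairs it is
  conservative (events are reported untested).
* Frameshift detection is alignment-based when CDS phase bookkeeping is
  unavailable; substitution-heavy alignments are flagged frameshift
  conservatively.
* The RBP screen establishes correlation and binding-site colocation,
  not mechanism.

## End-to-end run

```{r, eval = FALSE}
cfg <- pipeline_config(
  simulate = sim_config(n_genes = 100, seed = 1),
  out_dir = "spliceswitch_run")
res <- run_pipeline(cfg)
head(res$switches)
res$summary$table
```

Every stage writes a TSV under `out_dir` together with `manifest.json`
recording the thresholds and seed; rerunning with the same configuration
reproduces identical files.
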