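# End-to-end orchestration from a configuration (R list or YAML file):
# simulate or load inputs, run every analysis stage, write TSV tables and
# a manifest.  The whole run is a deterministic function of config + seed.

#' Percentage with half-up rounding to two decimals
#'
#' `100 * n_events / n_total`, rounded half-up to match conventional
#' report formatting (e.g. 13 of 44 prints as 29.55).
#'
#' @param n_events,n_total Non-negative counts, `n_total > 0`.
#' @return The rounded percentage.
#' @export
percent_recurrence <- function(n_events, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0")
  if (any(n_events < 0) || any(n_events > n_total))
    stop("require 0 <= n_events <= n_total")
  x <- 100 * n_events / n_total
  floor(x * 100 + 0.5) / 100
}

#' Assemble a pipeline configuration
#'
#' Either `simulate` (a [sim_config()] or list of its arguments) or the
#' input paths (`gtf`, `expression`, `samples`, and optionally `proteins`,
#' `domains`, `sites`, `gene_sets`) must be provided.
#'
#' @param simulate Optional simulation block.
#' @param inputs Optional named list of input file paths.
#' @param tpm_min,fc_cutoff,min_concordance,pseudocount DEI thresholds.
#' @param dpsi_min,fdr_alpha Event-test thresholds.
#' @param min_reciprocal_frac,min_abs_r,max_p Switch/RBP thresholds.
#' @param presence_tpm Sharing presence threshold.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            tpm_min = 10, fc_cutoff = 0.2,
                            min_concordance = 6, pseudocount = 0.1,
                            dpsi_min = 0.1, fdr_alpha = 0.05,
                            min_reciprocal_frac = 0.25, min_abs_r = 0.3,
                            max_p = 0.05, presence_tpm = 1, seed = 1,
                            out_dir = tempfile("spliceswitch_run")) {
  if (is.null(simulate) && is.null(inputs))
    stop("config needs either a simulate block or input paths")
  if (!is.null(inputs)) {
    need <- c("gtf", "expression", "samples")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      stop("missing input path(s): ", paste(miss, collapse = ", "))
    gone <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(gone))
      stop("input file(s) not found: ", paste(gone, collapse = ", "))
  }
  stopifnot(tpm_min >= 0, fc_cutoff >= 0, min_concordance >= 0,
            dpsi_min >= 0 && dpsi_min <= 1,
            fdr_alpha > 0 && fdr_alpha <= 1,
            min_reciprocal_frac >= 0 && min_reciprocal_frac <= 1)
  structure(list(simulate = simulate, inputs = inputs, tpm_min = tpm_min,
                 fc_cutoff = fc_cutoff, min_concordance = min_concordance,
                 pseudocount = pseudocount, dpsi_min = dpsi_min,
                 fdr_alpha = fdr_alpha,
                 min_reciprocal_frac = min_reciprocal_frac,
                 min_abs_r = min_abs_r, max_p = max_p,
                 presence_tpm = presence_tpm, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulate:` mapping is passed to [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    y$simulate$seed <- y$simulate$seed %||% y$seed %||% 1
    y$simulate <- do.call(sim_config, y$simulate)
  }
  do.call(pipeline_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full isoform-switch discovery pipeline
#'
#' Sequences: simulate (or load) -> matched pairs -> differential isoform
#' calls -> recurrence + concordance filter -> sharing/diversity -> event
#' classification + PSI tests -> switch detection -> domain impact funnel
#' -> enrichment/crossover -> RBP screen -> summary report.  Every stage's
#' table is written under `config$out_dir` together with a
#' `manifest.json` recording thresholds and seed; rerunning with the same
#' config and seed reproduces identical outputs.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @return Invisibly, a list with all stage outputs (`cohort`, `pairs`,
#'   `dei_calls`, `records`, `retained`, `sharing`, `diversity`, `events`,
#'   `psi`, `event_tests`, `switches`, `screen`, `enrichment`,
#'   `crossover_tab`, `rbp`, `summary`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[spliceswitch] ", ...)

  # ---- inputs ----
  if (!is.null(config$simulate)) {
    simcfg <- config$simulate
    if (!inherits(simcfg, "sim_config")) simcfg <- do.call(sim_config, simcfg)
    cohort <- simulate_cohort(simcfg)
    log_msg("simulated cohort: ", length(cohort$annotation), " genes, ",
            nrow(cohort$expr$tpm), " isoforms")
  } else {
    gmapann <- read_gtf(config$inputs$gtf)
    cohort <- list(annotation = gmapann,
                   expr = read_expression_matrix(config$inputs$expression,
                                                 isoform_gene_map(gmapann)),
                   sheet = read_sample_sheet(config$inputs$samples),
                   proteins = if (!is.null(config$inputs$proteins))
                     read_fasta(config$inputs$proteins) else character(),
                   domains = if (!is.null(config$inputs$domains))
                     read_domain_table(config$inputs$domains) else NULL,
                   sites = if (!is.null(config$inputs$sites))
                     read_bed_sites(config$inputs$sites) else NULL,
                   gene_sets = if (!is.null(config$inputs$gene_sets))
                     read_gmt(config$inputs$gene_sets) else list(),
                   truth = NULL)
  }
  expr <- cohort$expr
  annotation <- cohort$annotation

  # ---- differential isoform screen ----
  pairs <- make_pairs(cohort$sheet)
  log_msg(nrow(pairs), " matched pairs")
  dei_calls <- call_dei(expr, pairs, config$tpm_min, config$fc_cutoff,
                        config$pseudocount)
  records <- recurrence(dei_calls, pairs)
  retained <- concordance_filter(records, config$min_concordance)
  log_msg(nrow(records), " isoforms with calls in; ", nrow(retained),
          " retained by concordance filter")
  curve <- cumulative_recurrence_curve(records)
  share <- sharing_stats(expr, cohort$sheet, config$presence_tpm)
  divers <- isoform_diversity(expr, config$pseudocount)

  # ---- splicing events ----
  events <- classify_events_all(annotation)
  psi <- compute_psi_all(events, expr)
  etests <- test_events(psi, pairs, config$dpsi_min, config$fdr_alpha)
  log_msg(nrow(events), " events classified; ",
          sum(etests$significant), " significant")

  # ---- switches + protein consequences ----
  switches <- detect_switches(expr, pairs, dei_calls,
                              config$min_reciprocal_frac, config$tpm_min,
                              config$fc_cutoff, config$pseudocount)
  log_msg(nrow(switches), " reciprocal switch calls")
  screen <- if (length(cohort$proteins) && !is.null(cohort$domains))
    functional_screen(retained, annotation, cohort$proteins,
                      cohort$domains, cohort$gene_sets)
  else data.frame()

  # ---- enrichment ----
  dei_genes <- unique(expr$isoform_to_gene[retained$isoform_id])
  gene_universe <- unique(expr$isoform_to_gene)
  enr <- if (length(cohort$gene_sets))
    ora(dei_genes, cohort$gene_sets, gene_universe, config$fdr_alpha)
  else data.frame()
  cross <- if (length(cohort$gene_sets))
    crossover(dei_genes, cohort$gene_sets, gene_universe)
  else data.frame()

  # ---- RBP screen ----
  rbp_res <- NULL
  if (!is.null(cohort$sites)) {
    target <- cohort$target_gene %||%
      (if (nrow(switches)) switches$gene_id[1L] else NULL)
    rbp_names <- unique(cohort$sites$rbp_name)
    rbp_iso <- stats::setNames(paste0(rbp_names, ".t1"), rbp_names)
    rbp_iso <- rbp_iso[rbp_iso %in% rownames(expr$tpm)]
    if (!is.null(target) && length(rbp_iso))
      rbp_res <- rbp_screen(annotation[[target]], cohort$sites, expr,
                            rbp_iso, min_abs_r = config$min_abs_r,
                            max_p = config$max_p)
  }

  summary <- summary_report(expr, records, retained, share, etests,
                            switches, pairs, dei_calls)

  # ---- outputs ----
  o <- function(f) file.path(config$out_dir, f)
  .write_tsv(dei_calls, o("dei_calls.tsv"))
  .write_tsv(records, o("recurrence.tsv"))
  .write_tsv(retained, o("recurrence_retained.tsv"))
  .write_tsv(curve, o("recurrence_curve.tsv"))
  .write_tsv(divers, o("diversity.tsv"))
  .write_tsv(data.frame(share), o("sharing.tsv"))
  ev_out <- events
  ev_out$inclusion_isoforms <- vapply(events$inclusion_isoforms,
                                      paste, "", collapse = ",")
  ev_out$exclusion_isoforms <- vapply(events$exclusion_isoforms,
                                      paste, "", collapse = ",")
  .write_tsv(ev_out, o("events.tsv"))
  .write_tsv(psi, o("psi.tsv"))
  .write_tsv(etests, o("event_tests.tsv"))
  .write_tsv(switches, o("switches.tsv"))
  if (NROW(screen)) .write_tsv(screen, o("functional_candidates.tsv"))
  if (NROW(enr)) .write_tsv(enr, o("enrichment.tsv"))
  if (NROW(cross)) .write_tsv(cross, o("crossover.tsv"))
  if (!is.null(rbp_res) && NROW(rbp_res$ranked))
    .write_tsv(rbp_res$ranked, o("rbp_candidates.tsv"))
  .write_tsv(summary$table, o("summary.tsv"))
  .write_tsv(summary$per_pair, o("per_pair_counts.tsv"))
  manifest <- list(package = "spliceswitch",
                   version = as.character(utils::packageVersion("spliceswitch")),
                   seed = config$seed,
                   thresholds = config[c("tpm_min", "fc_cutoff",
                                         "min_concordance", "pseudocount",
                                         "dpsi_min", "fdr_alpha",
                                         "min_reciprocal_frac", "min_abs_r",
                                         "max_p", "presence_tpm")])
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(cohort = cohort, pairs = pairs, dei_calls = dei_calls,
                 records = records, retained = retained, curve = curve,
                 sharing = share, diversity = divers, events = events,
                 psi = psi, event_tests = etests, switches = switches,
                 screen = screen, enrichment = enr, crossover_tab = cross,
                 rbp = rbp_res, summary = summary,
                 out_dir = config$out_dir))
}

#' Cohort-level summary statistics
#'
#' Totals, sharing fractions, per-pair up/down counts and switch
#' percentages; all percentages computed with [percent_recurrence()] and
#' all totals as sums of their parts.
#'
#' @param expr An [expr_matrix()].
#' @param records Recurrence records.
#' @param retained Concordance-filtered records.
#' @param share Output of [sharing_stats()].
#' @param event_tests Output of [test_events()].
#' @param switches Output of [detect_switches()].
#' @param pairs Matched pairs.
#' @param dei_calls Data frame from [call_dei()].
#' @return List with `table` (two-column key/value data frame) and
#'   `per_pair` (up/down counts per pair).
#' @export
summary_report <- function(expr, records, retained, share, event_tests,
                           switches, pairs, dei_calls = NULL) {
  n_iso <- nrow(expr$tpm)
  n_genes <- length(unique(expr$isoform_to_gene))
  n_dei <- nrow(records)
  per_pair <- data.frame(pair_id = pairs$pair_id,
                         n_up = 0L, n_down = 0L, stringsAsFactors = FALSE)
  if (!is.null(dei_calls) && nrow(dei_calls)) {
    upt <- table(factor(dei_calls$pair_id[dei_calls$direction == "up"],
                        levels = pairs$pair_id))
    dnt <- table(factor(dei_calls$pair_id[dei_calls$direction == "down"],
                        levels = pairs$pair_id))
    per_pair$n_up <- as.integer(upt)
    per_pair$n_down <- as.integer(dnt)
  }
  tab <- data.frame(
    key = c("n_isoforms", "n_genes", "n_pairs", "n_isoforms_with_calls",
            "n_retained_concordant", "pct_retained_of_called",
            "n_shared", "n_baseline_only", "n_dp_only", "pct_shared",
            "n_events_significant", "n_switch_calls"),
    value = c(n_iso, n_genes, nrow(pairs), n_dei, nrow(retained),
              if (n_dei > 0) percent_recurrence(nrow(retained), n_dei) else 0,
              share$n_shared, share$n_baseline_only, share$n_dp_only,
              {
                tot <- share$n_shared + share$n_baseline_only + share$n_dp_only
                if (tot > 0) percent_recurrence(share$n_shared, tot) else 0
              },
              sum(event_tests$significant), nrow(switches)),
    stringsAsFactors = FALSE)
  # internal consistency audit: totals equal sums of parts
  stopifnot(share$n_shared + share$n_baseline_only + share$n_dp_only <= n_iso)
  list(table = tab, per_pair = per_pair)
}
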