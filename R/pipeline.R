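#' Pipeline configuration
#'
#' All stage thresholds default to the study's values: RPKM detection
#' threshold 0.1 with bins at 5/100/1000; breakpoint tolerance 10 and
#' adjacency gap 100 kb with probe flank 20 for chimeras; FS/QD/DP hard
#' filters 30/2/5 with the 3-in-35 cluster rule; ASE depth filters 3/10,
#' allelic-ratio cutoffs 0.65/0.35 and FDR 0.05. Unknown arguments are
#' rejected; every threshold is echoed into the run report.
#'
#' @param seed Master seed for the simulation stage.
#' @param rpkm_thresholds Detection/bin thresholds.
#' @param tolerance,adjacency_max_gap,probe_flank Chimera-stage settings.
#' @param fs_max,qd_min,dp_min,cluster_size,cluster_window,exclude_chroms
#'   Variant-filter settings.
#' @param splice_region_window,flank_window Consequence-annotation windows.
#' @param min_allele_depth,min_total_depth,ratio_hi,ratio_lo,fdr ASE
#'   settings.
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            rpkm_thresholds = c(0.1, 5, 100, 1000),
                            tolerance = 10, adjacency_max_gap = 1e5,
                            probe_flank = 20,
                            fs_max = 30.0, qd_min = 2.0, dp_min = 5L,
                            cluster_size = 3L, cluster_window = 35L,
                            exclude_chroms = c("^scaffold", "^GL", "^AEMK",
                                               "^JH", "^MT$", "^chrM$"),
                            splice_region_window = 8L, flank_window = 5000L,
                            min_allele_depth = 3L, min_total_depth = 10L,
                            ratio_hi = 0.65, ratio_lo = 0.35, fdr = 0.05,
                            sim = NULL) {
  if (ratio_lo >= ratio_hi) abort("config error: ratio_lo must be < ratio_hi")
  if (fdr <= 0 || fdr >= 1) abort("config error: fdr must lie in (0, 1)")
  if (length(rpkm_thresholds) != 4 || any(diff(rpkm_thresholds) <= 0)) {
    abort("config error: rpkm_thresholds must be strictly increasing")
  }
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Simulates the dataset, then runs expression, chimera, variant and ASE
#' stages and assembles a report mirroring the headline summaries: detected
#' genes and abundance bins; consensus chimera count, class partition and
#' canonical fraction; retained SNPs, substitution spectrum and Ts/Tv,
#' per-gene histogram, known/novel partition and QTL overlap; eligible ASE
#' sites, calls and the nonsynonymous-enrichment test. Identical seed and
#' config give an identical report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: when given, per-stage TSVs and the
#'   report (JSON and text) are written there.
#' @return List of class `pipeline_report` with components `expression`,
#'   `chimera`, `variants`, `ase` and `params`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- simulate_dataset(config$sim)

  # expression stage
  expr_tbl <- compute_rpkm(sim$expression$counts, sim$annotation,
                           sim$expression$total_reads)
  expr_summary <- summarize_expression(expr_tbl, config$rpkm_thresholds)
  expr <- list(table = expr_tbl, summary = expr_summary,
               top = top_expressed(expr_tbl, 25))

  # chimera stage
  cons <- consensus_candidates(sim$fusions$candidates_a,
                               sim$fusions$candidates_b,
                               tolerance = config$tolerance)
  cls <- classify_chimeras(cons, sim$annotation,
                           adjacency_max_gap = config$adjacency_max_gap)
  cls <- check_canonical_splice(cls, sim$genome)
  spanning <- purrr::map_int(seq_len(nrow(cls)), function(i) {
    count_junction_reads(cls[i, ], sim$genome, sim$fusions$reads,
                         probe_flank = config$probe_flank)
  })
  cls$spanning_reads <- spanning
  chim <- list(consensus = cls, summary = summarize_chimera_classes(cls))

  # variant stage
  filt <- filter_variants(sim$variants$variants,
                          fs_max = config$fs_max, qd_min = config$qd_min,
                          dp_min = config$dp_min,
                          cluster_size = config$cluster_size,
                          cluster_window = config$cluster_window,
                          exclude_chroms = config$exclude_chroms)
  annotated <- annotate_variants(filt$retained, sim$annotation, sim$genome,
                                 splice_region_window = config$splice_region_window,
                                 flank_window = config$flank_window)
  spectrum <- summarize_substitutions(filt$retained)
  per_gene <- per_gene_snp_counts(filt$retained, sim$annotation)
  dbs <- compare_dbsnp(filt$retained, sim$dbsnp$catalogue)
  qtl <- qtl_overlap(filt$retained, sim$qtl)
  vars <- list(filter = filt, annotated = annotated, spectrum = spectrum,
               per_gene = per_gene, dbsnp = dbs, qtl = qtl)

  # ASE stage
  eligible <- filter_ase_sites(sim$ase$sites,
                               min_allele_depth = config$min_allele_depth,
                               min_total_depth = config$min_total_depth)
  tested <- test_ase(eligible$eligible)
  calls <- call_ase(tested, ratio_hi = config$ratio_hi,
                    ratio_lo = config$ratio_lo, fdr = config$fdr)
  truth_eligible <- sim$ase$truth[
    sim$ase$sites$n_ref >= config$min_allele_depth &
      sim$ase$sites$n_alt >= config$min_allele_depth &
      (sim$ase$sites$n_ref + sim$ase$sites$n_alt) >= config$min_total_depth, ]
  enrich <- enrichment_nonsyn(calls$results$is_ase, truth_eligible$is_nonsyn)
  ase <- list(filter = eligible, calls = calls, enrichment = enrich,
              bias = ase_bias_diagnostics(eligible$eligible),
              truth_eligible = truth_eligible)

  report <- structure(
    list(expression = expr, chimera = chim, variants = vars, ase = ase,
         params = config, sim = sim),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  expression: %d genes, %d detected (%.1f%% weak)\n",
              x$expression$summary$n_genes, x$expression$summary$n_detected,
              x$expression$summary$pct_weak))
  cat(sprintf("  chimera: %d consensus candidates, %.1f%% canonical\n",
              x$chimera$summary$n, x$chimera$summary$canonical$pct_canonical))
  cat(sprintf("  variants: %d retained of %d (Ts/Tv %.2f)\n",
              nrow(x$variants$filter$retained), x$variants$filter$n_input,
              x$variants$spectrum$tstv_ratio))
  cat(sprintf("  ase: %d calls among %d eligible sites\n",
              x$ase$calls$n_ase, x$ase$calls$n_eligible))
  invisible(x)
}

#' Flatten a pipeline report to the headline numbers
#'
#' Every value is computed by the stage modules; nothing is derived only
#' here.
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return One-row tibble of headline statistics.
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble(
    n_genes = x$expression$summary$n_genes,
    n_detected = x$expression$summary$n_detected,
    pct_weak = x$expression$summary$pct_weak,
    pct_abundant = x$expression$summary$pct_abundant,
    n_consensus_chimeras = x$chimera$summary$n,
    pct_canonical = x$chimera$summary$canonical$pct_canonical,
    n_snps_retained = nrow(x$variants$filter$retained),
    tstv_ratio = x$variants$spectrum$tstv_ratio,
    pct_dbsnp_known = x$variants$dbsnp$pct_known,
    pct_in_qtl = x$variants$qtl$pct_in_qtl,
    n_ase_eligible = x$ase$calls$n_eligible,
    n_ase_calls = x$ase$calls$n_ase,
    enrichment_p = x$ase$enrichment$p_value)
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$expression$table,
                   file.path(out_dir, "expression_rpkm.tsv"))
  readr::write_tsv(report$chimera$consensus,
                   file.path(out_dir, "chimera_consensus.tsv"))
  readr::write_tsv(report$variants$annotated,
                   file.path(out_dir, "variants_annotated.tsv"))
  readr::write_tsv(report$ase$calls$results,
                   file.path(out_dir, "ase_results.tsv"))
  g <- glance(report)
  thresholds <- report$params[
    c("rpkm_thresholds", "tolerance", "adjacency_max_gap", "probe_flank",
      "fs_max", "qd_min", "dp_min", "cluster_size", "cluster_window",
      "splice_region_window", "flank_window", "min_allele_depth",
      "min_total_depth", "ratio_hi", "ratio_lo", "fdr", "seed")]
  jsonlite::write_json(list(summary = as.list(g), thresholds = thresholds),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(
    "pipeline report",
    sprintf("genes detected: %d of %d (weak %.1f%%, abundant %.1f%%)",
            g$n_detected, g$n_genes, g$pct_weak, g$pct_abundant),
    sprintf("consensus chimeric RNAs: %d (canonical %.1f%%)",
            g$n_consensus_chimeras, g$pct_canonical),
    sprintf("retained SNPs: %d (Ts/Tv %.2f, dbSNP %.1f%%, in QTL %.2f%%)",
            g$n_snps_retained, g$tstv_ratio, g$pct_dbsnp_known, g$pct_in_qtl),
    sprintf("ASE: %d calls among %d eligible (enrichment p = %.3g)",
            g$n_ase_calls, g$n_ase_eligible, g$enrichment_p))
  readr::write_lines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
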