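#' Generate heterozygous-site allele counts with ASE truth labels
#'
#' A configured fraction of sites is truly allele-specific: their alternate
#' counts are drawn binomially with probability `p_ase`; all other sites
#' draw with probability 0.5. Depths are Poisson around the configured
#' mean (at least 1). Each site also receives a nonsynonymous flag, drawn
#' with a higher probability at true-ASE sites so the enrichment test has
#' signal to find.
#'
#' @param config A [sim_config()].
#' @return List with `sites` (tibble `chrom, pos, ref, alt, n_ref, n_alt`)
#'   and `truth` (`site_id, is_ase_true, p_true, is_nonsyn`).
#' @export
simulate_allele_counts <- function(config) {
  if (config$ase_fraction < 0 || config$ase_fraction > 1) {
    abort("ase_fraction must lie in [0, 1]")
  }
  withr::with_seed(config$seed + 404L, {
    n <- config$ase_n_sites
    n_ase <- round(config$ase_fraction * n)
    is_ase <- c(rep(TRUE, n_ase), rep(FALSE, n - n_ase))[sample(n)]
    p_true <- ifelse(is_ase, config$p_ase, 0.5)
    depth <- pmax(1L, rpois(n, config$ase_depth_mean))
    n_alt <- rbinom(n, depth, p_true)
    refs <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alts <- vapply(refs, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                   character(1), USE.NAMES = FALSE)
    is_nonsyn <- runif(n) < ifelse(is_ase, config$ase_nonsyn_prob_ase,
                                   config$ase_nonsyn_prob_balanced)
    list(
      sites = tibble(chrom = "1", pos = seq_len(n) * 50L,
                     ref = refs, alt = alts,
                     n_ref = as.integer(depth - n_alt),
                     n_alt = as.integer(n_alt)),
      truth = tibble(site_id = seq_len(n), is_ase_true = is_ase,
                     p_true = p_true, is_nonsyn = is_nonsyn))
  })
}

#' Generate QTL regions over a fixed trait list
#'
#' Regions are drawn per trait, non-overlapping within a trait, on the main
#' chromosomes.
#'
#' @param config A [sim_config()].
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   `trait`.
#' @export
simulate_qtl_regions <- function(config) {
  withr::with_seed(config$seed + 505L, {
    traits <- rep(config$qtl_traits, length.out = config$qtl_n_regions)
    rows <- list()
    placed <- list()
    for (i in seq_along(traits)) {
      tr <- traits[i]
      done <- FALSE; guard <- 0L
      while (!done && guard < 2000L) {
        guard <- guard + 1L
        ch <- sample(as.character(seq_len(config$n_chromosomes)), 1)
        len <- sample(config$qtl_region_length_range[1]:config$qtl_region_length_range[2], 1)
        start <- sample(seq_len(config$chrom_length - len), 1)
        end <- start + len - 1L
        prev <- placed[[tr]]
        clash <- !is.null(prev) &&
          any(prev$chrom == ch & prev$start <= end & prev$end >= start)
        if (!clash) {
          row <- tibble(chrom = ch, start = start, end = end, trait = tr)
          rows[[length(rows) + 1L]] <- row
          placed[[tr]] <- dplyr::bind_rows(prev, row)
          done <- TRUE
        }
      }
      if (!done) abort("infeasible QTL plan: could not place region")
    }
    dplyr::bind_rows(rows) |> dplyr::arrange(.data$chrom, .data$start)
  })
}

#' Generate a known-SNP catalogue covering a fraction of retained variants
#'
#' Samples `dbsnp_known_fraction` of the variants expected to survive
#' filtering, adds catalogue-only entries at unused positions and a few
#' same-position/different-allele decoys (which must *not* match under
#' allele-aware comparison).
#'
#' @param config A [sim_config()].
#' @param variants Variant tibble (typically retained variants).
#' @return List with `catalogue` (tibble `chrom, pos, ref, alt, id`) and
#'   `truth` (per input variant: `in_catalogue`).
#' @export
simulate_dbsnp_catalogue <- function(config, variants) {
  withr::with_seed(config$seed + 606L, {
    n <- nrow(variants)
    n_known <- round(config$dbsnp_known_fraction * n)
    known_idx <- sort(sample(n, n_known))
    cat_rows <- variants[known_idx, c("chrom", "pos", "ref", "alt")]
    cat_rows$id <- sprintf("rs%07d", seq_len(n_known))
    # decoys: same position, different alternate allele
    decoy_idx <- setdiff(seq_len(n), known_idx)
    decoy_idx <- head(decoy_idx, config$dbsnp_n_decoys)
    decoys <- variants[decoy_idx, c("chrom", "pos", "ref", "alt")]
    if (nrow(decoys) > 0) {
      decoys$alt <- vapply(seq_len(nrow(decoys)), function(i) {
        sample(setdiff(c("A", "C", "G", "T"),
                       c(decoys$ref[i], decoys$alt[i])), 1)
      }, character(1))
      decoys$id <- sprintf("rs9%06d", seq_len(nrow(decoys)))
    }
    extra <- tibble(
      chrom = sample(as.character(seq_len(config$n_chromosomes)),
                     config$dbsnp_n_extra, replace = TRUE),
      pos = sample(seq_len(config$chrom_length), config$dbsnp_n_extra),
      ref = sample(c("A", "C", "G", "T"), config$dbsnp_n_extra, replace = TRUE))
    extra$alt <- vapply(extra$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1),
      USE.NAMES = FALSE)
    extra$id <- sprintf("rs8%06d", seq_len(config$dbsnp_n_extra))
    catalogue <- dplyr::bind_rows(cat_rows, decoys, extra) |>
      dplyr::arrange(.data$chrom, .data$pos)
    truth <- tibble(chrom = variants$chrom, pos = variants$pos,
                    in_catalogue = seq_len(n) %in% known_idx)
    list(catalogue = catalogue, truth = truth)
  })
}

#' Generate per-gene read counts spanning the abundance bins
#'
#' Target RPKM values are drawn log-uniformly over 0.01-3000 (a handful of
#' genes get zero counts), then converted to integer counts for the
#' configured library size so realised RPKM recovers the target up to
#' rounding.
#'
#' @param config A [sim_config()].
#' @param annotation The generated [tx_annotation()].
#' @return List with `counts` (tibble `gene_id, count`), `total_reads` and
#'   `truth` (`gene_id, target_rpkm`).
#' @export
simulate_expression_counts <- function(config, annotation) {
  withr::with_seed(config$seed + 707L, {
    lens <- gene_exonic_lengths(annotation)
    n <- nrow(lens)
    target <- 10^runif(n, log10(0.01), log10(3000))
    target[sample(n, max(1L, round(0.05 * n)))] <- 0
    counts <- as.integer(round(target * config$expr_total_reads *
                                 lens$exonic_length / 1e9))
    list(
      counts = tibble(gene_id = lens$gene_id, count = counts),
      total_reads = config$expr_total_reads,
      truth = tibble(gene_id = lens$gene_id, target_rpkm = target))
  })
}

#' Run every generator and assemble the full synthetic dataset
#'
#' Order matters: the fusion generator edits the genome (planting junction
#' dinucleotides) before variants are drawn, so variant reference alleles
#' always match the final FASTA.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset` with components `config`, `genome`,
#'   `annotation`, `fusions`, `variants`, `ase`, `qtl`, `dbsnp`,
#'   `expression`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  gsim <- simulate_genome(config)
  fus <- simulate_fusions(config, gsim)
  vars <- simulate_variants(config, gsim$annotation, fus$genome)
  ase <- simulate_allele_counts(config)
  qtl <- simulate_qtl_regions(config)
  expr <- simulate_expression_counts(config, gsim$annotation)
  # catalogue built over the variants that pass filtering, per plan
  retained_plan <- vars$variants[vars$truth$fate == "pass", ]
  dbsnp <- simulate_dbsnp_catalogue(config, retained_plan)
  structure(list(config = config, genome = fus$genome,
                 annotation = gsim$annotation,
                 fusion_pairs = gsim$fusion_pairs,
                 fusions = fus[c("candidates_a", "candidates_b", "reads", "truth")],
                 variants = vars, ase = ase, qtl = qtl, dbsnp = dbsnp,
                 expression = expr),
            class = "sim_dataset")
}

#' Write a synthetic dataset to disk in standard formats
#'
#' FASTA genome, GTF annotation, VCF variants, FASTQ junction reads,
#' BED-like QTL regions and TSV tables (caller candidates, allele counts,
#' known-SNP catalogue, per-gene counts, truth tables).
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_genome_fasta(sim$genome, p("genome.fa"))
  write_gtf(sim$annotation, p("annotation.gtf"))
  write_vcf_snvs(sim$variants$variants, p("variants.vcf"))
  readr::write_tsv(sim$variants$truth, p("variants_truth.tsv"))
  readr::write_tsv(sim$fusions$candidates_a, p("candidates_chimerascan.tsv"))
  readr::write_tsv(sim$fusions$candidates_b, p("candidates_fusionmap.tsv"))
  readr::write_tsv(sim$fusions$truth, p("fusions_truth.tsv"))
  write_fastq_seqs(sim$fusions$reads, p("junction_reads.fastq"))
  readr::write_tsv(sim$ase$sites, p("allele_counts.tsv"))
  readr::write_tsv(sim$ase$truth, p("ase_truth.tsv"))
  write_qtl_bed(sim$qtl, p("qtl_regions.bed"))
  readr::write_tsv(sim$dbsnp$catalogue, p("dbsnp_catalogue.tsv"))
  readr::write_tsv(sim$expression$counts, p("gene_counts.tsv"))
  invisible(list(
    genome = p("genome.fa"), annotation = p("annotation.gtf"),
    variants = p("variants.vcf"), variants_truth = p("variants_truth.tsv"),
    candidates_a = p("candidates_chimerascan.tsv"),
    candidates_b = p("candidates_fusionmap.tsv"),
    fusions_truth = p("fusions_truth.tsv"),
    reads = p("junction_reads.fastq"),
    allele_counts = p("allele_counts.tsv"), ase_truth = p("ase_truth.tsv"),
    qtl = p("qtl_regions.bed"), dbsnp = p("dbsnp_catalogue.tsv"),
    counts = p("gene_counts.tsv")))
}
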