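mk_var <- function(chrom = "1", pos, ref = "A", alt = "G", fs = 1, qd = 20,
                   dp = 30) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), id = NA_character_,
                 ref = ref, alt = alt, fs = fs, qd = qd, dp = as.integer(dp),
                 genotype = "het", ad_ref = 10L, ad_alt = 10L)
}

test_that("hard-filter boundaries are retained; failures are removed in order", {
  v <- dplyr::bind_rows(
    mk_var(pos = 100, fs = 30.0, qd = 2.0, dp = 5),   # all boundaries: keep
    mk_var(pos = 200, fs = 30.01),                     # FS fail
    mk_var(pos = 300, qd = 1.99),                      # QD fail
    mk_var(pos = 400, dp = 4),                         # DP fail
    mk_var(pos = 500, fs = 31, qd = 1))                # FS wins the reason
  f <- filter_variants(v)
  expect_equal(f$retained$pos, 100L)
  expect_equal(f$counts$n[f$counts$rule == "hard_FS"], 2L)
  expect_equal(f$counts$n[f$counts$rule == "hard_QD"], 1L)
  expect_equal(f$counts$n[f$counts$rule == "hard_DP"], 1L)
  expect_equal(sum(f$counts$n) + nrow(f$retained), f$n_input)
})

test_that("cluster rule removes 3 SNPs spanning <= 35 bases, boundary exact", {
  v35 <- dplyr::bind_rows(mk_var(pos = 100), mk_var(pos = 115),
                          mk_var(pos = 134))
  expect_equal(nrow(filter_variants(v35)$retained), 0)
  v36 <- dplyr::bind_rows(mk_var(pos = 100), mk_var(pos = 115),
                          mk_var(pos = 135))
  expect_equal(nrow(filter_variants(v36)$retained), 3)
  # overlapping windows union their removals
  v4 <- dplyr::bind_rows(mk_var(pos = 100), mk_var(pos = 115),
                         mk_var(pos = 130), mk_var(pos = 145))
  expect_equal(nrow(filter_variants(v4)$retained), 0)
})

test_that("excluded chromosomes are dropped first; missing values fail", {
  v <- dplyr::bind_rows(mk_var(chrom = "MT", pos = 10, fs = 31),
                        mk_var(chrom = "scaffold_9", pos = 20),
                        mk_var(pos = 900, fs = NA))
  f <- suppressMessages(filter_variants(v))
  expect_equal(f$counts$n[f$counts$rule == "excluded_chrom"], 2L)
  expect_equal(f$counts$n[f$counts$rule == "hard_FS"], 1L)
  expect_equal(nrow(f$retained), 0)
})

test_that("coding consequences come from strand-aware codon re-translation", {
  # '+' gene, single exon fully CDS at 101..130 (10 codons)
  ann <- toy_annotation(exon_starts = 101, exon_ends = 130,
                        cds_starts = 101, cds_ends = 130)
  base <- strrep("A", 250)
  genome <- c(`1` = base)
  # plant codon ATG at 104..106
  substr(genome[["1"]], 104, 106) <- "ATG"
  v <- mk_var(pos = 105, ref = "T", alt = "C")  # ATG -> ACG, Met -> Thr
  expect_equal(annotate_variants(v, ann, genome)$consequence, "nonsynonymous")
  # GCT -> GCC synonymous at third position
  substr(genome[["1"]], 107, 109) <- "GCT"
  v2 <- mk_var(pos = 109, ref = "T", alt = "C")
  expect_equal(annotate_variants(v2, ann, genome)$consequence, "synonymous")
  # TAC -> TAA creates a stop
  substr(genome[["1"]], 110, 112) <- "TAC"
  v3 <- mk_var(pos = 112, ref = "C", alt = "A")
  expect_equal(annotate_variants(v3, ann, genome)$consequence, "stop_affecting")
})

test_that("non-coding classes follow containment and window rules", {
  ann <- toy_annotation()  # exons 101-200, 301-400, 601-700; CDS 131-670
  genome <- c(`1` = strrep("A", 10000))
  cases <- list(
    list(pos = 110, cls = "utr5"),
    list(pos = 680, cls = "utr3"),
    list(pos = 205, cls = "splice_region"),   # 5 nt into the intron
    list(pos = 250, cls = "intron"),
    list(pos = 90, cls = "upstream"),
    list(pos = 800, cls = "downstream"),
    list(pos = 9000, cls = "intergenic"))
  for (cs in cases) {
    v <- mk_var(pos = cs$pos)
    expect_equal(annotate_variants(v, ann, genome)$consequence, cs$cls,
                 info = paste("pos", cs$pos))
  }
})

test_that("minus-strand annotation matches the CDS re-translation oracle", {
  sim <- simulate_genome(sim_config(seed = 17))
  genome <- sim$genome
  ann <- sim$annotation
  minus_tx <- ann$transcripts[ann$transcripts$strand == "-", ]
  withr::with_seed(4, {
    checked <- 0
    for (t in seq_len(nrow(minus_tx))) {
      txid <- minus_tx$transcript_id[t]
      cds <- ann$cds[ann$cds$transcript_id == txid, ]
      gpos <- unlist(lapply(seq_len(nrow(cds)), function(i) cds$start[i]:cds$end[i]))
      gpos <- gpos[seq_len(length(gpos) - length(gpos) %% 3)]
      for (k in sample(length(gpos), 4)) {
        pos <- gpos[k]
        ref <- substr(genome[[cds$chrom[1]]], pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        got <- annotate_variants(mk_var(chrom = cds$chrom[1], pos = pos,
                                        ref = ref, alt = alt),
                                 ann, genome)$consequence
        want <- oracle_coding_class(ann, genome, txid, cds$chrom[1], pos, alt)
        # another (overlapping) gene may make the call *more* severe, never less
        expect_lte(match(got, c("stop_affecting", "nonsynonymous",
                                "synonymous")),
                   match(want, c("stop_affecting", "nonsynonymous",
                                 "synonymous")))
        checked <- checked + 1
      }
      if (checked >= 40) break
    }
    expect_gte(checked, 20)
  })
})

test_that("substitution spectrum classifies transitions and transversions", {
  v <- tibble::tibble(ref = c("A", "G", "C", "A"), alt = c("G", "A", "T", "T"))
  s <- summarize_substitutions(v)
  expect_equal(s$n_transition, 3L)
  expect_equal(s$n_transversion, 1L)
  expect_equal(s$tstv_ratio, 3.00)
  expect_equal(sum(s$spectrum$n), 4L)

  all_tv <- tibble::tibble(ref = rep("A", 5), alt = rep("C", 5))
  s2 <- summarize_substitutions(all_tv)
  expect_equal(s2$tstv_ratio, 0)
  expect_equal(s2$n_transversion, 5L)
  # no transversions at all: the ratio is undefined, flagged as infinite
  all_ts <- tibble::tibble(ref = rep("A", 5), alt = rep("G", 5))
  s3 <- summarize_substitutions(all_ts)
  expect_true(s3$tstv_infinite)
  expect_true(is.na(s3$tstv_ratio))
})

test_that("per-gene counts honour overlap semantics and histogram bins", {
  ann <- two_gene_annotation(list(100L, 500L, "+"), list(300L, 900L, "+"))
  v <- mk_var(pos = 400)  # inside both spans
  pg <- per_gene_snp_counts(v, ann)
  expect_equal(sort(pg$per_gene$gene_id), c("GA", "GB"))
  expect_equal(pg$per_gene$n_snps, c(1L, 1L))

  v26 <- dplyr::bind_rows(lapply(seq(1000, by = 40, length.out = 26),
                                 function(p) mk_var(pos = p)))
  ann26 <- two_gene_annotation(list(900L, 2200L, "+"), list(5000L, 5100L, "+"))
  pg26 <- per_gene_snp_counts(v26, ann26)
  expect_equal(pg26$bins$n[pg26$bins$bin == ">25"], 1L)
  expect_equal(per_gene_snp_counts(mk_var(pos = 9999), ann26)$n_genes_with_snps, 0L)
})

test_that("catalogue matching requires allele agreement by default", {
  v <- dplyr::bind_rows(mk_var(pos = 10, ref = "A", alt = "G"),
                        mk_var(pos = 20, ref = "C", alt = "T"))
  cat <- tibble::tibble(chrom = "1", pos = c(10L, 20L), ref = c("A", "C"),
                        alt = c("G", "A"), id = c("rs1", "rs2"))
  res <- compare_dbsnp(v, cat)
  expect_equal(res$n_known, 1L)           # pos 20 alleles differ -> novel
  expect_equal(res$n_known + res$n_novel, 2L)
  res2 <- compare_dbsnp(v, cat, match_alleles = FALSE)
  expect_equal(res2$n_known, 2L)
  empty <- compare_dbsnp(v, cat[0, ])
  expect_equal(empty$pct_known, 0)
})

test_that("QTL overlap uses inclusive boundaries and set semantics", {
  regions <- tibble::tibble(
    chrom = "1", start = c(100L, 150L, 500L), end = c(200L, 250L, 600L),
    trait = c("growth", "growth", "meat"))
  v <- mk_var(pos = 200)  # at the boundary of region 1, inside region 2
  q <- qtl_overlap(v, regions)
  expect_equal(q$n_in_qtl, 1L)
  expect_equal(q$per_trait$n_snps[q$per_trait$trait == "growth"], 1L)
  expect_equal(q$n_regions_hit, 2L)
  # a SNP in 3 regions of 2 traits counts once per trait and once overall
  v3 <- mk_var(pos = 175)
  regions2 <- dplyr::bind_rows(regions,
                               tibble::tibble(chrom = "1", start = 160L,
                                              end = 180L, trait = "meat"))
  q3 <- qtl_overlap(v3, regions2)
  expect_equal(q3$n_in_qtl, 1L)
  expect_equal(sum(q3$per_trait$n_snps), 2L)
})
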