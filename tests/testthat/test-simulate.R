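# the generator runs with a reduced plan in most blocks to keep the suite
# fast; full-plan behaviour is exercised in the acceptance tests

small_config <- function(seed = 11) {
  sim_config(
    seed = seed,
    variant_class_counts = c(nonsynonymous = 6L, synonymous = 6L,
                             stop_affecting = 2L, splice_region = 3L,
                             utr5 = 3L, utr3 = 3L, intron = 8L,
                             upstream = 4L, downstream = 4L,
                             intergenic = 6L),
    n_fail_fs = 3L, n_fail_qd = 3L, n_fail_dp = 3L, n_clusters = 2L,
    n_scaffold_variants = 3L, n_mt_variants = 2L,
    ase_n_sites = 400L, n_background_reads = 20L)
}

test_that("identical seed and config give byte-identical artifacts", {
  cfg <- small_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_dataset(cfg), d1)
  p2 <- write_simulation(simulate_dataset(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readr::read_file(p1[[k]]), readr::read_file(p2[[k]]),
                     info = k)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  p3 <- write_simulation(simulate_dataset(small_config(seed = 12)), d3)
  expect_false(identical(readr::read_file(p1$variants),
                         readr::read_file(p3$variants)))
})

test_that("generated files close the loop through the package readers", {
  cfg <- small_config()
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_no_warning({
    genome <- read_genome_fasta(paths$genome)
    ann <- read_gtf(paths$annotation)
    vars <- read_vcf_snvs(paths$variants)
    ca <- read_fusion_candidates(paths$candidates_a)
    counts <- read_allele_counts(paths$allele_counts)
    qtl <- read_qtl_bed(paths$qtl)
    cat <- read_snp_catalogue(paths$dbsnp)
    reads <- read_fastq_seqs(paths$reads)
  })
  expect_equal(nchar(genome[["1"]]), cfg$chrom_length)
  expect_equal(nrow(ann$genes), nrow(sim$annotation$genes))
  expect_equal(nrow(vars), nrow(sim$variants$variants))
  expect_equal(vars$fs, round(sim$variants$variants$fs, 2))
  expect_equal(length(reads), length(sim$fusions$reads))
})

test_that("truth tables match the configured plan", {
  cfg <- small_config()
  sim <- simulate_dataset(cfg)
  tr <- sim$variants$truth
  pass <- tr[tr$fate == "pass", ]
  expect_equal(as.integer(table(pass$class)[names(cfg$variant_class_counts)]),
               unname(cfg$variant_class_counts))
  expect_equal(sum(tr$fate == "hard_QD"), 3L)
  expect_equal(sum(tr$fate == "cluster"), 6L)   # 2 clusters of 3
  expect_equal(sum(tr$fate == "excluded_chrom"), 5L)
  # ASE plan realised exactly
  expect_equal(sum(sim$ase$truth$is_ase_true),
               round(cfg$ase_fraction * cfg$ase_n_sites))
})

test_that("degenerate allele-count plans behave as stated", {
  cfg <- small_config()
  cfg$p_ase <- 1.0
  ac <- simulate_allele_counts(cfg)
  ase_rows <- ac$truth$is_ase_true
  expect_true(all(ac$sites$n_ref[ase_rows] == 0))
  cfg$ase_fraction <- 1.5
  expect_error(simulate_allele_counts(cfg), "ase_fraction")
})

test_that("infeasible plans fail before any file is written", {
  cfg <- small_config()
  cfg$n_background_genes <- 4L   # not enough for intra/inter pairs
  expect_error(simulate_genome(cfg), "infeasible")
  cfg2 <- small_config()
  cfg2$chrom_length <- 30000L    # genes cannot fit
  expect_error(simulate_genome(cfg2), "infeasible")
})

test_that("planned hard-filter and cluster fates are recovered by the filter", {
  sim <- simulate_dataset(small_config())
  f <- filter_variants(sim$variants$variants)
  tr <- sim$variants$truth
  key <- function(ch, p) paste(ch, p)
  expect_setequal(key(f$retained$chrom, f$retained$pos),
                  key(tr$chrom, tr$pos)[tr$fate == "pass"])
  merged <- dplyr::inner_join(f$removed, tr, by = c("chrom", "pos"))
  expect_true(all(merged$reason == merged$fate))
})
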