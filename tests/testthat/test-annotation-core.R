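test_that("strand-aware sequence extraction and bounds checking", {
  genome <- c(`1` = "AACGT")
  expect_equal(extract_sequence(genome, "1", 2, 4, "+"), "ACG")
  expect_equal(extract_sequence(genome, "1", 2, 4, "-"), "CGT")
  expect_equal(extract_sequence(genome, "1", 1, 5, "*"), "AACGT")
  expect_error(extract_sequence(genome, "1", 4, 9), "out of bounds")
  expect_error(extract_sequence(genome, "2", 1, 2), "unknown chromosome")
})

test_that("minus-strand extraction equals reverse complement of plus strand", {
  genome <- toy_genome(len = 300, seed = 7)
  withr::with_seed(11, {
    for (i in 1:25) {
      s <- sample(1:250, 1); e <- s + sample(0:49, 1)
      expect_equal(extract_sequence(genome, "1", s, e, "-"),
                   revcomp(extract_sequence(genome, "1", s, e, "+")))
    }
  })
})

test_that("codon translation follows the standard genetic code", {
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon("TAA"), "*")
  expect_equal(translate_codon("TAG"), "*")
  expect_equal(translate_codon("TGA"), "*")
  expect_true(is.na(translate_codon("ANG")))
  expect_error(translate_codon("AT"), "exactly 3 nt")
})

test_that("GTF structure is validated and errors name the offending line", {
  gtf_lines <- c(
    '1\tsrc\tgene\t100\t700\t.\t+\t.\tgene_id "G1"; gene_name "G1"; gene_biotype "protein_coding";',
    '1\tsrc\ttranscript\t100\t700\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    '1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    '1\tsrc\texon\t500\t700\t.\t+\t.\tgene_id "G1"; transcript_id "T1";')
  f <- withr::local_tempfile(fileext = ".gtf")
  readr::write_lines(gtf_lines, f)
  ann <- read_gtf(f)
  expect_equal(nrow(ann$exons), 2)
  expect_equal(nrow(ann$genes), 1)

  bad <- gtf_lines
  bad[4] <- '1\tsrc\texon\t700\t500\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'
  readr::write_lines(bad, f)
  expect_error(read_gtf(f), "line 4.*end < start")

  # exon outside the gene span is a structural error
  bad2 <- gtf_lines
  bad2[4] <- '1\tsrc\texon\t500\t900\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'
  readr::write_lines(bad2, f)
  expect_error(read_gtf(f), "outside gene span")

  # transcript referencing an absent gene
  bad3 <- gtf_lines[-1]
  readr::write_lines(bad3, f)
  expect_error(read_gtf(f), "absent gene")
})

test_that("GTF write/read round-trip preserves coordinates, strands, ids", {
  sim <- simulate_genome(sim_config(seed = 5, n_background_genes = 22,
                                    chrom_length = 500000L))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$annotation, f)
  back <- read_gtf(f)
  for (part in c("genes", "transcripts", "exons", "cds")) {
    expect_equal(as.data.frame(dplyr::arrange(back[[part]],
                                              dplyr::across(dplyr::everything()))),
                 as.data.frame(dplyr::arrange(sim$annotation[[part]],
                                              dplyr::across(dplyr::everything()))),
                 info = part)
  }
})

test_that("VCF write/read cycle preserves FS/QD/DP/AD and a rewrite is byte-identical", {
  v <- tibble::tibble(
    chrom = c("1", "1", "2"), pos = c(100L, 250L, 40L),
    id = c(NA, "rs1", NA), ref = c("A", "C", "G"), alt = c("G", "T", "C"),
    fs = c(0.12, 31.5, 2),  qd = c(12.34, 1.5, 30),
    dp = c(20L, 4L, 55L), genotype = c("het", "het", "hom_alt"),
    ad_ref = c(9L, 2L, 0L), ad_alt = c(11L, 2L, 55L))
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_snvs(v, f1)
  back <- read_vcf_snvs(f1)
  expect_equal(back$fs, v$fs)
  expect_equal(back$qd, v$qd)
  expect_equal(back$dp, v$dp)
  expect_equal(back$ad_ref, v$ad_ref)
  expect_equal(back$ad_alt, v$ad_alt)
  expect_equal(back$genotype, v$genotype)
  write_vcf_snvs(back, f2)
  expect_identical(readr::read_lines(f1), readr::read_lines(f2))
})

test_that("multi-allelic and non-SNV records are skipped on read", {
  f <- withr::local_tempfile(fileext = ".vcf")
  readr::write_lines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t10\t.\tA\tG,T\t.\t.\tFS=1.00;QD=10.00;DP=20\tGT:AD\t0/1:10,10",
    "1\t20\t.\tAT\tA\t.\t.\tFS=1.00;QD=10.00;DP=20\tGT:AD\t0/1:10,10",
    "1\t30\t.\tA\tG\t.\t.\tFS=1.00;QD=10.00;DP=20\tGT:AD\t0/1:10,10"), f)
  expect_message(x <- read_vcf_snvs(f), "skipped 2")
  expect_equal(nrow(x), 1)
  expect_equal(x$pos, 30L)
})

test_that("BED-style QTL input converts to 1-based inclusive and back", {
  f <- withr::local_tempfile(fileext = ".bed")
  readr::write_lines("1\t99\t200\tbirth_weight", f)
  r <- read_qtl_bed(f)
  expect_equal(r$start, 100L)
  expect_equal(r$end, 200L)
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_qtl_bed(r, f2)
  expect_identical(readr::read_lines(f2), "1\t99\t200\tbirth_weight")
  readr::write_lines("1\t100\t100\tx", f)
  expect_error(read_qtl_bed(f), "zero")
})
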