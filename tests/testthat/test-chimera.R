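test_that("consensus matching is by unordered gene pair", {
  a <- fusion_row("g1", "g2", caller = "A")
  b <- fusion_row("g2", "g1", caller = "B")
  expect_equal(nrow(consensus_candidates(a, b)), 1)

  a12 <- dplyr::bind_rows(lapply(1:12, function(i)
    fusion_row(sprintf("ga%02d", i), sprintf("gb%02d", i), caller = "A")))
  b9 <- dplyr::bind_rows(
    lapply(1:7, function(i) fusion_row(sprintf("ga%02d", i),
                                       sprintf("gb%02d", i), caller = "B")),
    lapply(1:2, function(i) fusion_row(sprintf("x%02d", i),
                                       sprintf("y%02d", i), caller = "B")))
  expect_equal(nrow(consensus_candidates(a12, b9)), 7)
  disjoint <- consensus_candidates(fusion_row("p", "q"), fusion_row("r", "s"))
  expect_equal(nrow(disjoint), 0)
})

test_that("consensus is symmetric in gene-pair membership and dedupes inputs", {
  a <- dplyr::bind_rows(fusion_row("g1", "g2"), fusion_row("g1", "g2"),
                        fusion_row("g3", "g4"))
  b <- dplyr::bind_rows(fusion_row("g2", "g1"), fusion_row("g5", "g6"))
  expect_message(ab <- consensus_candidates(a, b), "duplicate")
  ba <- suppressMessages(consensus_candidates(b, a))
  pairset <- function(x) sort(paste(pmin(x$gene5, x$gene3),
                                    pmax(x$gene5, x$gene3)))
  expect_equal(pairset(ab), pairset(ba))
})

test_that("structural classification follows the adjacency decision order", {
  cls1 <- classify_chimeras(
    fusion_row("GA", "GB"),
    two_gene_annotation(list(1000L, 2000L, "+"), list(2500L, 3500L, "+")),
    adjacency_max_gap = 1e5)
  expect_equal(cls1$class, "ADJACENT")
  expect_equal(cls1$subtype, "READ_THROUGH")

  cls2 <- classify_chimeras(
    fusion_row("GA", "GB"),
    two_gene_annotation(list(1000L, 2000L, "+"), list(2500L, 3500L, "-")))
  expect_equal(cls2$subtype, "CONVERGENT")

  cls3 <- classify_chimeras(
    fusion_row("GA", "GB"),
    two_gene_annotation(list(1000L, 2000L, "-"), list(2500L, 3500L, "+")))
  expect_equal(cls3$subtype, "DIVERGENT")

  cls4 <- classify_chimeras(
    fusion_row("GA", "GB", chrom3 = "2"),
    two_gene_annotation(list(1000L, 2000L, "+"), list(2500L, 3500L, "+"),
                        chrom_b = "2"))
  expect_equal(cls4$class, "INTERCHROMOSOMAL")

  # beyond the adjacency gap: plain intrachromosomal
  cls5 <- classify_chimeras(
    fusion_row("GA", "GB"),
    two_gene_annotation(list(1000L, 2000L, "+"), list(250000L, 251000L, "+")))
  expect_equal(cls5$class, "INTRACHROMOSOMAL")

  expect_error(
    classify_chimeras(fusion_row("GA", "nope"),
                      two_gene_annotation(list(1000L, 2000L, "+"),
                                          list(2500L, 3500L, "+"))),
    "unknown gene")
})

test_that("classification is total and orientation-order invariant", {
  sim <- simulate_genome(sim_config(seed = 9))
  fus <- simulate_fusions(sim_config(seed = 9), sim)
  cons <- consensus_candidates(fus$candidates_a, fus$candidates_b)
  cls <- classify_chimeras(cons, sim$annotation)
  expect_false(any(is.na(cls$class)))
  expect_true(all(is.na(cls$subtype) == (cls$class != "ADJACENT")))
})

test_that("GT/AG rule is checked strand-aware at both breakpoints", {
  # layout: donor dinucleotide right after break5=30, acceptor right before
  # break3=61
  g <- c(`1` = paste0(strrep("A", 30), "GT", strrep("A", 26),
                      "AG", strrep("A", 40)))
  cand <- fusion_row("x", "y", break5 = 30, break3 = 61)
  expect_true(check_canonical_splice(cand, g)$canonical)

  g_bad <- c(`1` = paste0(strrep("A", 30), "GC", strrep("A", 26),
                          "AG", strrep("A", 40)))
  expect_false(check_canonical_splice(cand, g_bad)$canonical)

  # minus-strand donor: forward-strand "AC" upstream of the breakpoint
  # reads GT in transcription direction
  g_minus <- c(`1` = paste0(strrep("A", 28), "ACT", strrep("A", 27),
                            "AG", strrep("A", 40)))
  cand_minus <- fusion_row("x", "y", break5 = 31, break3 = 61,
                           strand5 = "-")
  expect_true(check_canonical_splice(cand_minus, g_minus)$canonical)

  # breakpoint within 2 nt of the chromosome end: undetermined
  near_end <- fusion_row("x", "y", break5 = 99, break3 = 61)
  res <- check_canonical_splice(near_end, g)
  expect_false(res$canonical)
  expect_true(res$splice_undetermined)
})

test_that("canonical check agrees with a brute-force splice oracle", {
  # oracle: splice the two segments out of a toy genome and inspect the
  # first two bases of the removed downstream sequence and the last two of
  # the removed upstream sequence
  oracle <- function(cand, genome) {
    donor <- if (cand$strand5 == "+") {
      substr(genome[[cand$chrom5]], cand$break5 + 1, cand$break5 + 2)
    } else {
      revcomp(substr(genome[[cand$chrom5]], cand$break5 - 2, cand$break5 - 1))
    }
    acceptor <- if (cand$strand3 == "+") {
      substr(genome[[cand$chrom3]], cand$break3 - 2, cand$break3 - 1)
    } else {
      revcomp(substr(genome[[cand$chrom3]], cand$break3 + 1, cand$break3 + 2))
    }
    donor == "GT" && acceptor == "AG"
  }
  withr::with_seed(21, {
    for (i in 1:50) {
      genome <- toy_genome(len = 200, seed = i)
      cand <- fusion_row("x", "y",
                         break5 = sample(10:190, 1), break3 = sample(10:190, 1),
                         strand5 = sample(c("+", "-"), 1),
                         strand3 = sample(c("+", "-"), 1))
      expect_equal(check_canonical_splice(cand, genome)$canonical,
                   oracle(cand, genome))
    }
  })
})

test_that("junction reads are counted once each, on either strand", {
  genome <- toy_genome(len = 400, seed = 3)
  cand <- fusion_row("x", "y", break5 = 100, break3 = 250)
  probe <- junction_probe(cand, genome, 20)
  expect_equal(nchar(probe), 40)
  mk_read <- function(core) paste0(toy_genome(60, seed = nchar(core))[[1]],
                                   core, "ACGT")
  reads <- c(vapply(1:3, function(i) mk_read(probe), character(1)),
             mk_read(revcomp(probe)))
  expect_equal(count_junction_reads(cand, genome, reads), 4)
  expect_equal(count_junction_reads(cand, genome, c("ACGT", "GGCC")), 0)
})

test_that("homology hits need 20 mapped nt on both junction flanks", {
  hits <- tibble::tibble(
    query_id = c("h1", "h2", "h3"), subject_id = "human_tx",
    query_start = c(-25L, -20L, 5L), query_end = c(19L, 20L, 40L))
  out <- filter_junction_homology(hits)
  expect_equal(out$accepted, c(FALSE, TRUE, FALSE))
  expect_equal(out$flank3_mapped[1], 19L)
  expect_false(out$spans_junction[3])
})
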