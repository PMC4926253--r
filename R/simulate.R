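#' Simulation configuration for the synthetic-data generator
#'
#' Bundles every knob of the toy-data generator with the study's default
#' conditions: hard-filter thresholds and value ranges around the FS/QD/DP
#' cutoffs, a consequence-class plan, cluster and excluded-chromosome
#' variants, an ASE plan (5,000 sites, 20% true ASE with alternate-allele
#' probability 0.8, mean depth 100), a fusion plan covering all structural
#' classes with controlled consensus size and 90-nt junction reads, QTL
#' regions over a fixed trait list, and a known-SNP catalogue covering
#' 93.6% of retained variants. The same seed and config always produce
#' byte-identical artifacts; each artifact draws from its own stream
#' derived from the master seed.
#'
#' @param seed Master integer seed.
#' @param n_chromosomes,chrom_length Main chromosomes (named "1", "2", ...).
#'   A gene-free 10-kb `scaffold_1` and 5-kb `MT` are always appended.
#' @param n_background_genes Genes outside the designed fusion pairs
#'   (split evenly across chromosomes; at least 22 are needed by the
#'   default fusion plan).
#' @param exon_count_range,exon_length_range,intron_length_range Gene
#'   architecture ranges (uniform integer draws).
#' @param variant_class_counts Named integer vector of pass-fate variants
#'   per consequence class.
#' @param n_fail_fs,n_fail_qd,n_fail_dp Variants built to fail each hard
#'   filter.
#' @param n_clusters Clusters of 3 SNPs within 25 bases (removed by the
#'   35-base cluster rule).
#' @param n_scaffold_variants,n_mt_variants Variants on excluded
#'   chromosomes.
#' @param transition_prob Probability that a planted substitution is a
#'   transition when the class allows a choice.
#' @param ase_n_sites,ase_fraction,p_ase,ase_depth_mean ASE plan: site
#'   count, true-ASE fraction, alternate-allele probability at true-ASE
#'   sites (0.5 elsewhere), Poisson mean depth.
#' @param ase_nonsyn_prob_ase,ase_nonsyn_prob_balanced Probability that a
#'   site is nonsynonymous, for true-ASE and balanced sites (the gap drives
#'   the enrichment test).
#' @param fusion_class_counts Named integer vector of consensus candidates
#'   per structural class (`READ_THROUGH`, `CONVERGENT`, `DIVERGENT`,
#'   `OVERLAPPING`, `INTRACHROMOSOMAL`, `INTERCHROMOSOMAL`).
#' @param canonical_fraction Fraction of consensus candidates with planted
#'   GT/AG junctions (the rest get non-canonical dinucleotides).
#' @param support_mean Poisson mean of per-candidate junction-read support.
#' @param highlight_support Spanning-read count given to the first
#'   candidate (a fixed worked-example fixture).
#' @param n_extra_a,n_extra_b Caller-specific candidates outside the
#'   consensus.
#' @param read_length,probe_flank Junction-read geometry (nt).
#' @param n_background_reads Reads carrying no junction.
#' @param qtl_n_regions,qtl_region_length_range,qtl_traits QTL plan.
#' @param dbsnp_known_fraction Fraction of retained variants present in the
#'   catalogue.
#' @param dbsnp_n_extra,dbsnp_n_decoys Catalogue-only entries and
#'   same-position/different-allele decoys.
#' @param expr_total_reads Library size used for simulated counts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 600000L,
                       n_background_genes = 24L,
                       exon_count_range = c(3L, 5L),
                       exon_length_range = c(120L, 240L),
                       intron_length_range = c(300L, 900L),
                       variant_class_counts = c(
                         nonsynonymous = 40L, synonymous = 40L,
                         stop_affecting = 5L, splice_region = 10L,
                         utr5 = 15L, utr3 = 15L, intron = 60L,
                         upstream = 20L, downstream = 20L, intergenic = 40L),
                       n_fail_fs = 10L, n_fail_qd = 10L, n_fail_dp = 10L,
                       n_clusters = 4L,
                       n_scaffold_variants = 10L, n_mt_variants = 5L,
                       transition_prob = 0.70,
                       ase_n_sites = 5000L, ase_fraction = 0.2,
                       p_ase = 0.8, ase_depth_mean = 100,
                       ase_nonsyn_prob_ase = 0.12,
                       ase_nonsyn_prob_balanced = 0.04,
                       fusion_class_counts = c(
                         READ_THROUGH = 5L, CONVERGENT = 6L, DIVERGENT = 5L,
                         OVERLAPPING = 3L, INTRACHROMOSOMAL = 6L,
                         INTERCHROMOSOMAL = 2L),
                       canonical_fraction = 154 / 163,
                       support_mean = 15,
                       highlight_support = 37L,
                       n_extra_a = 6L, n_extra_b = 4L,
                       read_length = 90L, probe_flank = 20L,
                       n_background_reads = 150L,
                       qtl_n_regions = 24L,
                       qtl_region_length_range = c(20000L, 60000L),
                       qtl_traits = c("birth_weight", "average_daily_gain",
                                      "backfat_thickness", "loin_muscle_area",
                                      "intramuscular_fat", "drip_loss",
                                      "feed_conversion", "litter_size"),
                       dbsnp_known_fraction = 0.936,
                       dbsnp_n_extra = 30L, dbsnp_n_decoys = 5L,
                       expr_total_reads = 1e6) {
  fracs <- c(ase_fraction, p_ase, transition_prob, canonical_fraction,
             dbsnp_known_fraction, ase_nonsyn_prob_ase,
             ase_nonsyn_prob_balanced)
  if (any(fracs < 0 | fracs > 1)) abort("all fractions must lie in [0, 1]")
  if (ase_depth_mean <= 0) abort("ase_depth_mean must be > 0")
  structure(as.list(environment()), class = "sim_config")
}

rand_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# build one gene's exon table starting at `start` (genomic); returns list
# with exons tibble and span end
build_gene_exons <- function(start, config) {
  n_ex <- sample(config$exon_count_range[1]:config$exon_count_range[2], 1)
  ex_len <- sample(config$exon_length_range[1]:config$exon_length_range[2],
                   n_ex, replace = TRUE)
  in_len <- sample(config$intron_length_range[1]:config$intron_length_range[2],
                   max(0, n_ex - 1), replace = TRUE)
  starts <- integer(n_ex); ends <- integer(n_ex)
  cur <- start
  for (i in seq_len(n_ex)) {
    starts[i] <- cur
    ends[i] <- cur + ex_len[i] - 1L
    cur <- ends[i] + (if (i < n_ex) in_len[i] else 0L) + 1L
  }
  list(starts = starts, ends = ends, end = ends[n_ex])
}

# UTR sizes such that CDS length is a multiple of 3
utr_sizes <- function(exonic_len, u5 = 30L) {
  u3 <- 30L + (exonic_len - u5 - 30L) %% 3L
  c(u5 = u5, u3 = u3)
}

# assemble gene/transcript/exon/cds rows from an exon layout
gene_rows <- function(gene_id, chrom, strand, starts, ends) {
  exonic <- sum(ends - starts + 1L)
  u <- utr_sizes(exonic)
  span <- c(min(starts), max(ends))
  if (strand == "+") {
    cds_lo <- starts[1] + u[["u5"]]
    cds_hi <- ends[length(ends)] - u[["u3"]]
  } else {
    cds_lo <- starts[1] + u[["u3"]]
    cds_hi <- ends[length(ends)] - u[["u5"]]
  }
  cds <- purrr::map_dfr(seq_along(starts), function(i) {
    lo <- max(starts[i], cds_lo); hi <- min(ends[i], cds_hi)
    if (lo > hi) return(NULL)
    tibble(start = lo, end = hi)
  })
  txid <- sub("^G", "T", gene_id)
  list(
    gene = tibble(gene_id = gene_id, symbol = gene_id,
                  biotype = "protein_coding", chrom = chrom,
                  start = span[1], end = span[2], strand = strand),
    transcript = tibble(transcript_id = txid, gene_id = gene_id,
                        chrom = chrom, start = span[1], end = span[2],
                        strand = strand),
    exons = tibble(transcript_id = txid, gene_id = gene_id, chrom = chrom,
                   start = starts, end = ends, strand = strand),
    cds = tibble(transcript_id = txid, gene_id = gene_id, chrom = chrom,
                 start = cds$start, end = cds$end, strand = strand))
}

#' Generate the toy genome and annotation
#'
#' Places designed adjacent gene pairs in every orientation the fusion plan
#' needs (same-strand, convergent, divergent, exon-sharing), plus
#' background genes used for intra- and interchromosomal pairs, then fills
#' chromosomes with random sequence. A gene-free `scaffold_1` and `MT` are
#' appended for the chromosome-exclusion filter.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_genome` with `genome` (named character
#'   vector), `annotation` ([tx_annotation()]), `fusion_pairs` (tibble:
#'   `class`, `gene5`, `gene3`) and `background_genes` (character vector).
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed + 101L, {
    fc <- config$fusion_class_counts
    need_bg <- 3L * fc[["INTRACHROMOSOMAL"]] + 2L * fc[["INTERCHROMOSOMAL"]]
    if (config$n_background_genes < need_bg) {
      abort(sprintf("infeasible plan: %d background genes needed, %d configured",
                    need_bg, config$n_background_genes))
    }
    # unit list: designed pairs first, then overlap pairs, then singles
    units <- c(
      rep(list(list(kind = "pair", class = "READ_THROUGH", strands = c("+", "+"))),
          fc[["READ_THROUGH"]]),
      rep(list(list(kind = "pair", class = "CONVERGENT", strands = c("+", "-"))),
          fc[["CONVERGENT"]]),
      rep(list(list(kind = "pair", class = "DIVERGENT", strands = c("-", "+"))),
          fc[["DIVERGENT"]]),
      rep(list(list(kind = "overlap", class = "OVERLAPPING")),
          fc[["OVERLAPPING"]]))
    n_chrom <- config$n_chromosomes
    chroms <- as.character(seq_len(n_chrom))
    cursor <- setNames(rep(2001L, n_chrom), chroms)
    genes <- list(); transcripts <- list(); exons <- list(); cds <- list()
    pair_rows <- list()
    gi <- 0L
    next_id <- function() { gi <<- gi + 1L; sprintf("G%03d", gi) }
    add_gene <- function(rows) {
      genes[[length(genes) + 1L]] <<- rows$gene
      transcripts[[length(transcripts) + 1L]] <<- rows$transcript
      exons[[length(exons) + 1L]] <<- rows$exons
      cds[[length(cds) + 1L]] <<- rows$cds
    }
    place_unit <- function(unit, chrom) {
      start <- cursor[[chrom]]
      if (unit$kind == "pair") {
        idA <- next_id(); idB <- next_id()
        la <- build_gene_exons(start, config)
        add_gene(gene_rows(idA, chrom, unit$strands[1], la$starts, la$ends))
        gapped <- la$end + sample(800:2500, 1)
        lb <- build_gene_exons(gapped + 1L, config)
        add_gene(gene_rows(idB, chrom, unit$strands[2], lb$starts, lb$ends))
        pair_rows[[length(pair_rows) + 1L]] <<-
          tibble(class = unit$class, gene5 = idA, gene3 = idB)
        cursor[[chrom]] <<- lb$end + sample(8000:15000, 1)
      } else if (unit$kind == "overlap") {
        idA <- next_id(); idB <- next_id()
        la <- build_gene_exons(start, config)
        add_gene(gene_rows(idA, chrom, "+", la$starts, la$ends))
        # gene B starts at A's second exon (identical coordinates) and
        # continues past A's end
        b_starts <- la$starts[2]; b_ends <- la$ends[2]
        cur <- la$end + sample(300:600, 1)
        for (k in 1:2) {
          len <- sample(config$exon_length_range[1]:config$exon_length_range[2], 1)
          b_starts <- c(b_starts, cur)
          b_ends <- c(b_ends, cur + len - 1L)
          cur <- cur + len + sample(config$intron_length_range[1]:config$intron_length_range[2], 1)
        }
        add_gene(gene_rows(idB, chrom, "+", b_starts, b_ends))
        pair_rows[[length(pair_rows) + 1L]] <<-
          tibble(class = "OVERLAPPING", gene5 = idA, gene3 = idB)
        cursor[[chrom]] <<- max(b_ends) + sample(8000:15000, 1)
      } else {
        id <- next_id()
        l <- build_gene_exons(start, config)
        add_gene(gene_rows(id, chrom, sample(c("+", "-"), 1), l$starts, l$ends))
        cursor[[chrom]] <<- l$end + sample(8000:15000, 1)
        return(id)
      }
      invisible(NULL)
    }
    # spread designed units round-robin across chromosomes
    for (i in seq_along(units)) {
      place_unit(units[[i]], chroms[(i - 1L) %% n_chrom + 1L])
    }
    # background singles: consecutive blocks per chromosome so that
    # (i, i+2) triples have gene i+1 wholly inside the gap
    bg_per_chrom <- split(seq_len(config$n_background_genes),
                          rep(chroms, length.out = config$n_background_genes) |>
                            sort())
    background <- list()
    for (ch in chroms) {
      ids <- character(0)
      for (k in seq_along(bg_per_chrom[[ch]])) {
        ids <- c(ids, place_unit(list(kind = "single"), ch))
      }
      background[[ch]] <- ids
    }
    if (any(cursor > config$chrom_length - 2000L)) {
      abort("infeasible plan: genes do not fit in the configured chromosome length")
    }
    # intra- and interchromosomal pairs from background genes
    for (ch in chroms) {
      ids <- background[[ch]]
      n_tri <- fc[["INTRACHROMOSOMAL"]] %/% n_chrom +
        as.integer(match(ch, chroms) <= fc[["INTRACHROMOSOMAL"]] %% n_chrom)
      for (t in seq_len(n_tri)) {
        i <- (t - 1L) * 3L + 1L
        pair_rows[[length(pair_rows) + 1L]] <-
          tibble(class = "INTRACHROMOSOMAL", gene5 = ids[i], gene3 = ids[i + 2L])
      }
    }
    for (p in seq_len(fc[["INTERCHROMOSOMAL"]])) {
      g5 <- background[[chroms[1]]][9L + p]
      g3 <- background[[chroms[2]]][9L + p]
      pair_rows[[length(pair_rows) + 1L]] <-
        tibble(class = "INTERCHROMOSOMAL", gene5 = g5, gene3 = g3)
    }
    ann <- tx_annotation(dplyr::bind_rows(genes), dplyr::bind_rows(transcripts),
                         dplyr::bind_rows(exons), dplyr::bind_rows(cds))
    if (nrow(ann$genes) == 0) warn("simulate_genome: empty annotation")
    genome <- setNames(
      c(vapply(chroms, function(ch) rand_dna(config$chrom_length), character(1)),
        rand_dna(10000L), rand_dna(5000L)),
      c(chroms, "scaffold_1", "MT"))
    structure(list(genome = genome, annotation = ann,
                   fusion_pairs = dplyr::bind_rows(pair_rows),
                   background_genes = unname(unlist(background))),
              class = "sim_genome")
  })
}

# transcription-order exon table of a gene's (single) transcript
tx_exons_in_order <- function(annotation, gene_id) {
  ex <- annotation$exons[annotation$exons$gene_id == gene_id, ]
  ex <- ex[order(ex$start), ]
  if (ex$strand[1] == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  ex
}

# breakpoint of the 5' partner: transcription-direction end of its first
# exon; and of the 3' partner: transcription-direction start of its second
# exon
fusion_breakpoints <- function(annotation, gene5, gene3) {
  e5 <- tx_exons_in_order(annotation, gene5)
  e3 <- tx_exons_in_order(annotation, gene3)
  s5 <- e5$strand[1]; s3 <- e3$strand[1]
  b5 <- if (s5 == "+") e5$end[1] else e5$start[1]
  ex3 <- e3[min(2L, nrow(e3)), ]
  b3 <- if (s3 == "+") ex3$start else ex3$end
  list(chrom5 = e5$chrom[1], break5 = b5, strand5 = s5,
       chrom3 = e3$chrom[1], break3 = b3, strand3 = s3)
}

# plant donor/acceptor dinucleotides (canonical GT/AG or a non-canonical
# CC/CC read) around a breakpoint pair
plant_splice_sites <- function(genome, bp, canonical) {
  donor <- if (canonical) "GT" else "CC"
  accep <- if (canonical) "AG" else "CC"
  if (bp$strand5 == "+") {
    genome <- genome_edit(genome, bp$chrom5, bp$break5 + 1L, donor)
  } else {
    genome <- genome_edit(genome, bp$chrom5, bp$break5 - 2L, revcomp(donor))
  }
  if (bp$strand3 == "+") {
    genome <- genome_edit(genome, bp$chrom3, bp$break3 - 2L, accep)
  } else {
    genome <- genome_edit(genome, bp$chrom3, bp$break3 + 1L, revcomp(accep))
  }
  genome
}

#' Generate fusion candidates, junction reads and caller tables
#'
#' Realises the configured class plan over the designed gene pairs: plants
#' canonical GT/AG (or non-canonical) dinucleotides in the genome at each
#' consensus candidate's breakpoints, emits two caller tables whose
#' intersection is exactly the consensus set (plus caller-specific extras),
#' and writes junction reads embedding each candidate's probe — the first
#' candidate receives a fixed spanning-read count for worked examples.
#'
#' @param config A [sim_config()].
#' @param gsim A `sim_genome` from [simulate_genome()].
#' @return List with the edited `genome`, `candidates_a`, `candidates_b`,
#'   `reads` (named character vector) and `truth` (tibble with class,
#'   canonical flag, consensus flag and read support per candidate).
#' @export
simulate_fusions <- function(config, gsim) {
  withr::with_seed(config$seed + 202L, {
    ann <- gsim$annotation
    genome <- gsim$genome
    pairs <- gsim$fusion_pairs
    n <- nrow(pairs)
    n_noncanon <- n - round(config$canonical_fraction * n)
    canonical <- rep(TRUE, n)
    if (n_noncanon > 0) canonical[sample(n, n_noncanon)] <- FALSE
    support <- rpois(n, config$support_mean) + 1L
    support[1] <- config$highlight_support
    rows <- list(); truth <- list(); reads <- character(0)
    for (i in seq_len(n)) {
      bp <- fusion_breakpoints(ann, pairs$gene5[i], pairs$gene3[i])
      genome <- plant_splice_sites(genome, bp, canonical[i])
      rows[[i]] <- tibble(
        chrom5 = bp$chrom5, break5 = bp$break5, strand5 = bp$strand5,
        gene5 = pairs$gene5[i],
        chrom3 = bp$chrom3, break3 = bp$break3, strand3 = bp$strand3,
        gene3 = pairs$gene3[i],
        support = support[i])
      truth[[i]] <- tibble(
        gene5 = pairs$gene5[i], gene3 = pairs$gene3[i],
        class = pairs$class[i], canonical = canonical[i],
        consensus = TRUE, n_junction_reads = support[i])
    }
    consensus <- dplyr::bind_rows(rows)
    # junction reads: probe embedded at a random offset, half the reads
    # reverse-complemented
    for (i in seq_len(n)) {
      probe <- junction_probe(consensus[i, ], genome, config$probe_flank)
      for (r in seq_len(support[i])) {
        pad <- config$read_length - nchar(probe)
        off <- sample(0:pad, 1)
        seq <- paste0(rand_dna(off), probe, rand_dna(pad - off))
        if (runif(1) < 0.5) seq <- revcomp(seq)
        reads <- c(reads, setNames(seq, sprintf("read_c%02d_%03d", i, r)))
      }
    }
    if (config$n_background_reads > 0) {
      bg <- vapply(seq_len(config$n_background_reads),
                   function(i) rand_dna(config$read_length), character(1))
      reads <- c(reads, setNames(bg, sprintf("read_bg_%04d",
                                             seq_len(config$n_background_reads))))
    }
    # caller-specific extras: unused background-gene pairs, no genome edits
    used_keys <- purrr::map2_chr(pairs$gene5, pairs$gene3,
                                 ~ paste(sort(c(.x, .y)), collapse = "|"))
    bg <- gsim$background_genes
    extra_pairs <- list()
    tries <- 0L
    while (length(extra_pairs) < config$n_extra_a + config$n_extra_b &&
           tries < 2000L) {
      tries <- tries + 1L
      cand <- sample(bg, 2)
      key <- paste(sort(cand), collapse = "|")
      if (key %in% used_keys) next
      used_keys <- c(used_keys, key)
      extra_pairs[[length(extra_pairs) + 1L]] <- cand
    }
    mk_extra <- function(g5, g3) {
      bp <- fusion_breakpoints(ann, g5, g3)
      tibble(chrom5 = bp$chrom5, break5 = bp$break5, strand5 = bp$strand5,
             gene5 = g5, chrom3 = bp$chrom3, break3 = bp$break3,
             strand3 = bp$strand3, gene3 = g3,
             support = rpois(1, config$support_mean) + 1L)
    }
    extras <- purrr::map_dfr(extra_pairs, ~ mk_extra(.x[1], .x[2]))
    extra_a <- extras[seq_len(config$n_extra_a), ]
    extra_b <- extras[config$n_extra_a + seq_len(config$n_extra_b), ]
    # caller B reports some consensus rows with partners swapped, to make
    # the unordered gene-pair matching observable
    cons_b <- consensus
    swap <- seq(1, n, by = 5)
    tmp <- cons_b[swap, c("chrom5", "break5", "strand5", "gene5")]
    cons_b[swap, c("chrom5", "break5", "strand5", "gene5")] <-
      cons_b[swap, c("chrom3", "break3", "strand3", "gene3")]
    cons_b[swap, c("chrom3", "break3", "strand3", "gene3")] <- tmp
    candidates_a <- dplyr::bind_rows(consensus, extra_a) |>
      dplyr::mutate(caller = "chimerascan")
    candidates_b <- dplyr::bind_rows(cons_b, extra_b) |>
      dplyr::mutate(caller = "fusionmap")
    list(genome = genome, candidates_a = candidates_a,
         candidates_b = candidates_b, reads = reads,
         truth = dplyr::bind_rows(truth))
  })
}
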