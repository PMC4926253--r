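# shared fixture builders: everything is generated in code at test time

# one-gene annotation with explicit exon/CDS layout
toy_annotation <- function(strand = "+",
                           chrom = "1",
                           exon_starts = c(101, 301, 601),
                           exon_ends = c(200, 400, 700),
                           cds_starts = c(131, 301, 601),
                           cds_ends = c(200, 400, 670),
                           gene_id = "G001") {
  txid <- sub("^G", "T", gene_id)
  span <- c(min(exon_starts), max(exon_ends))
  tx_annotation(
    genes = tibble::tibble(gene_id = gene_id, symbol = gene_id,
                           biotype = "protein_coding", chrom = chrom,
                           start = span[1], end = span[2], strand = strand),
    transcripts = tibble::tibble(transcript_id = txid, gene_id = gene_id,
                                 chrom = chrom, start = span[1], end = span[2],
                                 strand = strand),
    exons = tibble::tibble(transcript_id = txid, gene_id = gene_id,
                           chrom = chrom, start = exon_starts,
                           end = exon_ends, strand = strand),
    cds = tibble::tibble(transcript_id = txid, gene_id = gene_id,
                         chrom = chrom, start = cds_starts, end = cds_ends,
                         strand = strand))
}

# annotation holding two genes given as (start, end, strand) on chrom(s),
# each a single exon spanning the gene (sufficient for classification)
two_gene_annotation <- function(a, b, chrom_a = "1", chrom_b = "1") {
  mk <- function(id, span, chrom) {
    txid <- sub("^G", "T", id)
    list(
      g = tibble::tibble(gene_id = id, symbol = id, biotype = "protein_coding",
                         chrom = chrom, start = span[[1]], end = span[[2]],
                         strand = span[[3]]),
      t = tibble::tibble(transcript_id = txid, gene_id = id, chrom = chrom,
                         start = span[[1]], end = span[[2]], strand = span[[3]]),
      e = tibble::tibble(transcript_id = txid, gene_id = id, chrom = chrom,
                         start = span[[1]], end = span[[2]], strand = span[[3]]))
  }
  ga <- mk("GA", a, chrom_a); gb <- mk("GB", b, chrom_b)
  tx_annotation(rbind(ga$g, gb$g), rbind(ga$t, gb$t), rbind(ga$e, gb$e),
                tibble::tibble(transcript_id = character(0),
                               gene_id = character(0), chrom = character(0),
                               start = integer(0), end = integer(0),
                               strand = character(0)))
}

toy_genome <- function(len = 1000, seed = 42, chroms = "1") {
  withr::with_seed(seed, {
    setNames(vapply(chroms, function(ch)
      paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1)), chroms)
  })
}

# candidate row helper
fusion_row <- function(gene5, gene3, chrom5 = "1", chrom3 = "1",
                       break5 = 0L, break3 = 0L, strand5 = "+",
                       strand3 = "+", support = 5L, caller = "test") {
  tibble::tibble(chrom5 = chrom5, break5 = as.integer(break5),
                 strand5 = strand5, gene5 = gene5, chrom3 = chrom3,
                 break3 = as.integer(break3), strand3 = strand3,
                 gene3 = gene3, support = as.integer(support),
                 caller = caller)
}

# independent consequence oracle: rebuild the spliced CDS, substitute the
# base, translate both proteins with Biostrings, and diff the amino acids
oracle_coding_class <- function(annotation, genome, txid, chrom, pos, alt) {
  cds <- annotation$cds[annotation$cds$transcript_id == txid, ]
  cds <- cds[order(cds$start), ]
  strand <- cds$strand[1]
  ref_seq <- paste0(vapply(seq_len(nrow(cds)), function(i)
    substr(genome[[chrom]], cds$start[i], cds$end[i]), character(1)),
    collapse = "")
  gpos <- unlist(lapply(seq_len(nrow(cds)), function(i) cds$start[i]:cds$end[i]))
  k <- match(pos, gpos)
  if (is.na(k)) stop("oracle: position not in CDS")
  alt_seq <- ref_seq
  substr(alt_seq, k, k) <- alt
  if (strand == "-") {
    ref_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref_seq)))
    alt_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(alt_seq)))
  }
  trim <- nchar(ref_seq) - nchar(ref_seq) %% 3
  p_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(ref_seq, 1, trim)), no.init.codon = TRUE))
  p_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(alt_seq, 1, trim)), no.init.codon = TRUE))
  if (p_ref == p_alt) return("synonymous")
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  a <- substr(p_ref, d, d); b <- substr(p_alt, d, d)
  if (xor(a == "*", b == "*")) "stop_affecting" else "nonsynonymous"
}
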