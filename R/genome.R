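#' Read a genome FASTA into a named sequence set
#'
#' Sequences are uppercased on read; names are truncated at the first
#' whitespace so they match GTF/VCF chromosome names.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named character vector, one uppercase nucleotide string per
#'   chromosome.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of sequences over \{A,C,G,T,N\}.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a strand-aware subsequence from a genome
#'
#' Coordinates are 1-based inclusive. For `strand = "-"` the reverse
#' complement of the forward-strand substring is returned, so the result
#' always reads in transcription direction.
#'
#' @param genome Named character vector (see [read_genome_fasta()]).
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded, treated as `"+"`).
#' @return The nucleotide string of length `end - start + 1`.
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    abort(paste0("unknown chromosome: ", chrom))
  }
  n <- nchar(genome[[chrom]])
  if (start < 1 || end > n) {
    abort(sprintf("interval %d-%d out of bounds for chromosome %s (length %d)",
                  start, end, chrom, n))
  }
  if (end < start) abort("end < start in extract_sequence()")
  s <- substr(genome[[chrom]], start, end)
  if (identical(strand, "-")) revcomp(s) else s
}

#' Translate a single codon under the standard genetic code
#'
#' @param codon A 3-nt string over \{A,C,G,T\}; any other character (for
#'   example `N`) yields an undetermined result.
#' @return One-letter amino-acid code, `"*"` for a stop codon, or `NA_character_`
#'   (undetermined) when the codon contains an ambiguous base.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L) abort("codon must be exactly 3 nt")
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[[codon]])
}

# vectorised internal variant (no validation beyond alphabet)
translate_codons <- function(codons) {
  vapply(codons, function(cd) {
    if (grepl("[^ACGT]", cd)) NA_character_ else unname(Biostrings::GENETIC_CODE[[cd]])
  }, character(1), USE.NAMES = FALSE)
}

# in-place replacement of genome bases, 1-based inclusive
genome_edit <- function(genome, chrom, start, replacement) {
  substr(genome[[chrom]], start, start + nchar(replacement) - 1L) <- replacement
  genome
}
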