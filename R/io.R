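#' Read biallelic SNVs from a VCF file
#'
#' Reads VCF 4.x via `vcfR`, keeping biallelic single-nucleotide variants
#' only; multi-allelic records and indels are skipped with a logged count.
#' The INFO keys `FS`, `QD`, `DP` and the FORMAT key `AD` (first sample) are
#' parsed into columns.
#'
#' @param path Path to a VCF file.
#' @return Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`, `fs`,
#'   `qd`, `dp`, `genotype`, `ad_ref`, `ad_alt`.
#' @export
read_vcf_snvs <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0) {
    return(tibble(chrom = character(0), pos = integer(0), id = character(0),
                  ref = character(0), alt = character(0), fs = double(0),
                  qd = double(0), dp = integer(0), genotype = character(0),
                  ad_ref = integer(0), ad_alt = integer(0)))
  }
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    inform(sprintf("read_vcf_snvs: skipped %d multi-allelic or non-SNV record(s)",
                   n_skip))
  }
  fs <- suppressWarnings(as.numeric(vcfR::extract.info(v, "FS")))[keep]
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(v, "QD")))[keep]
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))[keep]
  gt_raw <- vcfR::extract.gt(v, element = "GT")[keep, 1]
  ad_raw <- vcfR::extract.gt(v, element = "AD")[keep, 1]
  ad <- stringr::str_split_fixed(ad_raw, ",", 2)
  genotype <- dplyr::case_match(
    gsub("\\|", "/", gt_raw),
    "0/0" ~ "hom_ref",
    c("0/1", "1/0") ~ "het",
    "1/1" ~ "hom_alt",
    .default = "other")
  tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    id = dplyr::na_if(fix$ID[keep], "."),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    fs = fs, qd = qd, dp = dp,
    genotype = genotype,
    ad_ref = as.integer(ad[, 1]),
    ad_alt = as.integer(ad[, 2]))
}

#' Write biallelic SNVs to a VCF file
#'
#' Emits a minimal VCF 4.2 with INFO keys `FS`, `QD`, `DP` and FORMAT
#' `GT:AD` for one sample. `FS` and `QD` are printed with two decimals so
#' that a write/read/write cycle is byte-identical.
#'
#' @param variants Tibble as returned by [read_vcf_snvs()].
#' @param path Output path.
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf_snvs <- function(variants, path, sample = "sample1") {
  gt_code <- dplyr::case_match(variants$genotype,
    "hom_ref" ~ "0/0", "het" ~ "0/1", "hom_alt" ~ "1/1", .default = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled Fisher strand bias\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tFS=%.2f;QD=%.2f;DP=%d\tGT:AD\t%s:%d,%d",
                  variants$chrom, variants$pos,
                  dplyr::coalesce(variants$id, "."),
                  variants$ref, variants$alt,
                  variants$fs, variants$qd, variants$dp,
                  gt_code, variants$ad_ref, variants$ad_alt)
  readr::write_lines(c(header, rows), path)
  invisible(path)
}

#' Read a heterozygous-site allele-count table
#'
#' Accepts the tab-separated `chrom, pos, ref, alt, n_ref, n_alt` layout
#' (compatible with ASEReadCounter-style output after column selection).
#'
#' @param path Path to the TSV.
#' @return Tibble with those six columns.
#' @export
read_allele_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         pos = readr::col_integer(),
                         ref = readr::col_character(),
                         alt = readr::col_character(),
                         n_ref = readr::col_integer(),
                         n_alt = readr::col_integer()))
  if (any(x$n_ref < 0 | x$n_alt < 0)) {
    abort("negative allele counts in allele-count table")
  }
  x
}

#' Read a fusion-candidate table
#'
#' One row per candidate with 5' and 3' partner coordinates, caller tag and
#' support count (columns `chrom5, break5, strand5, gene5, chrom3, break3,
#' strand3, gene3, support, caller`).
#'
#' @param path Path to the TSV.
#' @return Tibble of candidates.
#' @export
read_fusion_candidates <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom5 = readr::col_character(),
                    break5 = readr::col_integer(),
                    strand5 = readr::col_character(),
                    gene5 = readr::col_character(),
                    chrom3 = readr::col_character(),
                    break3 = readr::col_integer(),
                    strand3 = readr::col_character(),
                    gene3 = readr::col_character(),
                    support = readr::col_integer(),
                    caller = readr::col_character()))
}

#' Read QTL regions from a BED-like file
#'
#' BED coordinates (0-based, half-open) are converted to the package's
#' 1-based inclusive convention on read; the 4th column is the trait label.
#' Zero-length regions are rejected.
#'
#' @param path Path to a 4-column BED/TSV file without header.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive), `trait`.
#' @export
read_qtl_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "bed_start", "bed_end", "trait"),
                       show_col_types = FALSE,
                       col_types = "ciic")
  if (any(x$bed_end <= x$bed_start)) {
    abort("zero- or negative-length QTL region in BED input")
  }
  tibble(chrom = x$chrom, start = x$bed_start + 1L, end = x$bed_end,
         trait = x$trait)
}

#' Write QTL regions to a BED-like file
#'
#' @param regions Tibble as returned by [read_qtl_bed()] (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qtl_bed <- function(regions, path) {
  readr::write_tsv(
    tibble(chrom = regions$chrom, bed_start = regions$start - 1L,
           bed_end = regions$end, trait = regions$trait),
    path, col_names = FALSE)
  invisible(path)
}

#' Read a known-SNP catalogue
#'
#' @param path TSV with columns `chrom, pos, ref, alt, id`.
#' @return Tibble of catalogue entries (duplicates deduplicated with a
#'   warning).
#' @export
read_snp_catalogue <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, col_types = "ciccc")
  n <- nrow(x)
  x <- dplyr::distinct(x)
  if (nrow(x) < n) {
    warn(sprintf("known-SNP catalogue: removed %d duplicate row(s)", n - nrow(x)))
  }
  x
}

#' Read sequencing reads from a FASTQ file
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return Character vector of read sequences, named by read id.
#' @export
read_fastq_seqs <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Write sequencing reads to a FASTQ file
#'
#' All bases receive the maximal placeholder quality `I`.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq_seqs <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals)
  invisible(path)
}
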