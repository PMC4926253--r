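#' Build a gene annotation object from feature tables
#'
#' The annotation container used throughout the package: a list of four
#' tibbles (`genes`, `transcripts`, `exons`, `cds`) with 1-based inclusive
#' coordinates, validated against the structural invariants a GTF implies
#' (exons sorted and non-overlapping within a transcript, CDS contained in
#' exons, transcript spans inside gene spans, consistent strands).
#'
#' @param genes Tibble with columns `gene_id`, `symbol`, `biotype`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param transcripts Tibble with `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param exons Tibble with `transcript_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param cds Tibble with the same columns as `exons` (may have zero rows).
#' @return An object of class `tx_annotation`.
#' @export
tx_annotation <- function(genes, transcripts, exons, cds) {
  ann <- structure(
    list(
      genes = as_tibble(genes),
      transcripts = as_tibble(transcripts),
      exons = dplyr::arrange(as_tibble(exons), .data$transcript_id, .data$start),
      cds = dplyr::arrange(as_tibble(cds), .data$transcript_id, .data$start)
    ),
    class = "tx_annotation"
  )
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  g <- ann$genes; tx <- ann$transcripts; ex <- ann$exons; cds <- ann$cds
  if (any(g$end < g$start)) abort("gene with end < start")
  bad_tx <- setdiff(tx$gene_id, g$gene_id)
  if (length(bad_tx) > 0) {
    abort(paste0("transcript references absent gene: ", bad_tx[1]))
  }
  if (nrow(ex) > 0) {
    # exon containment in gene span
    j <- dplyr::left_join(ex, g[, c("gene_id", "start", "end")],
                          by = "gene_id", suffix = c("", ".gene"))
    out <- j$start < j$start.gene | j$end > j$end.gene
    if (any(out)) {
      abort(paste0("exon outside gene span for gene ", j$gene_id[which(out)[1]]))
    }
    # non-overlap within transcript
    ov <- ex |>
      dplyr::group_by(.data$transcript_id) |>
      dplyr::summarise(bad = any(.data$start[-1] <= cummax(.data$end)[-dplyr::n()]),
                       .groups = "drop")
    if (any(ov$bad, na.rm = TRUE)) {
      abort(paste0("overlapping exons in transcript ",
                   ov$transcript_id[which(ov$bad)[1]]))
    }
  }
  if (nrow(cds) > 0) {
    # every CDS interval inside some exon of its transcript
    j <- dplyr::inner_join(cds, ex, by = "transcript_id",
                           suffix = c("", ".ex"), relationship = "many-to-many")
    ok <- j |>
      dplyr::group_by(.data$transcript_id, .data$start, .data$end) |>
      dplyr::summarise(
        hit = any(.data$start >= .data$start.ex & .data$end <= .data$end.ex),
        .groups = "drop")
    if (any(!ok$hit)) {
      abort(paste0("CDS interval not contained in any exon of transcript ",
                   ok$transcript_id[which(!ok$hit)[1]]))
    }
  }
  invisible(ann)
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat(sprintf("<tx_annotation> %d genes, %d transcripts, %d exons, %d CDS intervals\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

gtf_attr <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0(key, ' "([^"]*)"'))[, 2]
  m
}

#' Read a GTF annotation file
#'
#' Supports the gene/transcript/exon/CDS feature set; other feature tags are
#' ignored with a warning. Coordinates are kept 1-based inclusive as in the
#' file. Malformed rows (non-integer coordinates, `end < start`) raise an
#' error naming the offending line.
#'
#' @param path Path to a GTF file.
#' @return A [tx_annotation()] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("GTF file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  fields <- stringr::str_split(lines[keep], "\t")
  nf <- lengths(fields)
  if (any(nf < 9)) {
    abort(sprintf("GTF parse error at line %d: expected 9 tab-separated fields",
                  lineno[which(nf < 9)[1]]))
  }
  mat <- do.call(rbind, lapply(fields, `[`, 1:9))
  start <- suppressWarnings(as.integer(mat[, 4]))
  end <- suppressWarnings(as.integer(mat[, 5]))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    abort(sprintf("GTF parse error at line %d: non-integer coordinates",
                  lineno[which(bad)[1]]))
  }
  rev_bad <- end < start
  if (any(rev_bad)) {
    abort(sprintf("GTF parse error at line %d: end < start",
                  lineno[which(rev_bad)[1]]))
  }
  feat <- tibble(
    chrom = mat[, 1], feature = mat[, 3], start = start, end = end,
    strand = mat[, 7], attrs = mat[, 9]
  )
  known <- c("gene", "transcript", "exon", "CDS")
  unknown <- setdiff(unique(feat$feature), known)
  if (length(unknown) > 0) {
    warn(paste0("ignoring unknown GTF feature tags: ",
                paste(unknown, collapse = ", ")))
    feat <- dplyr::filter(feat, .data$feature %in% known)
  }
  feat$gene_id <- gtf_attr(feat$attrs, "gene_id")
  feat$transcript_id <- gtf_attr(feat$attrs, "transcript_id")
  feat$symbol <- gtf_attr(feat$attrs, "gene_name")
  feat$biotype <- gtf_attr(feat$attrs, "gene_biotype")

  genes <- feat |>
    dplyr::filter(.data$feature == "gene") |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      symbol = dplyr::coalesce(.data$symbol, .data$gene_id),
      biotype = dplyr::coalesce(.data$biotype, "protein_coding"),
      chrom = .data$chrom, start = .data$start, end = .data$end,
      strand = .data$strand)
  transcripts <- feat |>
    dplyr::filter(.data$feature == "transcript") |>
    dplyr::transmute(transcript_id = .data$transcript_id,
                     gene_id = .data$gene_id, chrom = .data$chrom,
                     start = .data$start, end = .data$end,
                     strand = .data$strand)
  pick <- function(tag) {
    feat |>
      dplyr::filter(.data$feature == tag) |>
      dplyr::transmute(transcript_id = .data$transcript_id,
                       gene_id = .data$gene_id, chrom = .data$chrom,
                       start = .data$start, end = .data$end,
                       strand = .data$strand)
  }
  tx_annotation(genes, transcripts, pick("exon"), pick("CDS"))
}

#' Write an annotation to GTF
#'
#' Round-trips with [read_gtf()]: coordinates, strands and identifiers are
#' preserved exactly.
#'
#' @param annotation A [tx_annotation()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  g <- annotation$genes
  gene_rows <- sprintf(
    '%s\ttxevents\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; gene_biotype "%s";',
    g$chrom, g$start, g$end, g$strand, g$gene_id, g$symbol, g$biotype)
  fmt_child <- function(df, tag) {
    if (nrow(df) == 0) return(character(0))
    sprintf('%s\ttxevents\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            df$chrom, tag, df$start, df$end, df$strand, df$gene_id,
            df$transcript_id)
  }
  rows <- c(gene_rows,
            fmt_child(annotation$transcripts, "transcript"),
            fmt_child(annotation$exons, "exon"),
            fmt_child(annotation$cds, "CDS"))
  readr::write_lines(rows, path)
  invisible(path)
}

#' Exonic length of each gene (union of exons across transcripts)
#'
#' The per-gene exon model length used for RPKM: the number of genomic bases
#' covered by at least one exon of any transcript of the gene.
#'
#' @param annotation A [tx_annotation()] object.
#' @return Tibble with `gene_id` and `exonic_length`.
#' @export
gene_exonic_lengths <- function(annotation) {
  ex <- annotation$exons
  if (nrow(ex) == 0) return(tibble(gene_id = character(0), exonic_length = integer(0)))
  ex |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      exonic_length = sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = .data$start, end = .data$end)))),
      .groups = "drop")
}

# transcription-direction map of a transcript's CDS: tibble of genomic
# positions in translation order with codon index and within-codon offset
cds_position_map <- function(annotation, transcript_id) {
  cds <- annotation$cds[annotation$cds$transcript_id == transcript_id, ]
  if (nrow(cds) == 0) return(NULL)
  pos <- unlist(lapply(seq_len(nrow(cds)), function(i) cds$start[i]:cds$end[i]))
  pos <- sort(pos)
  strand <- cds$strand[1]
  if (strand == "-") pos <- rev(pos)
  tibble(
    pos = pos,
    cds_index = seq_along(pos),
    codon = (seq_along(pos) - 1L) %/% 3L + 1L,
    offset = (seq_along(pos) - 1L) %% 3L + 1L,
    strand = strand,
    chrom = cds$chrom[1]
  )
}
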