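#' Consensus of two fusion-caller candidate lists
#'
#' A candidate is in the consensus when the other caller reports the same
#' unordered gene pair. Coordinates and support of the consensus row are
#' taken from the first list (first-caller precedence); when the second
#' caller's breakpoints also agree within `tolerance` bases the match is
#' flagged in `breakpoint_match`. Identical duplicate rows within one list
#' are deduplicated with a logged count.
#'
#' @param list_a,list_b Candidate tibbles (see [read_fusion_candidates()]).
#' @param tolerance Maximum breakpoint distance (bases) for
#'   `breakpoint_match`; default 10.
#' @return Tibble of consensus candidates (columns of `list_a` plus
#'   `candidate_id`, `support_b`, `breakpoint_match`).
#' @export
consensus_candidates <- function(list_a, list_b, tolerance = 10) {
  if (tolerance < 0) abort("tolerance must be >= 0")
  dedupe <- function(x, tag) {
    n <- nrow(x)
    x <- dplyr::distinct(x)
    if (nrow(x) < n) {
      inform(sprintf("consensus_candidates: removed %d duplicate row(s) from %s",
                     n - nrow(x), tag))
    }
    x
  }
  a <- dedupe(list_a, "list A")
  b <- dedupe(list_b, "list B")
  pair_key <- function(x) {
    paste(pmin(x$gene5, x$gene3), pmax(x$gene5, x$gene3), sep = "|")
  }
  a$.pair <- pair_key(a)
  b$.pair <- pair_key(b)
  # one consensus row per gene pair, first-caller precedence for coordinates
  a <- dplyr::distinct(a, .data$.pair, .keep_all = TRUE)
  b <- dplyr::distinct(b, .data$.pair, .keep_all = TRUE)
  m <- dplyr::inner_join(
    a, b[, c(".pair", "break5", "break3", "support")],
    by = ".pair", suffix = c("", "_b"))
  bp_match <- (abs(m$break5 - m$break5_b) <= tolerance &
                 abs(m$break3 - m$break3_b) <= tolerance) |
    (abs(m$break5 - m$break3_b) <= tolerance &
       abs(m$break3 - m$break5_b) <= tolerance)
  out <- m |>
    dplyr::mutate(breakpoint_match = bp_match) |>
    dplyr::select(-".pair", -"break5_b", -"break3_b") |>
    dplyr::mutate(candidate_id = sprintf("chimera_%03d", dplyr::row_number()),
                  .before = 1)
  out
}

#' Structurally classify fusion candidates
#'
#' Decision order per candidate: partners on different chromosomes are
#' `INTERCHROMOSOMAL`; partners sharing at least one exon with identical
#' coordinates are adjacent `OVERLAPPING`; partners whose gene spans overlap
#' or lie within `adjacency_max_gap` bases with no third gene wholly inside
#' the gap are adjacent — same strand `READ_THROUGH`, opposite strands
#' `DIVERGENT` when the two 5' ends face the gap and `CONVERGENT` when the
#' two 3' ends do; everything else is `INTRACHROMOSOMAL`.
#'
#' @param candidates Candidate tibble with `gene5`, `gene3` columns.
#' @param annotation A [tx_annotation()] object containing both partners.
#' @param adjacency_max_gap Maximum intergenic gap (bases) for adjacency;
#'   default 1e5.
#' @return `candidates` with columns `class` (top level) and `subtype`
#'   (`NA` unless `class == "ADJACENT"`).
#' @export
classify_chimeras <- function(candidates, annotation, adjacency_max_gap = 1e5) {
  g <- annotation$genes
  ex <- annotation$exons
  exon_keys <- split(paste(ex$chrom, ex$start, ex$end), ex$gene_id)
  cls <- purrr::map(seq_len(nrow(candidates)), function(i) {
    id5 <- candidates$gene5[i]; id3 <- candidates$gene3[i]
    g5 <- g[g$gene_id == id5, ]; g3 <- g[g$gene_id == id3, ]
    if (nrow(g5) == 0 || nrow(g3) == 0) {
      abort(sprintf("unknown gene id in candidate %s-%s", id5, id3))
    }
    if (g5$chrom != g3$chrom) {
      return(list(class = "INTERCHROMOSOMAL", subtype = NA_character_))
    }
    shared <- length(intersect(exon_keys[[id5]] %||% character(0),
                               exon_keys[[id3]] %||% character(0))) > 0
    if (shared) return(list(class = "ADJACENT", subtype = "OVERLAPPING"))
    # order partners along the chromosome
    if (g5$start <= g3$start) { left <- g5; right <- g3 } else { left <- g3; right <- g5 }
    gap <- right$start - left$end - 1L
    adjacent <- gap <= adjacency_max_gap
    if (adjacent && gap > 0) {
      inside <- g$gene_id != id5 & g$gene_id != id3 & g$chrom == g5$chrom &
        g$start > left$end & g$end < right$start
      if (any(inside)) adjacent <- FALSE
    }
    if (!adjacent) {
      return(list(class = "INTRACHROMOSOMAL", subtype = NA_character_))
    }
    if (left$strand == right$strand) {
      return(list(class = "ADJACENT", subtype = "READ_THROUGH"))
    }
    # opposite strands: which ends face the gap between the spans?
    # left gene contributes its right (downstream-coordinate) end,
    # right gene its left end; '+' left end is the 5' end, etc.
    sub <- if (left$strand == "-") "DIVERGENT" else "CONVERGENT"
    list(class = "ADJACENT", subtype = sub)
  })
  candidates |>
    dplyr::mutate(class = purrr::map_chr(cls, "class"),
                  subtype = purrr::map_chr(cls, "subtype"))
}

#' Verify canonical GT/AG dinucleotides at a fusion junction
#'
#' True when the strand-aware genomic dinucleotide immediately downstream
#' of the 5' breakpoint reads `GT` (donor) and the dinucleotide immediately
#' upstream of the 3' breakpoint reads `AG` (acceptor). For a minus-strand
#' partner, positions step toward decreasing coordinates and bases are
#' complemented. Breakpoints within 2 nt of a chromosome end cannot be
#' evaluated and are reported non-canonical with `splice_undetermined`.
#'
#' @param candidates Candidate tibble with `chrom5`, `break5`, `strand5`,
#'   `chrom3`, `break3`, `strand3`.
#' @param genome Named character vector of chromosome sequences.
#' @return `candidates` with logical columns `canonical` and
#'   `splice_undetermined`.
#' @export
check_canonical_splice <- function(candidates, genome) {
  res <- purrr::map(seq_len(nrow(candidates)), function(i) {
    x <- candidates[i, ]
    len5 <- nchar(genome[[x$chrom5]])
    len3 <- nchar(genome[[x$chrom3]])
    donor_ok <- if (x$strand5 == "-") x$break5 - 2 >= 1 else x$break5 + 2 <= len5
    accep_ok <- if (x$strand3 == "-") x$break3 + 2 <= len3 else x$break3 - 2 >= 1
    if (!donor_ok || !accep_ok) {
      return(list(canonical = FALSE, undetermined = TRUE))
    }
    donor <- if (x$strand5 == "-") {
      extract_sequence(genome, x$chrom5, x$break5 - 2, x$break5 - 1, "-")
    } else {
      extract_sequence(genome, x$chrom5, x$break5 + 1, x$break5 + 2, "+")
    }
    acceptor <- if (x$strand3 == "-") {
      extract_sequence(genome, x$chrom3, x$break3 + 1, x$break3 + 2, "-")
    } else {
      extract_sequence(genome, x$chrom3, x$break3 - 2, x$break3 - 1, "+")
    }
    list(canonical = donor == "GT" && acceptor == "AG", undetermined = FALSE)
  })
  candidates |>
    dplyr::mutate(canonical = purrr::map_lgl(res, "canonical"),
                  splice_undetermined = purrr::map_lgl(res, "undetermined"))
}

#' Junction probe sequence for a fusion candidate
#'
#' Concatenates the last `flank` transcribed nucleotides of the 5' segment
#' with the first `flank` transcribed nucleotides of the 3' segment,
#' reverse-complementing minus-strand partners.
#'
#' @param candidate One-row candidate tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param flank Nucleotides taken from each side of the junction.
#' @return The probe string of length `2 * flank`.
#' @export
junction_probe <- function(candidate, genome, flank = 20) {
  x <- candidate
  side5 <- if (x$strand5 == "-") {
    extract_sequence(genome, x$chrom5, x$break5, x$break5 + flank - 1, "-")
  } else {
    extract_sequence(genome, x$chrom5, x$break5 - flank + 1, x$break5, "+")
  }
  side3 <- if (x$strand3 == "-") {
    extract_sequence(genome, x$chrom3, x$break3 - flank + 1, x$break3, "-")
  } else {
    extract_sequence(genome, x$chrom3, x$break3, x$break3 + flank - 1, "+")
  }
  paste0(side5, side3)
}

#' Count reads spanning a fusion junction
#'
#' Exact-substring search (the in-silico analogue of grepping the FASTQ):
#' a read is counted when it contains the junction probe or its reverse
#' complement; each read is counted at most once.
#'
#' @param candidate One-row candidate tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param reads Character vector of read sequences (see [read_fastq_seqs()]).
#' @param probe_flank Nucleotides per junction side in the probe (>= 10).
#' @return Integer count of spanning reads.
#' @export
count_junction_reads <- function(candidate, genome, reads, probe_flank = 20) {
  if (probe_flank < 10) abort("probe_flank must be >= 10")
  probe <- junction_probe(candidate, genome, probe_flank)
  if (grepl("N", probe, fixed = TRUE)) {
    abort("junction probe contains N; try a smaller probe_flank")
  }
  hit <- stringr::str_detect(reads, stringr::fixed(probe)) |
    stringr::str_detect(reads, stringr::fixed(revcomp(probe)))
  sum(hit)
}

#' Apply the cross-species flank-coverage filter to junction alignment hits
#'
#' A hit against another species' chimeric transcript set is accepted only
#' when the aligned query segment covers at least `min_flank` nucleotides on
#' both sides of the fusion junction. Hits not overlapping the junction are
#' rejected and flagged.
#'
#' @param hits Tibble with `query_id`, `subject_id`, `query_start`,
#'   `query_end` — query coordinates relative to the junction: positions
#'   -1, -2, ... lie 5' of the junction, +1, +2, ... lie 3' of it (there is
#'   no position 0).
#' @param min_flank Minimum mapped nucleotides per side (default 20).
#' @return `hits` with logical columns `spans_junction` and `accepted`, plus
#'   `flank5_mapped` / `flank3_mapped` counts.
#' @export
filter_junction_homology <- function(hits, min_flank = 20) {
  hits |>
    dplyr::mutate(
      flank5_mapped = pmax(0L, pmin(.data$query_end, -1L) - .data$query_start + 1L),
      flank3_mapped = pmax(0L, .data$query_end - pmax(.data$query_start, 1L) + 1L),
      spans_junction = .data$query_start <= -1L & .data$query_end >= 1L,
      accepted = .data$spans_junction &
        .data$flank5_mapped >= min_flank & .data$flank3_mapped >= min_flank)
}

#' Summarise a classified candidate set
#'
#' Counts and percentages (1 decimal) of the top-level class partition,
#' adjacent subtypes, and — when present — the canonical GT/AG fraction.
#'
#' @param classified Tibble from [classify_chimeras()], optionally after
#'   [check_canonical_splice()].
#' @return List with tibbles `classes`, `subtypes` and (optionally) a
#'   one-row `canonical` summary.
#' @export
summarize_chimera_classes <- function(classified) {
  n_total <- nrow(classified)
  classes <- classified |>
    dplyr::count(.data$class, name = "n") |>
    dplyr::mutate(pct = vapply(.data$n, pct1, numeric(1), den = n_total))
  subtypes <- classified |>
    dplyr::filter(.data$class == "ADJACENT") |>
    dplyr::count(.data$subtype, name = "n")
  out <- list(classes = classes, subtypes = subtypes, n = n_total)
  if ("canonical" %in% names(classified)) {
    out$canonical <- tibble(
      n_canonical = sum(classified$canonical),
      n = n_total,
      pct_canonical = pct1(sum(classified$canonical), n_total))
  }
  out
}

#' Plot the structural class partition of a chimera set
#'
#' @param classified Tibble from [classify_chimeras()].
#' @return A ggplot bar chart of classes, adjacent candidates split by
#'   subtype.
#' @export
plot_chimera_classes <- function(classified) {
  d <- classified |>
    dplyr::mutate(group = ifelse(.data$class == "ADJACENT",
                                 paste0("ADJACENT/", .data$subtype), .data$class))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, fill = .data$class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "candidates") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
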