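#' Filter RNA-seq SNVs: chromosome exclusion, hard filters, cluster filter
#'
#' Removal order: (1) variants on excluded chromosomes (unplaced scaffolds
#' and mitochondria by default); (2) hard filters — `FS > fs_max`,
#' `QD < qd_min` or `DP < dp_min`, boundary values retained, missing values
#' treated as failing; (3) cluster filter — for positions sorted per
#' chromosome, any `cluster_size` consecutive variants spanning at most
#' `cluster_window` bases (inclusive span) are all removed, overlapping
#' windows unioned. Duplicate site+allele rows are collapsed with a warning.
#'
#' @param variants Tibble from [read_vcf_snvs()].
#' @param fs_max,qd_min,dp_min Hard-filter thresholds (defaults 30.0, 2.0, 5).
#' @param cluster_size,cluster_window Cluster rule (defaults 3 SNPs / 35 bases).
#' @param exclude_chroms Regular expressions; a chromosome matching any of
#'   them is excluded. Default drops scaffold-like names and `MT`.
#' @return Object of class `variant_filter`: list with `retained` (tibble),
#'   `removed` (tibble with a `reason` column) and `counts` (per-rule
#'   removal counts; reasons are mutually exclusive in the order
#'   excluded_chrom, FS, QD, DP, cluster, so counts plus retained sum to
#'   the input).
#' @export
filter_variants <- function(variants,
                            fs_max = 30.0, qd_min = 2.0, dp_min = 5L,
                            cluster_size = 3L, cluster_window = 35L,
                            exclude_chroms = c("^scaffold", "^GL", "^AEMK",
                                               "^JH", "^MT$", "^chrM$")) {
  n0 <- nrow(variants)
  variants <- dplyr::distinct(variants, .data$chrom, .data$pos, .data$ref,
                              .data$alt, .keep_all = TRUE)
  if (nrow(variants) < n0) {
    warn(sprintf("filter_variants: collapsed %d duplicate site+allele row(s)",
                 n0 - nrow(variants)))
  }
  variants <- dplyr::arrange(variants, .data$chrom, .data$pos)

  excl_pat <- paste(exclude_chroms, collapse = "|")
  excluded <- stringr::str_detect(variants$chrom, excl_pat)
  if (any(is.na(variants$fs) | is.na(variants$qd) | is.na(variants$dp))) {
    inform("filter_variants: records with missing FS/QD/DP treated as failing")
  }
  fail_fs <- is.na(variants$fs) | variants$fs > fs_max
  fail_qd <- is.na(variants$qd) | variants$qd < qd_min
  fail_dp <- is.na(variants$dp) | variants$dp < dp_min

  reason <- rep(NA_character_, nrow(variants))
  reason[excluded] <- "excluded_chrom"
  reason[is.na(reason) & fail_fs] <- "hard_FS"
  reason[is.na(reason) & fail_qd] <- "hard_QD"
  reason[is.na(reason) & fail_dp] <- "hard_DP"

  # cluster filter over survivors of steps (1)-(2)
  surv <- which(is.na(reason))
  sv <- variants[surv, ]
  cluster_hit <- rep(FALSE, length(surv))
  for (ch in unique(sv$chrom)) {
    idx <- which(sv$chrom == ch)
    p <- sv$pos[idx]  # already sorted
    k <- cluster_size
    if (length(p) >= k) {
      for (i in seq_len(length(p) - k + 1L)) {
        if (p[i + k - 1L] - p[i] + 1L <= cluster_window) {
          cluster_hit[idx[i:(i + k - 1L)]] <- TRUE
        }
      }
    }
  }
  reason[surv[cluster_hit]] <- "cluster"

  retained <- variants[is.na(reason), ]
  removed <- variants[!is.na(reason), ]
  removed$reason <- reason[!is.na(reason)]
  counts <- tibble(
    rule = c("excluded_chrom", "hard_FS", "hard_QD", "hard_DP", "cluster"),
    n = c(sum(reason == "excluded_chrom", na.rm = TRUE),
          sum(reason == "hard_FS", na.rm = TRUE),
          sum(reason == "hard_QD", na.rm = TRUE),
          sum(reason == "hard_DP", na.rm = TRUE),
          sum(reason == "cluster", na.rm = TRUE)))
  structure(list(retained = retained, removed = removed, counts = counts,
                 n_input = nrow(variants)),
            class = "variant_filter")
}

#' @export
print.variant_filter <- function(x, ...) {
  cat(sprintf("<variant_filter> %d in, %d retained\n", x$n_input,
              nrow(x$retained)))
  print(x$counts)
  invisible(x)
}

#' @rdname filter_variants
#' @param x A `variant_filter` object.
#' @param ... Unused.
#' @export
tidy.variant_filter <- function(x, ...) x$counts

#' @rdname filter_variants
#' @export
glance.variant_filter <- function(x, ...) {
  tibble(n_input = x$n_input, n_retained = nrow(x$retained),
         n_removed = nrow(x$removed))
}

severity_order <- c("stop_affecting", "nonsynonymous", "synonymous",
                    "splice_region", "utr5", "utr3", "intron",
                    "upstream", "downstream", "intergenic")

# classes of one variant against one transcript (most severe only)
classify_against_transcript <- function(chrom, pos, ref, alt, annotation,
                                        genome, tx_row,
                                        splice_region_window, flank_window) {
  txid <- tx_row$transcript_id
  strand <- tx_row$strand
  ex <- annotation$cds[annotation$cds$transcript_id == txid, ]
  in_cds <- nrow(ex) > 0 && any(pos >= ex$start & pos <= ex$end)
  if (in_cds) {
    map <- cds_position_map(annotation, txid)
    row <- map[map$pos == pos, ]
    codon_pos <- map$pos[map$codon == row$codon]  # already in translation order
    ref_codon <- paste0(vapply(codon_pos, function(p) {
      extract_sequence(genome, chrom, p, p, strand)
    }, character(1)), collapse = "")
    alt_codon <- ref_codon
    substr(alt_codon, row$offset, row$offset) <- if (strand == "-") revcomp(alt) else alt
    aa_ref <- translate_codons(ref_codon)
    aa_alt <- translate_codons(alt_codon)
    if (is.na(aa_ref) || is.na(aa_alt)) return("intron")  # ambiguous base: defensive
    if (xor(aa_ref == "*", aa_alt == "*")) return("stop_affecting")
    if (aa_ref == aa_alt) return("synonymous")
    return("nonsynonymous")
  }
  exs <- annotation$exons[annotation$exons$transcript_id == txid, ]
  exonic <- any(pos >= exs$start & pos <= exs$end)
  within_tx <- pos >= tx_row$start && pos <= tx_row$end
  if (exonic && nrow(ex) > 0) {
    # UTR: exonic, non-CDS; side determined in transcription direction
    cds_lo <- min(ex$start); cds_hi <- max(ex$end)
    before <- pos < cds_lo
    utr5 <- (strand == "+" && before) || (strand == "-" && !before)
    return(if (utr5) "utr5" else "utr3")
  }
  if (within_tx && !exonic) {
    # intronic; splice region = within splice_region_window nt of a boundary
    d_donor <- pos - exs$end      # distance into intron after an exon
    d_accep <- exs$start - pos    # distance into intron before an exon
    near <- any(d_donor >= 1 & d_donor <= splice_region_window) ||
      any(d_accep >= 1 & d_accep <= splice_region_window)
    return(if (near) "splice_region" else "intron")
  }
  if (exonic) return("intron")  # exonic in a transcript without CDS records
  NA_character_
}

#' Annotate SNV consequences against gene models
#'
#' Coding positions are classified by strand-aware codon re-translation
#' (synonymous / nonsynonymous / stop_affecting); intronic positions within
#' `splice_region_window` nt of an exon-intron boundary are `splice_region`;
#' exonic non-CDS positions are `utr5`/`utr3`; positions within
#' `flank_window` nt of a gene span are `upstream`/`downstream` relative to
#' the gene's strand; everything else is `intergenic`. When a variant hits
#' several transcripts or genes, the most severe class wins
#' (stop_affecting > nonsynonymous > synonymous > splice_region > UTR >
#' intron > upstream/downstream > intergenic).
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param annotation A [tx_annotation()] object.
#' @param genome Named character vector of chromosome sequences.
#' @param splice_region_window Intronic nt from a boundary counting as
#'   splice region (default 8).
#' @param flank_window Up/downstream flank size in nt (default 5000).
#' @return `variants` with columns `consequence` and `gene_id` (the gene
#'   carrying the most severe class; `NA` for intergenic).
#' @export
annotate_variants <- function(variants, annotation, genome,
                              splice_region_window = 8L, flank_window = 5000L) {
  g <- annotation$genes
  tx <- annotation$transcripts
  res <- purrr::map(seq_len(nrow(variants)), function(i) {
    chrom <- variants$chrom[i]; pos <- variants$pos[i]
    ref <- variants$ref[i]; alt <- variants$alt[i]
    hits <- g[g$chrom == chrom & g$start <= pos & g$end >= pos, ]
    best <- "intergenic"; best_gene <- NA_character_
    better <- function(a, b) match(a, severity_order) < match(b, severity_order)
    if (nrow(hits) > 0) {
      for (j in seq_len(nrow(hits))) {
        gid <- hits$gene_id[j]
        txs <- tx[tx$gene_id == gid, ]
        gene_cls <- "intron"  # inside a gene span but outside all transcripts
        for (k in seq_len(nrow(txs))) {
          cls <- classify_against_transcript(chrom, pos, ref, alt, annotation,
                                             genome, txs[k, ],
                                             splice_region_window, flank_window)
          if (!is.na(cls) && better(cls, gene_cls)) gene_cls <- cls
        }
        if (better(gene_cls, best)) { best <- gene_cls; best_gene <- gid }
      }
    }
    if (best == "intergenic") {
      # flanking classes relative to the nearest qualifying gene strand
      near <- g[g$chrom == chrom & g$start <= pos + flank_window &
                  g$end >= pos - flank_window, ]
      if (nrow(near) > 0) {
        for (j in seq_len(nrow(near))) {
          gn <- near[j, ]
          if (pos < gn$start) {
            cls <- if (gn$strand == "+") "upstream" else "downstream"
          } else if (pos > gn$end) {
            cls <- if (gn$strand == "+") "downstream" else "upstream"
          } else next
          if (better(cls, best)) { best <- cls; best_gene <- gn$gene_id }
        }
      }
    }
    list(consequence = best, gene_id = best_gene)
  })
  variants |>
    dplyr::mutate(consequence = purrr::map_chr(res, "consequence"),
                  gene_id = purrr::map_chr(res, "gene_id"))
}

#' Substitution spectrum and transition:transversion ratio
#'
#' Counts the six unordered substitution types. Transitions are A/G and
#' C/T; the remaining four types are transversions. Percentages are
#' reported to two decimals, the Ts/Tv ratio to two decimals.
#'
#' @param variants Tibble with `ref` and `alt` single-base columns.
#' @return List with `spectrum` (tibble: type, n, pct), `n_transition`,
#'   `n_transversion`, `tstv_ratio` (NA with `tstv_infinite = TRUE` when no
#'   transversions are present).
#' @export
summarize_substitutions <- function(variants) {
  key <- paste(pmin(variants$ref, variants$alt),
               pmax(variants$ref, variants$alt), sep = "/")
  types <- c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")
  n <- vapply(types, function(t) sum(key == t), integer(1))
  total <- sum(n)
  ts <- n[["A/G"]] + n[["C/T"]]
  tv <- total - ts
  list(
    spectrum = tibble(type = types, n = unname(n),
                      pct = vapply(unname(n), pct2, numeric(1), den = total)),
    n_transition = ts,
    n_transversion = tv,
    pct_transition = pct2(ts, total),
    pct_transversion = pct2(tv, total),
    tstv_ratio = if (tv == 0) NA_real_ else round(ts / tv, 2),
    tstv_infinite = tv == 0 && ts > 0)
}

#' Plot the substitution spectrum
#'
#' @param variants Tibble with `ref` and `alt` columns.
#' @return A ggplot bar chart of the six substitution types, transitions
#'   highlighted.
#' @export
plot_substitution_spectrum <- function(variants) {
  sp <- summarize_substitutions(variants)$spectrum
  sp$kind <- ifelse(sp$type %in% c("A/G", "C/T"), "transition", "transversion")
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$type, y = .data$n, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "substitution type", y = "SNPs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-gene SNP counts and histogram bins
#'
#' A SNP increments every gene whose span contains it, so SNPs in
#' overlapping genes are counted for each. Histogram bins: fewer than 10,
#' 10-25, more than 25 SNPs.
#'
#' @param variants Tibble with `chrom` and `pos`.
#' @param annotation A [tx_annotation()] object.
#' @return List with `per_gene` (tibble gene_id, n_snps for genes with at
#'   least one SNP), `n_genes_with_snps`, `bins` (tibble bin, n, pct to one
#'   decimal) and `mean_snps_per_gene` (over genes with >= 1 SNP).
#' @export
per_gene_snp_counts <- function(variants, annotation) {
  g <- annotation$genes
  if (nrow(variants) == 0 || nrow(g) == 0) {
    return(list(per_gene = tibble(gene_id = character(0), n_snps = integer(0)),
                n_genes_with_snps = 0L,
                bins = tibble(bin = c("<10", "10-25", ">25"), n = c(0L, 0L, 0L),
                              pct = c(NA_real_, NA_real_, NA_real_)),
                mean_snps_per_gene = NA_real_))
  }
  counts <- purrr::map_int(seq_len(nrow(g)), function(j) {
    sum(variants$chrom == g$chrom[j] &
          variants$pos >= g$start[j] & variants$pos <= g$end[j])
  })
  per_gene <- tibble(gene_id = g$gene_id, n_snps = counts) |>
    dplyr::filter(.data$n_snps > 0) |>
    dplyr::arrange(dplyr::desc(.data$n_snps), .data$gene_id)
  nG <- nrow(per_gene)
  bins <- tibble(
    bin = c("<10", "10-25", ">25"),
    n = c(sum(per_gene$n_snps < 10), sum(per_gene$n_snps >= 10 & per_gene$n_snps <= 25),
          sum(per_gene$n_snps > 25)))
  bins$pct <- vapply(bins$n, pct1, numeric(1), den = nG)
  list(per_gene = per_gene, n_genes_with_snps = nG, bins = bins,
       mean_snps_per_gene = if (nG == 0) NA_real_ else
         round(sum(per_gene$n_snps) / nG, 1))
}

#' Partition SNVs into catalogue-known and novel
#'
#' A variant is known when the catalogue holds an entry at the same
#' chromosome and position whose allele pair matches (unordered) — unless
#' `match_alleles = FALSE`, in which case position alone suffices.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param catalogue Tibble from [read_snp_catalogue()].
#' @param match_alleles Require allele agreement (default TRUE).
#' @return List with `variants` (input plus `known` flag and matched
#'   `known_id`), `n_known`, `n_novel`, `pct_known` (one decimal).
#' @export
compare_dbsnp <- function(variants, catalogue, match_alleles = TRUE) {
  n <- nrow(catalogue)
  catalogue <- dplyr::distinct(catalogue, .data$chrom, .data$pos, .data$ref,
                               .data$alt, .keep_all = TRUE)
  if (nrow(catalogue) < n) {
    warn(sprintf("compare_dbsnp: removed %d duplicate catalogue row(s)",
                 n - nrow(catalogue)))
  }
  akey <- function(r, a) paste(pmin(r, a), pmax(r, a), sep = "/")
  if (match_alleles) {
    vk <- paste(variants$chrom, variants$pos, akey(variants$ref, variants$alt))
    ck <- paste(catalogue$chrom, catalogue$pos, akey(catalogue$ref, catalogue$alt))
  } else {
    vk <- paste(variants$chrom, variants$pos)
    ck <- paste(catalogue$chrom, catalogue$pos)
  }
  idx <- match(vk, ck)
  out <- variants |>
    dplyr::mutate(known = !is.na(idx), known_id = catalogue$id[idx])
  list(variants = out, n_known = sum(out$known), n_novel = sum(!out$known),
       pct_known = pct1(sum(out$known), nrow(out)))
}

#' Overlap SNVs with QTL regions
#'
#' @param variants Tibble with `chrom` and `pos`.
#' @param regions Tibble from [read_qtl_bed()] (1-based inclusive; a SNP at
#'   a region boundary counts as inside).
#' @return List with `per_trait` (tibble trait, n_snps: SNPs in >= 1 region
#'   of the trait), `n_in_qtl` (SNPs in >= 1 region of any trait),
#'   `pct_in_qtl` (two decimals), `n_regions_hit` (regions containing >= 1
#'   SNP) and `n_traits`.
#' @export
qtl_overlap <- function(variants, regions) {
  if (any(regions$end < regions$start)) abort("invalid QTL region (end < start)")
  ir_v <- split(variants$pos, variants$chrom)
  hit_any <- rep(FALSE, nrow(variants))
  region_hit <- rep(FALSE, nrow(regions))
  per_trait_hits <- matrix(FALSE, nrow = nrow(variants), ncol = 0)
  trait_sets <- lapply(unique(regions$trait), function(tr) rep(FALSE, nrow(variants)))
  names(trait_sets) <- unique(regions$trait)
  for (j in seq_len(nrow(regions))) {
    in_r <- variants$chrom == regions$chrom[j] &
      variants$pos >= regions$start[j] & variants$pos <= regions$end[j]
    region_hit[j] <- any(in_r)
    hit_any <- hit_any | in_r
    trait_sets[[regions$trait[j]]] <- trait_sets[[regions$trait[j]]] | in_r
  }
  per_trait <- tibble(
    trait = names(trait_sets),
    n_snps = unname(vapply(trait_sets, sum, integer(1)))) |>
    dplyr::arrange(dplyr::desc(.data$n_snps), .data$trait)
  list(per_trait = per_trait,
       n_in_qtl = sum(hit_any),
       pct_in_qtl = pct2(sum(hit_any), nrow(variants)),
       n_regions_hit = sum(region_hit),
       n_traits = length(trait_sets))
}
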