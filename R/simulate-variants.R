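# variant construction for the synthetic generator: every variant's
# consequence class is realised against the (possibly fusion-edited)
# genome, so the annotator must recover the truth label exactly.

# registry of chosen positions enforcing a 36-base minimum gap (so no
# accidental 3-in-35 clusters) except inside designed clusters
new_pos_registry <- function() new.env(parent = emptyenv())

pos_free <- function(reg, chrom, pos, min_gap = 36L) {
  taken <- reg[[chrom]] %||% integer(0)
  length(taken) == 0 || min(abs(taken - pos)) >= min_gap
}

pos_claim <- function(reg, chrom, pos) {
  reg[[chrom]] <- c(reg[[chrom]] %||% integer(0), pos)
}

pick_alt <- function(ref, transition_prob) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  if (runif(1) < transition_prob) ts[[ref]] else sample(tv[[ref]], 1)
}

# enumerate substitutions of one codon and their effect class
codon_substitutions <- function(ref_codon) {
  aa_ref <- translate_codons(ref_codon)
  out <- list()
  for (off in 1:3) {
    ref_base <- substr(ref_codon, off, off)
    for (alt in setdiff(c("A", "C", "G", "T"), ref_base)) {
      alt_codon <- ref_codon
      substr(alt_codon, off, off) <- alt
      aa_alt <- translate_codons(alt_codon)
      cls <- if (xor(aa_ref == "*", aa_alt == "*")) "stop_affecting"
      else if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
      out[[length(out) + 1L]] <- list(offset = off, alt = alt, class = cls)
    }
  }
  out
}

# flank positions must be > flank_window away from every *other* gene span
# and outside all gene spans, so the truth label is unambiguous
flank_clear <- function(genes, chrom, pos, own_gene, flank_window = 5000L) {
  others <- genes[genes$chrom == chrom & genes$gene_id != own_gene, ]
  inside_any <- any(genes$chrom == chrom & genes$start <= pos & genes$end >= pos)
  if (inside_any) return(FALSE)
  if (nrow(others) == 0) return(TRUE)
  all(pos < others$start - flank_window | pos > others$end + flank_window)
}

intergenic_clear <- function(genes, chrom, pos, flank_window = 5000L) {
  g <- genes[genes$chrom == chrom, ]
  if (nrow(g) == 0) return(TRUE)
  all(pos < g$start - flank_window | pos > g$end + flank_window)
}

#' Generate variants with known consequence classes and filter fates
#'
#' Builds the configured number of variants per consequence class by
#' construction against the supplied genome (codon substitutions are chosen
#' so the intended effect is guaranteed), plus variants engineered to fail
#' each hard filter, clusters of 3 SNPs within 35 bases, and variants on
#' excluded chromosomes. All other variants carry passing FS/QD/DP values.
#' Positions are kept at least 36 bases apart outside designed clusters.
#'
#' @param config A [sim_config()].
#' @param annotation The generated [tx_annotation()].
#' @param genome The genome *after* [simulate_fusions()] edits.
#' @return List with `variants` (tibble in [read_vcf_snvs()] layout) and
#'   `truth` (variant_id, class, gene_id, fate, cluster_id).
#' @export
simulate_variants <- function(config, annotation, genome) {
  withr::with_seed(config$seed + 303L, {
    reg <- new_pos_registry()
    genes <- annotation$genes
    txs <- annotation$transcripts
    out <- list()
    vid <- 0L
    emit <- function(chrom, pos, ref, alt, class, gene_id, fate,
                     cluster_id = NA_character_) {
      vid <<- vid + 1L
      fs <- if (fate == "hard_FS") round(runif(1, 31, 60), 2) else round(runif(1, 0, 20), 2)
      qd <- if (fate == "hard_QD") round(runif(1, 0, 1.9), 2) else round(runif(1, 5, 30), 2)
      dp_depth <- if (fate == "hard_DP") sample(2:4, 1) else sample(10:60, 1)
      ad_alt <- max(1L, min(dp_depth - 1L, rbinom(1, dp_depth, 0.5)))
      out[[length(out) + 1L]] <<- tibble(
        variant_id = sprintf("var_%04d", vid),
        chrom = chrom, pos = as.integer(pos),
        id = NA_character_, ref = ref, alt = alt,
        fs = fs, qd = qd, dp = as.integer(dp_depth),
        genotype = "het", ad_ref = as.integer(dp_depth - ad_alt),
        ad_alt = as.integer(ad_alt),
        class = class, gene_id = gene_id, fate = fate,
        cluster_id = cluster_id)
      pos_claim(reg, chrom, as.integer(pos))
    }

    plant_class <- function(class, n_needed, fate = "pass") {
      made <- 0L; guard <- 0L
      gene_order <- sample(genes$gene_id)
      gidx <- 1L
      while (made < n_needed && guard < 50000L) {
        guard <- guard + 1L
        gid <- gene_order[gidx]; gidx <- gidx %% length(gene_order) + 1L
        g <- genes[genes$gene_id == gid, ]
        txid <- txs$transcript_id[txs$gene_id == gid][1]
        ok <- FALSE
        if (class %in% c("nonsynonymous", "synonymous", "stop_affecting")) {
          map <- cds_position_map(annotation, txid)
          n_codon <- max(map$codon) - 1L  # keep away from a trailing partial codon
          cd <- sample(seq_len(n_codon), 1)
          rows <- map[map$codon == cd, ]
          ref_codon <- paste0(vapply(rows$pos, function(p)
            extract_sequence(genome, g$chrom, p, p, g$strand), character(1)),
            collapse = "")
          if (grepl("[^ACGT]", ref_codon)) next
          subs <- codon_substitutions(ref_codon)
          subs <- purrr::keep(subs, ~ .x$class == class)
          if (length(subs) == 0) next
          # prefer transitions when available
          is_ts <- vapply(subs, function(s) {
            rb <- substr(ref_codon, s$offset, s$offset)
            s$alt == c(A = "G", G = "A", C = "T", T = "C")[[rb]]
          }, logical(1))
          pick <- if (any(is_ts) && runif(1) < config$transition_prob) {
            subs[is_ts][[sample(sum(is_ts), 1)]]
          } else subs[[sample(length(subs), 1)]]
          pos <- rows$pos[rows$offset == pick$offset]
          ref <- extract_sequence(genome, g$chrom, pos, pos, "+")
          alt <- if (g$strand == "-") revcomp(pick$alt) else pick$alt
          if (ref == alt) next
          in_other_exon <- any(annotation$exons$gene_id != gid &
                                 annotation$exons$chrom == g$chrom &
                                 annotation$exons$start <= pos &
                                 annotation$exons$end >= pos)
          if (!in_other_exon && pos_free(reg, g$chrom, pos)) {
            emit(g$chrom, pos, ref, alt, class, gid, fate)
            ok <- TRUE
          }
        } else if (class %in% c("utr5", "utr3")) {
          ex <- tx_exons_in_order(annotation, gid)
          cdsg <- annotation$cds[annotation$cds$transcript_id == txid, ]
          # UTR bases sit in the transcription-first (utr5) or -last (utr3)
          # exon outside the CDS range
          if (class == "utr5") {
            e <- ex[1, ]
            cand <- if (g$strand == "+") e$start:(min(cdsg$start) - 1L)
            else (max(cdsg$end) + 1L):e$end
          } else {
            e <- ex[nrow(ex), ]
            cand <- if (g$strand == "+") (max(cdsg$end) + 1L):e$end
            else e$start:(min(cdsg$start) - 1L)
          }
          pos <- sample(cand, 1)
          in_other_exon <- any(annotation$exons$gene_id != gid &
                                 annotation$exons$chrom == g$chrom &
                                 annotation$exons$start <= pos &
                                 annotation$exons$end >= pos)
          if (!in_other_exon && pos_free(reg, g$chrom, pos)) {
            ref <- extract_sequence(genome, g$chrom, pos, pos, "+")
            emit(g$chrom, pos, ref, pick_alt(ref, config$transition_prob),
                 class, gid, fate)
            ok <- TRUE
          }
        } else if (class %in% c("intron", "splice_region")) {
          ex <- annotation$exons[annotation$exons$gene_id == gid, ]
          ex <- ex[order(ex$start), ]
          if (nrow(ex) < 2) next
          k <- sample(nrow(ex) - 1L, 1)
          in_lo <- ex$end[k] + 1L; in_hi <- ex$start[k + 1L] - 1L
          if (class == "splice_region") {
            d <- sample(3:8, 1)  # avoid the planted dinucleotides at +-1,2
            pos <- if (runif(1) < 0.5) ex$end[k] + d else ex$start[k + 1L] - d
          } else {
            lo <- in_lo + 9L; hi <- in_hi - 9L
            if (lo > hi) next
            pos <- sample(lo:hi, 1)
          }
          # overlap-pair genes can tuck another gene's exon inside an
          # intron; require the position to be intronic for every
          # transcript it touches
          ch_ex <- annotation$exons[annotation$exons$chrom == g$chrom, ]
          exonic_any <- any(ch_ex$start <= pos & ch_ex$end >= pos)
          near_boundary <- any(abs(ch_ex$start - pos) <= 8 | abs(ch_ex$end - pos) <= 8)
          bad <- exonic_any || (class == "intron" && near_boundary)
          if (!bad && pos_free(reg, g$chrom, pos)) {
            ref <- extract_sequence(genome, g$chrom, pos, pos, "+")
            emit(g$chrom, pos, ref, pick_alt(ref, config$transition_prob),
                 class, gid, fate)
            ok <- TRUE
          }
        } else if (class %in% c("upstream", "downstream")) {
          d <- sample(50:4000, 1)
          before_span <- (class == "upstream") == (g$strand == "+")
          pos <- if (before_span) g$start - d else g$end + d
          if (pos >= 1 && pos <= nchar(genome[[g$chrom]]) &&
              flank_clear(genes, g$chrom, pos, gid) &&
              pos_free(reg, g$chrom, pos)) {
            ref <- extract_sequence(genome, g$chrom, pos, pos, "+")
            emit(g$chrom, pos, ref, pick_alt(ref, config$transition_prob),
                 class, gid, fate)
            ok <- TRUE
          }
        } else if (class == "intergenic") {
          ch <- sample(as.character(seq_len(config$n_chromosomes)), 1)
          pos <- sample(2000:(config$chrom_length - 2000L), 1)
          if (intergenic_clear(genes, ch, pos) && pos_free(reg, ch, pos)) {
            ref <- extract_sequence(genome, ch, pos, pos, "+")
            emit(ch, pos, ref, pick_alt(ref, config$transition_prob),
                 class, NA_character_, fate)
            ok <- TRUE
          }
        }
        if (ok) made <- made + 1L
      }
      if (made < n_needed) {
        abort(sprintf("infeasible variant plan: placed %d of %d '%s' variants",
                      made, n_needed, class))
      }
    }

    for (cls in names(config$variant_class_counts)) {
      plant_class(cls, config$variant_class_counts[[cls]])
    }
    # hard-filter failures (intronic placement, one rule failed each)
    if (config$n_fail_fs > 0)
      plant_class("intron", config$n_fail_fs, fate = "hard_FS")
    if (config$n_fail_qd > 0)
      plant_class("intron", config$n_fail_qd, fate = "hard_QD")
    if (config$n_fail_dp > 0)
      plant_class("intron", config$n_fail_dp, fate = "hard_DP")
    # clusters: 3 SNPs spanning 25 bases at intergenic positions
    for (cl in seq_len(config$n_clusters)) {
      placed <- FALSE; guard <- 0L
      while (!placed && guard < 5000L) {
        guard <- guard + 1L
        ch <- sample(as.character(seq_len(config$n_chromosomes)), 1)
        p0 <- sample(2000:(config$chrom_length - 2000L), 1)
        ps <- c(p0, p0 + 12L, p0 + 24L)
        if (all(vapply(ps, function(p) intergenic_clear(genes, ch, p), logical(1))) &&
            all(vapply(ps, function(p) pos_free(reg, ch, p), logical(1)))) {
          for (p in ps) {
            ref <- extract_sequence(genome, ch, p, p, "+")
            emit(ch, p, ref, pick_alt(ref, config$transition_prob),
                 "intergenic", NA_character_, "cluster",
                 cluster_id = sprintf("cluster_%02d", cl))
          }
          placed <- TRUE
        }
      }
      if (!placed) abort("infeasible variant plan: could not place cluster")
    }
    # excluded chromosomes
    for (plan in list(list(ch = "scaffold_1", n = config$n_scaffold_variants),
                      list(ch = "MT", n = config$n_mt_variants))) {
      n_done <- 0L; guard <- 0L
      while (n_done < plan$n && guard < 5000L) {
        guard <- guard + 1L
        p <- sample(100:(nchar(genome[[plan$ch]]) - 100L), 1)
        if (pos_free(reg, plan$ch, p)) {
          ref <- extract_sequence(genome, plan$ch, p, p, "+")
          emit(plan$ch, p, ref, pick_alt(ref, config$transition_prob),
               "intergenic", NA_character_, "excluded_chrom")
          n_done <- n_done + 1L
        }
      }
    }
    all <- dplyr::bind_rows(out) |>
      dplyr::arrange(.data$chrom, .data$pos)
    list(
      variants = all[, c("chrom", "pos", "id", "ref", "alt", "fs", "qd", "dp",
                         "genotype", "ad_ref", "ad_alt")],
      truth = all[, c("variant_id", "chrom", "pos", "ref", "alt", "class",
                      "gene_id", "fate", "cluster_id")])
  })
}
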