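#' Compute RPKM from per-gene read counts
#'
#' RPKM = 1e9 * C / (N * L), where C is the gene's read count, N the
#' library-level number of mapped reads and L the length of the union of the
#' gene's exons across all its transcripts.
#'
#' @param counts Tibble with columns `gene_id` and `count`.
#' @param annotation A [tx_annotation()] object covering every counted gene.
#' @param total_reads N, the number of mapped reads in the library (> 0).
#' @return Tibble with `gene_id`, `symbol`, `count`, `exonic_length`, `rpkm`.
#' @export
compute_rpkm <- function(counts, annotation, total_reads) {
  if (total_reads <= 0) abort("total_reads must be > 0")
  lens <- gene_exonic_lengths(annotation)
  missing <- setdiff(counts$gene_id, annotation$genes$gene_id)
  if (length(missing) > 0) {
    abort(paste0("counted gene absent from annotation: ", missing[1]))
  }
  out <- counts |>
    dplyr::left_join(lens, by = "gene_id") |>
    dplyr::left_join(annotation$genes[, c("gene_id", "symbol")], by = "gene_id")
  if (any(is.na(out$exonic_length) | out$exonic_length == 0)) {
    bad <- out$gene_id[which(is.na(out$exonic_length) | out$exonic_length == 0)[1]]
    abort(paste0("gene with zero exonic length: ", bad))
  }
  out |>
    dplyr::transmute(
      gene_id = .data$gene_id, symbol = .data$symbol, count = .data$count,
      exonic_length = .data$exonic_length,
      rpkm = 1e9 * .data$count / (total_reads * .data$exonic_length))
}

#' Summarise expression detection and abundance bins
#'
#' A gene is detected when RPKM exceeds the detection threshold (strict
#' `>`). Detected genes are binned: weak (`RPKM < 5`), mid (`5 <= RPKM <
#' 100`), abundant (`RPKM >= 100`); highly expressed genes (`RPKM > 1000`)
#' are a subset of the abundant bin. Percentages are over detected genes,
#' rounded to one decimal.
#'
#' @param expression Tibble with an `rpkm` column (see [compute_rpkm()]).
#' @param thresholds Strictly increasing numeric vector
#'   `(detect, weak, abundant, high)`; defaults `c(0.1, 5, 100, 1000)`.
#' @return One-row tibble with counts `n_genes`, `n_detected`, `n_weak`,
#'   `n_mid`, `n_abundant`, `n_high` and percentages `pct_weak`,
#'   `pct_abundant` (1 decimal, over detected genes).
#' @export
summarize_expression <- function(expression, thresholds = c(0.1, 5, 100, 1000)) {
  if (length(thresholds) != 4 || any(diff(thresholds) <= 0)) {
    abort("thresholds must be four strictly increasing values")
  }
  if (nrow(expression) == 0) {
    warn("summarize_expression: empty expression table")
  }
  r <- expression$rpkm
  detected <- r > thresholds[1]
  n_det <- sum(detected)
  n_weak <- sum(detected & r < thresholds[2])
  n_abundant <- sum(r >= thresholds[3])
  n_high <- sum(r > thresholds[4])
  tibble(
    n_genes = length(r),
    n_detected = n_det,
    n_weak = n_weak,
    n_mid = n_det - n_weak - n_abundant,
    n_abundant = n_abundant,
    n_high = n_high,
    pct_weak = pct1(n_weak, n_det),
    pct_abundant = pct1(n_abundant, n_det))
}

#' Most highly expressed genes
#'
#' @param expression Tibble from [compute_rpkm()].
#' @param n Number of genes to return.
#' @return Tibble of the top `n` genes sorted by RPKM descending, ties
#'   broken by `gene_id`.
#' @export
top_expressed <- function(expression, n = 25) {
  expression |>
    dplyr::arrange(dplyr::desc(.data$rpkm), .data$gene_id) |>
    head(n)
}

#' Plot the abundance-bin distribution of detected genes
#'
#' @param expression Tibble from [compute_rpkm()].
#' @param thresholds As in [summarize_expression()].
#' @return A ggplot object (bar chart of detected genes per abundance bin).
#' @export
plot_expression_bins <- function(expression, thresholds = c(0.1, 5, 100, 1000)) {
  det <- dplyr::filter(expression, .data$rpkm > thresholds[1])
  det$bin <- cut(det$rpkm, breaks = c(thresholds[1], thresholds[2:3], Inf),
                 labels = c("weak (<5)", "mid [5,100)", "abundant (≥100)"),
                 right = FALSE)
  ggplot2::ggplot(det, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "RPKM bin", y = "detected genes") +
    ggplot2::theme_minimal()
}

# percentage helpers: printed precision follows the reporting conventions
# used throughout (1 decimal for headline fractions, 2 for QTL/TsTv)
pct1 <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 1)
pct2 <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 2)
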