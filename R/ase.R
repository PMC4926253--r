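#' Depth-filter heterozygous sites for ASE testing
#'
#' A site is eligible when each allele has read depth of at least
#' `min_allele_depth` and the total depth is at least `min_total_depth`
#' (boundaries inclusive).
#'
#' @param sites Tibble with `n_ref` and `n_alt` columns (see
#'   [read_allele_counts()]).
#' @param min_allele_depth Minimum per-allele depth (default 3).
#' @param min_total_depth Minimum total depth (default 10).
#' @return List with `eligible` (tibble), `n_removed` and `n_input`.
#' @export
filter_ase_sites <- function(sites, min_allele_depth = 3L, min_total_depth = 10L) {
  if (any(sites$n_ref < 0 | sites$n_alt < 0)) {
    abort("negative allele counts")
  }
  keep <- sites$n_ref >= min_allele_depth & sites$n_alt >= min_allele_depth &
    (sites$n_ref + sites$n_alt) >= min_total_depth
  list(eligible = sites[keep, ], n_removed = sum(!keep), n_input = nrow(sites))
}

#' Two-sided exact binomial p-value by tail doubling
#'
#' P-value of observing `k` successes in `n` trials under success
#' probability `p0`, computed as twice the smaller of the two tail
#' probabilities `P(X <= k)` and `P(X >= k)`, capped at 1.
#'
#' @param k Successes (vectorised).
#' @param n Trials.
#' @param p0 Null success probability (default 0.5).
#' @return Numeric vector of p-values.
#' @export
binom_p_twosided <- function(k, n, p0 = 0.5) {
  lower <- pbinom(k, n, p0)
  upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Allelic ratio and binomial test per heterozygous site
#'
#' The allelic ratio is the non-reference allele count over the total
#' count; the p-value tests the alternate count against a balanced
#' binomial (`p0 = 0.5`) two-sidedly (see [binom_p_twosided()]).
#'
#' @param sites Eligible-site tibble with `n_ref` and `n_alt`.
#' @param p0 Null alternate-allele probability (default 0.5).
#' @return `sites` with columns `ratio` and `p_value`.
#' @export
test_ase <- function(sites, p0 = 0.5) {
  total <- sites$n_ref + sites$n_alt
  if (any(total == 0)) abort("site with zero total depth (should be filtered)")
  sites |>
    dplyr::mutate(ratio = .data$n_alt / total,
                  p_value = binom_p_twosided(.data$n_alt, total, p0))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard BH step-up over the supplied p-values (the multiplicity `m` is
#' their number, i.e. the eligible-site count when called on the full
#' eligible set), returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call allele-specific expression
#'
#' A site shows significant allelic imbalance when its allelic ratio is
#' above `ratio_hi` or below `ratio_lo` (strict inequalities) and its BH
#' q-value is below `fdr`. q-values are computed here across all supplied
#' sites, so pass the complete eligible set.
#'
#' @param tested Tibble from [test_ase()] (columns `ratio`, `p_value`).
#' @param ratio_hi,ratio_lo Allelic-ratio cutoffs (defaults 0.65 / 0.35).
#' @param fdr FDR threshold (default 0.05).
#' @return Object of class `ase_calls`: the input tibble with `q_value` and
#'   `is_ase` columns plus call metadata; use [tidy()]/[glance()] to
#'   extract results.
#' @export
call_ase <- function(tested, ratio_hi = 0.65, ratio_lo = 0.35, fdr = 0.05) {
  if (ratio_lo >= ratio_hi || ratio_lo <= 0 || ratio_hi >= 1) {
    abort("require 0 < ratio_lo < ratio_hi < 1")
  }
  if (fdr <= 0 || fdr >= 1) abort("fdr must lie in (0, 1)")
  out <- tested |>
    dplyr::mutate(q_value = adjust_fdr(.data$p_value),
                  is_ase = (.data$ratio > ratio_hi | .data$ratio < ratio_lo) &
                    .data$q_value < fdr)
  structure(list(results = out,
                 params = list(ratio_hi = ratio_hi, ratio_lo = ratio_lo,
                               fdr = fdr),
                 n_eligible = nrow(out),
                 n_ase = sum(out$is_ase)),
            class = "ase_calls")
}

#' @export
print.ase_calls <- function(x, ...) {
  cat(sprintf("<ase_calls> %d of %d eligible sites show allelic imbalance (ratio >%.2f or <%.2f, FDR <%.2f)\n",
              x$n_ase, x$n_eligible, x$params$ratio_hi, x$params$ratio_lo,
              x$params$fdr))
  invisible(x)
}

#' @rdname call_ase
#' @param x An `ase_calls` object.
#' @param ... Unused.
#' @export
tidy.ase_calls <- function(x, ...) x$results

#' @rdname call_ase
#' @export
glance.ase_calls <- function(x, ...) {
  tibble(n_eligible = x$n_eligible, n_ase = x$n_ase,
         pct_ase = pct1(x$n_ase, x$n_eligible),
         median_ratio = stats::median(x$results$ratio),
         ratio_hi = x$params$ratio_hi, ratio_lo = x$params$ratio_lo,
         fdr = x$params$fdr)
}

#' @rdname call_ase
#' @param object An `ase_calls` object.
#' @export
autoplot.ase_calls <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio,
                                  y = -log10(pmax(.data$q_value, 1e-300)),
                                  colour = .data$is_ase)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(object$params$ratio_lo,
                                       object$params$ratio_hi),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b")) +
    ggplot2::labs(x = "alternate-allele ratio", y = expression(-log[10]~q),
                  colour = "ASE") +
    ggplot2::theme_minimal()
}

#' Global reference/alternate depth diagnostics
#'
#' Reports the overall alternate-allele fraction over all eligible sites so
#' systematic reference-mapping bias is visible; no correction is applied.
#'
#' @param sites Tibble with `n_ref` and `n_alt`.
#' @return One-row tibble with total depths and the global alt fraction.
#' @export
ase_bias_diagnostics <- function(sites) {
  tibble(total_ref = sum(sites$n_ref), total_alt = sum(sites$n_alt),
         global_alt_fraction = sum(sites$n_alt) /
           (sum(sites$n_ref) + sum(sites$n_alt)))
}

#' Fisher test for nonsynonymous enrichment among ASE sites
#'
#' Builds the 2x2 table (rows ASE / non-ASE, columns nonsynonymous /
#' other) and computes the two-sided Fisher exact p-value (sum of
#' hypergeometric probabilities no larger than the observed table's).
#' An empty margin yields p = 1 with `degenerate = TRUE`.
#'
#' @param is_ase Logical vector of ASE flags.
#' @param is_nonsyn Logical vector (same length) marking nonsynonymous
#'   sites.
#' @return List with `table` (2x2 matrix), `p_value`, `odds_ratio` and
#'   `degenerate`.
#' @export
enrichment_nonsyn <- function(is_ase, is_nonsyn) {
  if (length(is_ase) != length(is_nonsyn)) {
    abort("is_ase and is_nonsyn must have equal length")
  }
  tab <- matrix(c(sum(is_ase & is_nonsyn), sum(is_ase & !is_nonsyn),
                  sum(!is_ase & is_nonsyn), sum(!is_ase & !is_nonsyn)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("ASE", "non-ASE"),
                                c("nonsynonymous", "other")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(list(table = tab, p_value = 1, odds_ratio = NA_real_,
                degenerate = TRUE))
  }
  ft <- fisher.test(tab)
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate), degenerate = FALSE)
}
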