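test_that("eligibility thresholds are inclusive on the stated boundaries", {
  sites <- tibble::tibble(chrom = "1", pos = 1:4, ref = "A", alt = "G",
                          n_ref = c(3L, 2L, 4L, 5L),
                          n_alt = c(7L, 100L, 5L, 5L))
  f <- filter_ase_sites(sites)
  expect_equal(f$eligible$pos, c(1L, 4L))  # (3,7) and (5,5) pass
  expect_equal(f$n_removed, 2L)            # (2,100) allele<3; (4,5) total 9
  expect_error(filter_ase_sites(dplyr::mutate(sites, n_ref = -1L)), "negative")
})

test_that("binomial p-values match closed forms and tail enumeration", {
  s55 <- test_ase(tibble::tibble(n_ref = 5L, n_alt = 5L))
  expect_equal(s55$ratio, 0.5)
  expect_equal(s55$p_value, 1.0)

  s016 <- test_ase(tibble::tibble(n_ref = 0L, n_alt = 16L))
  expect_equal(s016$ratio, 1.0)
  expect_equal(s016$p_value, 2 * 0.5^16)

  # oracle: explicit tail sums over the binomial pmf
  oracle_p <- function(k, n) {
    lower <- sum(vapply(0:k, function(j) choose(n, j) * 0.5^n, numeric(1)))
    upper <- sum(vapply(k:n, function(j) choose(n, j) * 0.5^n, numeric(1)))
    min(1, 2 * min(lower, upper))
  }
  s3070 <- test_ase(tibble::tibble(n_ref = 30L, n_alt = 70L))
  expect_equal(s3070$ratio, 0.7)
  expect_equal(s3070$p_value, oracle_p(70, 100), tolerance = 1e-12)
})

test_that("binomial test is symmetric and monotone in imbalance", {
  # symmetry: swapping ref and alt mirrors the ratio, keeps the p-value
  withr::with_seed(5, {
    for (i in 1:30) {
      a <- sample(3:60, 1); b <- sample(3:60, 1)
      r1 <- test_ase(tibble::tibble(n_ref = a, n_alt = b))
      r2 <- test_ase(tibble::tibble(n_ref = b, n_alt = a))
      expect_equal(r1$p_value, r2$p_value)
      expect_equal(r1$ratio, 1 - r2$ratio)
    }
  })
  # monotone: at fixed depth, p never increases as |n_alt - n_ref| grows
  n <- 40L
  p <- binom_p_twosided(20:40, n)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("BH adjustment matches the hand-computed step-up and is
           permutation invariant", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(adjust_fdr(numeric(0)), numeric(0))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(8, {
    p <- runif(200)
    perm <- sample(200)
    expect_equal(adjust_fdr(p)[perm], adjust_fdr(p[perm]))
  })
})

test_that("ASE decision rule applies strict ratio and FDR cutoffs", {
  tested <- tibble::tibble(
    chrom = "1", pos = 1:3, ref = "A", alt = "G",
    n_ref = c(30L, 35L, 80L), n_alt = c(70L, 65L, 20L),
    ratio = c(0.70, 0.65, 0.20), p_value = c(1e-4, 1e-5, 0.9))
  calls <- call_ase(tested)
  res <- tidy(calls)
  expect_true(res$is_ase[1])
  expect_false(res$is_ase[2])   # ratio exactly 0.65 is not called
  expect_false(res$is_ase[3])   # q fails
  expect_error(call_ase(tested, ratio_hi = 0.3, ratio_lo = 0.4), "ratio_lo")
  g <- glance(calls)
  expect_equal(g$n_ase, 1L)
})

test_that("Fisher enrichment p matches full hypergeometric enumeration", {
  oracle_fisher <- function(tab) {
    m <- sum(tab[, 1]); n_other <- sum(tab[, 2]); k <- sum(tab[1, ])
    probs <- vapply(max(0, k - n_other):min(k, m), function(a)
      dhyper(a, m, n_other, k), numeric(1))
    obs <- dhyper(tab[1, 1], m, n_other, k)
    sum(probs[probs <= obs + 1e-12])
  }
  flags <- function(tab) {
    list(is_ase = rep(c(TRUE, FALSE), times = rowSums(tab)),
         is_nonsyn = c(rep(c(TRUE, FALSE), times = tab[1, ]),
                       rep(c(TRUE, FALSE), times = tab[2, ])))
  }
  t1 <- matrix(c(8, 2, 1, 5), nrow = 2, byrow = TRUE)
  f1 <- flags(t1)
  expect_equal(enrichment_nonsyn(f1$is_ase, f1$is_nonsyn)$p_value,
               oracle_fisher(t1), tolerance = 1e-10)
  t2 <- matrix(c(5, 5, 5, 5), nrow = 2, byrow = TRUE)
  f2 <- flags(t2)
  expect_equal(enrichment_nonsyn(f2$is_ase, f2$is_nonsyn)$p_value, 1.0)
  # empty ASE margin is degenerate
  deg <- enrichment_nonsyn(rep(FALSE, 10), rep(c(TRUE, FALSE), 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("bias diagnostics report the global alternate fraction", {
  d <- ase_bias_diagnostics(tibble::tibble(n_ref = c(10L, 30L),
                                           n_alt = c(10L, 10L)))
  expect_equal(d$global_alt_fraction, 20 / 60)
})
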