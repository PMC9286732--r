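# Statistical core against frozen oracle values and small enumerations.

test_that("exact binomial allelic test matches closed forms and enumeration", {
  expect_equal(binomial_allelic_test(10, 0), 2 * 0.5^10)
  expect_equal(binomial_allelic_test(5, 5), 1)
  # frozen value computed by direct likelihood-ordering enumeration of
  # Binomial(100, 0.5)
  expect_equal(binomial_allelic_test(75, 25), 5.6362820342054214e-07)
  expect_true(is.na(binomial_allelic_test(0, 0)))
  # vectorised
  expect_equal(binomial_allelic_test(c(10, 5), c(0, 5)), c(2 * 0.5^10, 1))
})

test_that("BH adjustment matches the naive sorted oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.1, NaN)), "NaN")
  # random instance vs naive step-up oracle
  set.seed(7)
  p <- runif(20)
  o <- order(p)
  q_oracle <- numeric(20)
  m <- 20
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q_oracle[o[i]] <- prev
  }
  expect_equal(bh_fdr(p), q_oracle)
})

test_that("weighted KS statistic and p behave on canonical cases", {
  r <- ks_two_sample(c(100, 110), c(100, 110), c(3, 3), c(3, 3))
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  r <- ks_two_sample(100, 120, 5, 5)
  expect_equal(r$D, 1)
  # D = 0.4 with permutation p from all C(10,5) splits (frozen enumeration)
  r <- ks_two_sample(c(100, 110), c(100, 110), c(3, 2), c(1, 4),
                     method = "exact")
  expect_equal(r$D, 0.4)
  expect_equal(r$p, 132 / 252, tolerance = 1e-12)
  # under-threshold input returns the sentinel
  r <- ks_two_sample(c(100, 110), c(100, 110), c(2, 2), c(3, 3))
  expect_false(r$ok)
  expect_true(is.na(r$p))
})

test_that("Fisher combination matches the chi-square tail", {
  expect_equal(fisher_combine(0.3), 0.3)
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(c(0.5, 0.5)),
               pchisq(2.772589, df = 4, lower.tail = FALSE), tolerance = 1e-6)
  expect_warning(p0 <- fisher_combine(c(0, 0.5)), "clipped")
  expect_true(p0 >= 0 && p0 <= 1)
})

test_that("Fisher exact 2x2 matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(2, 2, 2, 2)$p, 1)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$p, 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 0, 3, 4)$p, 1)   # degenerate row
})

test_that("rank-sum test: exact enumeration and identical-input behaviour", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), method = "exact")$p, 1)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), method = "exact")$p, 1 / 3,
               tolerance = 1e-12)
  # ties do not produce NaN in either mode
  expect_false(is.nan(wilcoxon_rank_sum(c(1, 1, 2), c(1, 2, 2), method = "exact")$p))
  expect_false(is.nan(wilcoxon_rank_sum(rep(1, 6), c(rep(1, 5), 2), method = "normal")$p))
  # agrees with stats::wilcox.test exact mode in the no-tie case
  set.seed(11)
  for (i in 1:20) {
    x <- sample(100, 5); y <- sample(200, 6) + 300
    y <- sample(c(x + 0.5, y))[1:6]
    expect_equal(wilcoxon_rank_sum(x, y, method = "exact")$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("shape classifier separates single- and multi-TSS changes by construction", {
  # single: one dominant allelic difference; residual identical
  members <- data.frame(contig = "c", strand = "+", pos = c(100L, 110L, 120L),
                        a1 = c(40L, 10L, 10L), a2 = c(8L, 10L, 10L),
                        untagged = 0L, all = c(48L, 20L, 20L),
                        region_id = 1L, tsc_id = 1L)
  # multi: differences spread over positions; residual still significant
  m2 <- data.frame(contig = "c", strand = "+",
                   pos = c(200L, 210L, 220L, 230L),
                   a1 = c(40L, 5L, 40L, 5L), a2 = c(5L, 40L, 8L, 40L),
                   untagged = 0L, all = c(45L, 45L, 48L, 45L),
                   region_id = 2L, tsc_id = 2L)
  tsc_set <- structure(list(
    tsc = data.frame(tsc_id = 1:2, contig = "c", strand = "+",
                     region_id = 1:2, start = c(100L, 200L),
                     end = c(121L, 231L), n_tss = c(3L, 4L),
                     a1 = c(60L, 90L), a2 = c(28L, 93L), untagged = 0L,
                     all = c(88L, 183L), max_count = c(48L, 48L),
                     maxtss_pos = c(100L, 220L), n_maxtss = 1L),
    members = rbind(members, m2)), class = "tsc_set")
  set.seed(1)
  sh <- tsc_shape_test(tsc_set, method = "mc", B = 999)
  expect_true(all(sh$significant))
  cl <- classify_shape_change(tsc_set, sh, method = "mc", B = 999)
  expect_equal(cl$class[cl$tsc_id == 1], "single")
  expect_equal(cl$class[cl$tsc_id == 2], "multi")
  expect_equal(cl$masked_pos[cl$tsc_id == 1], 100L)
})

test_that("abundance and shape q-values control the false call rate under the null", {
  set.seed(21)
  n <- 400
  a1 <- rpois(n, 20); a2 <- rpois(n, 20)
  q <- bh_fdr(binomial_allelic_test(a1, a2))
  expect_lte(mean(q <= 0.1), 0.02)
})
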