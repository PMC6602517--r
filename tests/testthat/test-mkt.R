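test_that("Fisher exact p matches enumeration and the classic implementation", {
  expect_equal(fisher_exact_2x2(2, 0, 0, 2)$p_value, 1 / 3, tolerance = 1e-12)
  expect_identical(fisher_exact_2x2(1, 1, 1, 1)$p_value, 1)
  set.seed(31)
  for (i in 1:200) {
    t <- random_table()
    got <- fisher_exact_2x2(t[1], t[2], t[3], t[4])$p_value
    expect_equal(got, oracle_fisher_p(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
    m <- matrix(c(t[1], t[2], t[3], t[4]), 2)
    if (min(rowSums(m), colSums(m)) > 0)
      expect_equal(got, stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("zero-margin tables are flagged degenerate with p = 1", {
  res <- fisher_exact_2x2(0, 0, 3, 5)
  expect_identical(res$p_value, 1)
  expect_true("degenerate_margin" %in% res$notes)
})

test_that("alpha point estimate follows the MK ratio identity", {
  expect_equal(alpha_point(2, 2, 2, 2)$alpha, 0)
  expect_equal(alpha_point(10, 10, 20, 10)$alpha, 0.5)
  und <- alpha_point(1, 0, 5, 5)
  expect_true(is.na(und$alpha))
  expect_true("alpha_undefined" %in% und$notes)
  # alpha <= 1 and scale invariance over random tables
  set.seed(77)
  for (i in 1:100) {
    t <- random_table() + c(0, 1, 1, 0)   # ensure ps, dn > 0
    a1 <- alpha_point(t[1], t[2], t[3], t[4])$alpha
    expect_lte(a1, 1)
    k <- sample(2:9, 1)
    expect_equal(alpha_point(k * t[1], k * t[2], k * t[3], k * t[4])$alpha, a1)
  }
})

test_that("the standard test sums bins and ignores their arrangement", {
  v <- divergence_summary(20, 10)
  d1 <- daf_table(c(0.1, 0.5, 0.9), c(2, 5, 3), c(4, 4, 2), n_sample = 10)
  d2 <- daf_table(c(0.2, 0.8), c(9, 1), c(1, 9), n_sample = 10)  # same sums
  r1 <- mkt(d1, v, method = "standard")
  r2 <- mkt(d2, v, method = "standard")
  expect_equal(r1$alpha, 0.5)
  expect_equal(r1$alpha, r2$alpha)
  expect_equal(r1$p_value, r2$p_value)
  # all-zero polymorphism: alpha undefined, p degenerate
  d0 <- daf_table(0.5, 0, 0)
  r0 <- mkt(d0, v, method = "standard")
  expect_true(is.na(r0$alpha))
  expect_true("alpha_undefined" %in% r0$notes)
})

test_that("FWW at cutoff 0 is the standard test; positive cutoffs drop bins", {
  set.seed(12)
  for (i in 1:50) {
    d <- random_daf()
    v <- divergence_summary(rpois(1, 12) + 1, rpois(1, 8) + 1)
    s <- mkt(d, v, method = "standard")
    f <- mkt(d, v, method = "fww", cutoff = 0)
    expect_equal(f$alpha, s$alpha)
    expect_equal(f$p_value, s$p_value)
  }
  d <- daf_table(c(0.1, 0.5), pn = c(8, 2), ps = c(2, 8))
  v <- divergence_summary(10, 10)
  f <- mkt(d, v, method = "fww", cutoff = 0.25)
  expect_equal(unname(f$table[c("pn", "ps")]), c(2, 8))
  expect_equal(f$alpha, 0.75)
  expect_error(mkt(d, v, method = "fww", cutoff = 1), "cutoff")
})

test_that("FWW raises alpha when removed bins are Pn-enriched", {
  set.seed(9)
  for (i in 1:50) {
    # low bin strictly more Pn-biased than the high bins
    d <- daf_table(c(0.02, 0.4, 0.6),
                   pn = c(rpois(1, 20) + 10, rpois(1, 3), rpois(1, 3)),
                   ps = c(rpois(1, 3) + 1, rpois(1, 8) + 3, rpois(1, 8) + 3))
    v <- divergence_summary(rpois(1, 15) + 5, rpois(1, 10) + 5)
    low_ratio <- d$pn[1] / d$ps[1]
    high_ratio <- sum(d$pn[2:3]) / sum(d$ps[2:3])
    if (low_ratio > high_ratio) {
      expect_gte(mkt(d, v, "fww", cutoff = 0.25)$alpha,
                 mkt(d, v, "standard")$alpha)
    }
  }
})

test_that("eMKT partitions low-frequency polymorphism as specified", {
  d <- daf_table(c(0.05, 0.5), pn = c(10, 5), ps = c(4, 8))
  v <- divergence_summary(20, 10, m_n = 300, m_s = 100)
  r <- mkt(d, v, method = "emkt", cutoff = 0.1)
  expect_equal(r$pn_neutral, 7.5)             # 5 + 5*4/8
  expect_equal(r$weakly_deleterious, 7.5)     # 10 - 2.5
  expect_equal(r$alpha, 0.6875)               # 1 - (10*7.5)/(20*12)
  # regime fractions from the site totals
  expect_equal(unname(r$fractions["f"]), 100 * 7.5 / (300 * 12))
  expect_equal(unname(r$fractions["b"]), 100 * 7.5 / (300 * 12))
  expect_equal(sum(r$fractions), 1, tolerance = 1e-9)
  expect_true(all(r$fractions >= 0 & r$fractions <= 1))
})

test_that("eMKT equals the standard test on proportional spectra", {
  set.seed(41)
  for (i in 1:60) {
    ps <- rpois(8, 6) + 1
    k <- sample(1:4, 1)
    d <- daf_table(sort(sample(seq(0.01, 0.99, 0.01), 8)), pn = k * ps, ps = ps)
    v <- divergence_summary(rpois(1, 12) + 1, rpois(1, 8) + 1)
    cutoff <- runif(1, 0.05, max(d$daf))
    e <- mkt(d, v, method = "emkt", cutoff = cutoff)
    s <- mkt(d, v, method = "standard")
    expect_equal(e$alpha, s$alpha, tolerance = 1e-12)
  }
})

test_that("eMKT flags degenerate partitions and missing site totals", {
  # no neutral polymorphism above the cutoff
  d <- daf_table(c(0.02, 0.5), pn = c(5, 3), ps = c(4, 0))
  v <- divergence_summary(10, 5)
  r <- mkt(d, v, method = "emkt", cutoff = 0.1)
  expect_true("partition_undefined" %in% r$notes)
  expect_true(is.na(r$alpha))
  # unknown m_n/m_s: no fractions, note instead
  d2 <- daf_table(c(0.05, 0.5), pn = c(10, 5), ps = c(4, 8))
  r2 <- mkt(d2, v, method = "emkt", cutoff = 0.1)
  expect_null(r2$fractions)
  expect_true("site_totals_unknown" %in% r2$notes)
})

test_that("mkt() accepts gene records and its methods print coherently", {
  g <- random_gene("g1", 5)
  r <- mkt(g, method = "standard")
  expect_s3_class(r, "mkt")
  expect_equal(unname(coef(r)["alpha"]), r$alpha)
  expect_output(print(r), "Standard MKT")
  expect_output(summary(mkt(g, method = "emkt")), "Extended MKT")
  expect_error(confint(r), "asymptotic")
})
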