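test_that("fixed-threshold burden collapses strictly below T", {
  d <- cbind(v1 = c(0, 1, 2, 0))
  b <- ft_burden(d, maf = 0.01, threshold = 0.05)
  expect_equal(b$score, c(0, 1, 2, 0))
  expect_false(b$empty)
  # boundary: maf not strictly below T is excluded
  b2 <- ft_burden(cbind(c(1, 0, 1), c(0, 2, 0)), maf = c(0.06, 0.20),
                  threshold = 0.05)
  expect_true(b2$empty)
  expect_equal(b2$score, c(0, 0, 0))
  d3 <- cbind(c(1, 0, 1), c(0, 2, 1))
  b3 <- ft_burden(d3, maf = c(0.01, 0.02), threshold = 0.05)
  expect_equal(b3$score, c(1, 2, 2))
})

test_that("Madsen-Browning weights use the pseudocount frequency in the reference group", {
  # 8 individuals, reference = first 4, zero reference copies at v1
  d <- cbind(v1 = c(0, 0, 0, 0, 1, 0, 1, 0),
             v2 = c(0, 1, 0, 0, 0, 0, 0, 1))
  ref <- c(rep(TRUE, 4), rep(FALSE, 4))
  b <- we_burden(d, ref)
  expect_equal(unname(b$weights[1]), sqrt(4 * 0.1 * 0.9))  # q = 1/10
  expect_equal(b$score[5], 1 / 0.6, tolerance = 1e-12)
  # identical reference counts give identical weights; score invariant
  # under swapping the two columns
  d2 <- cbind(v1 = c(0, 1, 0, 0, 1, 0), v2 = c(1, 0, 0, 0, 0, 1))
  ref2 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  b2 <- we_burden(d2, ref2)
  b2s <- we_burden(d2[, c(2, 1)], ref2)
  expect_equal(unname(b2$weights), unname(rev(b2s$weights)))
  expect_equal(b2$score, b2s$score)
  # all-zero dosage collapses to the zero score regardless of weights
  expect_equal(we_burden(matrix(0, 4, 2), rep(TRUE, 4))$score, rep(0, 4))
  expect_error(we_burden(d, rep(FALSE, 8)), "empty reference")
})

test_that("burden statistic is the Pearson correlation with constant-input convention", {
  expect_equal(burden_statistic(rep(0, 5), rnorm(5)), 0)
  y <- c(1, 5, 2, 7)
  expect_equal(burden_statistic(y, y), 1)
  # frozen from the stats::cor oracle
  expect_equal(burden_statistic(c(0, 1, 2, 0), c(1, 2, 4, 1)),
               cor(c(0, 1, 2, 0), c(1, 2, 4, 1)))
  expect_equal(burden_statistic(c(0, 1, 2, 0), c(1, 2, 4, 1)),
               0.98473192783466, tolerance = 1e-12)
  expect_error(burden_statistic(1:4, 1:3), "length mismatch")
})

test_that("variable-threshold statistic matches brute-force threshold enumeration", {
  set.seed(31)
  for (i in 1:20) {
    n <- 12; m <- sample(1:5, 1)
    d <- matrix(rbinom(n * m, 2, runif(m, 0.05, 0.4)[rep(1:m, each = n)]),
                n, m)
    co <- make_cohort(d)
    y <- rnorm(n)
    got <- vt_statistic(co$dosage, co$maf, y)
    if (got$degenerate) {
      expect_true(all(co$maf == 0))
      next
    }
    want <- vt_brute_force(co$dosage, co$maf, y)
    expect_equal(got$z_max, want$z_max, tolerance = 1e-12)
    expect_equal(got$t_opt, want$t_opt)
  }
  # single polymorphic variant: one candidate, T_opt = its MAF
  co <- make_cohort(cbind(c(0, 1, 0, 2, 0, 0)))
  y <- c(0.1, 2.3, -0.5, 3.1, 0.2, 0)
  one <- vt_statistic(co$dosage, co$maf, y)
  expect_equal(one$t_opt, unname(co$maf[1]))
  expect_equal(one$z_max, abs(cor(co$dosage[, 1], y)))
  # constant phenotype: all thresholds give 0
  expect_equal(vt_statistic(co$dosage, co$maf, rep(2, 6))$z_max, 0)
  # VT dominates FT at any candidate threshold; at T above the largest MAF
  # the FT collapse equals VT's largest-MAF candidate
  d2 <- cbind(c(0, 1, 0, 0, 1, 0), c(1, 0, 0, 2, 0, 1), c(0, 0, 1, 0, 1, 1))
  co2 <- make_cohort(d2)
  vt <- vt_statistic(co2$dosage, co2$maf, y)
  for (t in vt$thresholds)
    expect_gte(vt$z_max,
               abs(burden_statistic(ft_burden(co2$dosage, co2$maf,
                                              min(t + 1e-9, 0.5)), y)))
  ft_all <- abs(burden_statistic(ft_burden(co2$dosage, co2$maf, 0.5), y))
  expect_equal(ft_all, vt$z_by_threshold[length(vt$thresholds)])
})

test_that("permutation p-value matches exhaustive enumeration for small n", {
  d <- cbind(c(0, 1, 2, 0, 1))
  co <- make_cohort(d)
  y <- c(0.3, 1.9, 3.1, -0.2, 1.2)
  stat <- ft_abs_stat(0.5)
  p_exact <- exact_perm_p(stat, co$dosage, co$maf, y)
  got <- permutation_pvalue(stat, co$dosage, co$maf, y, B = 1999, seed = 7)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(got$p_raw - p_exact), max(3 * se, 1 / 2000) + 1 / 2000)
  # VT inside the permutation loop, against the same oracle
  d2 <- cbind(c(0, 1, 0, 2, 1), c(1, 0, 0, 1, 0))
  co2 <- make_cohort(d2)
  vstat <- function(dd, mm, yy) vt_statistic(dd, mm, yy)$z_max
  p_exact2 <- exact_perm_p(vstat, co2$dosage, co2$maf, y)
  got2 <- permutation_pvalue(vstat, co2$dosage, co2$maf, y, B = 1999,
                             seed = 8)
  se2 <- sqrt(p_exact2 * (1 - p_exact2) / 2000)
  expect_lt(abs(got2$p_raw - p_exact2), max(3 * se2, 1 / 2000) + 1 / 2000)
})

test_that("permutation p-value floor, ties, and constant statistic", {
  # constant statistic: every permutation ties, p = 1
  co <- make_cohort(cbind(c(0, 1, 0, 1)))
  got <- permutation_pvalue(function(d, m, y) 42, co$dosage, co$maf,
                            rnorm(4), B = 50, seed = 1)
  expect_equal(got$p_raw, 1)
  # observed statistic strictly above every permuted one: p = 1/(B+1)
  n <- 40
  g <- c(rep(0, 22), rep(2, 18))
  co2 <- make_cohort(cbind(g))
  y <- g + rnorm(n, sd = 1e-3)
  got2 <- permutation_pvalue(ft_abs_stat(0.5), co2$dosage, co2$maf, y,
                             B = 999, seed = 2)
  expect_equal(got2$p_raw, 1 / 1000)
})

test_that("the vectorized gene engine reproduces the generic permutation loop", {
  set.seed(99)
  n <- 30
  d <- matrix(rbinom(n * 3, 2, c(0.02, 0.1, 0.3)[rep(1:3, each = n)]), n, 3)
  co <- make_cohort(d)
  y <- rnorm(n)
  B <- 200
  ft <- rare_gene_test(co$dosage, co$maf, y, "ft", threshold = 0.05,
                       B = B, seed = 5)
  ref <- permutation_pvalue(ft_abs_stat(0.05), co$dosage, co$maf, y,
                            B = B, seed = 5)
  expect_equal(ft$p_raw, ref$p_raw)
  expect_equal(ft$statistic, ref$statistic)
  vt <- rare_gene_test(co$dosage, co$maf, y, "vt", B = B, seed = 5)
  refv <- permutation_pvalue(function(dd, mm, yy) vt_statistic(dd, mm, yy)$z_max,
                             co$dosage, co$maf, y, B = B, seed = 5)
  expect_equal(vt$p_raw, refv$p_raw)
  we <- rare_gene_test(co$dosage, co$maf, y, "we", B = B, seed = 5)
  refw <- permutation_pvalue(function(dd, mm, yy)
    abs(burden_statistic(we_burden(dd, we_reference_group(yy)), yy)),
    co$dosage, co$maf, y, B = B, seed = 5)
  expect_equal(we$p_raw, refw$p_raw)
  expect_equal(we$statistic, refw$statistic)
})

test_that("tests are invariant to phenotype location and positive scale", {
  set.seed(12)
  n <- 25
  d <- matrix(rbinom(n * 2, 2, 0.15), n, 2)
  co <- make_cohort(d)
  y <- rnorm(n)
  for (m in c("ft", "we", "vt")) {
    a <- rare_gene_test(co$dosage, co$maf, y, m, B = 99, seed = 3)
    b <- rare_gene_test(co$dosage, co$maf, 3 * y + 10, m, B = 99, seed = 3)
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    expect_equal(a$p_raw, b$p_raw)
  }
})

test_that("empty or degenerate gene blocks give flagged null results", {
  co <- make_cohort(cbind(c(0, 2, 0, 2), c(2, 0, 2, 0)))  # mafs 0.5, 0.5
  y <- rnorm(4)
  ft <- rare_gene_test(co$dosage, co$maf, y, "ft", threshold = 0.05,
                       B = 49, seed = 1)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_raw, 1)
  expect_equal(ft$detail, "empty_burden")
  mono <- make_cohort(matrix(0, 5, 2))
  vt <- rare_gene_test(mono$dosage, mono$maf, rnorm(5), "vt", B = 49,
                       seed = 1)
  expect_equal(vt$detail, "degenerate")
  expect_equal(vt$p_raw, 1)
})
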