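test_that("gene partition follows the 5% boundary convention", {
  d <- cbind(r1 = c(rep(0, 49), 1),          # maf 0.01
             r2 = c(rep(0, 49), 1),
             c1 = rep(c(0, 1), 25),           # maf 0.25
             b1 = c(rep(1, 5), rep(0, 45)))   # maf 0.05 exactly
  co <- make_cohort(d)
  mp <- gene_map(list(rareOnly = c("r1"),
                      mixed = c("r2", "c1"),
                      boundary = "b1"), co)
  part <- partition_genes(co, mp)
  expect_equal(part$group1, "rareOnly")
  expect_equal(part$group2, "mixed")
  # maf exactly at the threshold counts as common
  expect_equal(part$group3, "boundary")
})

test_that("power and type I arithmetic over replicates", {
  # 2 causal + 3 null genes, 10 replicates, Bonferroni over 5 genes
  genes <- c("C1", "C2", "N1", "N2", "N3")
  truth <- c("C1", "C2")
  alpha <- 0.05
  mk <- function(p) gene_test_results(genes, "FT", 0.05, 0.5, p, p, 3L)
  # 7 causal detections out of 20, no null detections
  plist <- lapply(1:10, function(r) {
    p <- rep(0.9, 5)
    if (r <= 7) p[1] <- alpha / 5 / 2      # C1 detected in 7 replicates
    mk(p)
  })
  rep_ <- estimate_power_type1(plist, truth, alpha = alpha)
  expect_equal(rep_$power, 7 / 20)
  expect_equal(rep_$type1, 0)
  # all p = 1: power 0, type I 0
  rep0 <- estimate_power_type1(lapply(1:3, function(i) mk(rep(1, 5))),
                               truth)
  expect_equal(rep0$power, 0)
  expect_equal(rep0$type1, 0)
  # inconsistent gene sets across replicates error out
  bad <- list(mk(rep(0.5, 5)), mk(rep(0.5, 5))[1:4, ])
  expect_error(estimate_power_type1(bad, truth), "inconsistent")
})

test_that("qq table uses midpoint expected quantiles", {
  one <- qq_table(0.5)
  expect_equal(one$expected, -log10(0.5))
  expect_equal(one$observed, -log10(0.5))
  set.seed(10)
  u <- runif(2000)
  qq <- qq_table(u)
  expect_true(all(diff(qq$observed) >= 0))
  expect_lt(max(abs(qq$observed - qq$expected)[qq$expected < 1]), 0.25)
  # an inflated family sits above the diagonal in the tail
  infl <- pchisq(2 * qchisq(u, 1), 1, lower.tail = FALSE)
  qi <- qq_table(infl)
  tail_ <- qi$expected > 1
  expect_true(all(qi$observed[tail_] > qi$expected[tail_]))
})

test_that("causal gene ranking uses ascending p with average ties", {
  res <- gene_test_results(c("A", "B", "C", "D", "E"), "VT",
                           p_raw = c(0.01, 0.2, 0.2, 0.5, 0.9),
                           p_corrected = c(0.01, 0.2, 0.2, 0.5, 0.9))
  rk <- rank_causal_genes(res, c("A", "C", "Z"))
  expect_equal(rk$rank, c(1, 2.5, NA))
  expect_equal(rk$p, c(0.01, 0.2, NA))
  # brute-force sort oracle on a random table
  set.seed(40)
  p <- runif(10)
  res2 <- gene_test_results(sprintf("G%02d", 1:10), "FT", 0.05,
                            p_raw = p, p_corrected = p)
  rk2 <- rank_causal_genes(res2, sprintf("G%02d", 1:10))
  expect_equal(rk2$rank, rank(p))
})

test_that("combine_results fuses corrected component families per gene", {
  ft <- gene_test_results(c("A", "B"), "FT", 0.05, p_raw = c(0.1, 0.5),
                          p_corrected = c(0.2, 0.6), n_markers = 2L)
  cv <- gene_test_results(c("B", "A"), "CV_pmin", 0.05,
                          p_raw = c(0.3, 0.04),
                          p_corrected = c(0.4, 0.08), n_markers = 3L)
  comb <- combine_results(ft, cv)
  expect_equal(comb$method, rep("COMB_pmin", 2))
  iA <- which(comb$gene_id == "A")
  UA <- -2 * (log(0.2) + log(0.08))
  expect_equal(comb$statistic[iA], UA, tolerance = 1e-12)
  expect_equal(comb$p_raw[iA], pchisq(UA, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(combine_results(ft, cv, genes = "Z"), "no genes shared")
})

test_that("pipeline is deterministic and emits all artifacts on a tiny design", {
  cfg <- list(design = list(n_individuals = 100, n_genes = c(12, 8, 2),
                            seed = 6),
              phenotype = list(gamma = 0.3, n_replicates = 2, seed = 2),
              analysis = list(B = 99, seed = 11,
                              ft_thresholds = c(0.01, 0.05)))
  out1 <- suppressMessages(run_pipeline(cfg))
  out2 <- suppressMessages(run_pipeline(cfg))
  expect_identical(out1$results, out2$results)
  expect_identical(out1$report, out2$report)
  methods1 <- unique(out1$results[[1]]$method)
  expect_true(all(c("FT", "WE", "VT", "CV_pmin", "CV_lasso",
                    "COMB_pmin", "COMB_lasso") %in% methods1))
  # written artifacts round-trip
  dir <- file.path(tempdir(), "pipe_out")
  cfg$out_dir <- dir
  out3 <- suppressMessages(run_pipeline(cfg))
  expect_true(file.exists(file.path(dir, "results_rep001.tsv")))
  back <- read_results(file.path(dir, "results_rep001.tsv"))
  expect_equal(sort(unique(back$method)), sort(methods1))
})

test_that("a null design yields no Bonferroni-significant gene in a typical replicate", {
  cfg <- list(design = list(n_individuals = 150, n_genes = c(20, 10, 2),
                            seed = 19),
              phenotype = list(gamma = 0, n_replicates = 2, seed = 7),
              analysis = list(B = 199, seed = 3))
  out <- suppressMessages(run_pipeline(cfg))
  for (grp in names(out$report)) {
    tab <- out$report[[grp]]
    expect_true(all(is.na(tab$power)))
    expect_true(all(tab$type1 <= 0.12))
  }
})

test_that("a strong common causal variant in a mixed gene is caught by CV and combined tests", {
  sim <- simulate_cohort(study_design(n_individuals = 400,
                                      n_genes = c(20, 30, 5), seed = 23))
  part <- partition_genes(sim$cohort, sim$map)
  # plant a large effect on one mixed gene's common variant
  target <- part$group2[1]
  vids <- sim$map[[target]]
  cv_id <- vids[sim$cohort$maf[vids] >= 0.05][1]
  cm <- causal_model(data.frame(variant_id = cv_id, gene_id = target,
                                beta = 0.6), sim$map)
  y <- simulate_phenotype(sim$cohort, cm, sim$ancestry, gamma = 0,
                          seed = 5)$rep_1
  cv <- suppressMessages(run_common_tests(sim$cohort, sim$map, y,
                                          methods = "pmin",
                                          genes = part$group2))
  ft <- run_rare_tests(sim$cohort, sim$map, y, methods = "ft",
                       ft_thresholds = 0.01, B = 199, seed = 2,
                       genes = part$group2)
  ft$p_corrected <- ft$p_raw
  comb <- combine_results(ft, cv, genes = part$group2)
  n2 <- length(part$group2)
  bonf <- 0.05 / n2
  expect_lt(cv$p_corrected[cv$gene_id == target], bonf)
  expect_lt(comb$p_raw[comb$gene_id == target], bonf)
  # the 1% fixed-threshold burden misses the common signal
  expect_gt(ft$p_raw[ft$gene_id == target], bonf)
  # power is monotone in effect size on matched seeds
  p_at <- function(beta) {
    cmb <- causal_model(data.frame(variant_id = cv_id, gene_id = target,
                                   beta = beta), sim$map)
    yb <- simulate_phenotype(sim$cohort, cmb, sim$ancestry, gamma = 0,
                             seed = 5)$rep_1
    suppressMessages(run_common_tests(sim$cohort, sim$map, yb,
                                      methods = "pmin",
                                      genes = target))$p_corrected
  }
  expect_lt(p_at(0.6), p_at(0.15))
})
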