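test_that("Pearson 2x2 statistic matches hand computation", {
  r <- chi_squared_2x2(matrix(c(30, 70, 60, 40), 2, byrow = TRUE))
  expect_equal(r$statistic, 4400 / 242, tolerance = 1e-9)  # 18.1818...
  expect_equal(r$pvalue, pchisq(4400 / 242, 1, lower.tail = FALSE))

  flat <- chi_squared_2x2(matrix(c(50, 50, 50, 50), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$pvalue, 1)

  expect_equal(chi_squared_2x2(matrix(c(1, 0, 0, 1), 2))$statistic, 2)

  expect_warning(z <- chi_squared_2x2(matrix(c(0, 0, 3, 4), 2,
                                             byrow = TRUE)),
                 "marginal")
  expect_equal(z$pvalue, 1)
})

test_that("chi-squared agrees with an independent implementation on random tables", {
  set.seed(101)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    ours <- chi_squared_2x2(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$pvalue, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("exact rank-sum p equals the enumeration oracle (all 3v3 and 4v4 splits)", {
  for (n in c(3L, 4L)) {
    idxs <- utils::combn(2L * n, n)
    for (j in seq_len(ncol(idxs))) {
      vals <- seq_len(2L * n) / 10
      x <- vals[idxs[, j]]
      y <- vals[-idxs[, j]]
      p_exact <- suppressWarnings(
        wilcox.test(x, y, exact = TRUE)$p.value)
      expect_equal(p_exact, oracle_ranksum_p(x, y), tolerance = 1e-12)
      # the package's exact mode goes through the same null
      expect_equal(differential_with_reps(x, y, exact = TRUE)$pvalue,
                   p_exact, tolerance = 1e-12)
    }
  }
})

test_that("rank-sum benchmarks: separated 3v3 and 5v5, identical groups", {
  r <- differential_with_reps(c(0.10, 0.12, 0.11),
                              c(0.50, 0.55, 0.60), exact = TRUE)
  expect_equal(r$pvalue, 0.1)           # 2/C(6,3)
  # the default normal approximation can cross 0.05 at full separation
  rn <- differential_with_reps(c(0.10, 0.12, 0.11),
                               c(0.50, 0.55, 0.60))
  expect_lt(rn$pvalue, 0.05)
  expect_true(rn$significant)           # delta 0.44 > 0.2 too

  r55 <- differential_with_reps(1:5 / 10, 6:10 / 10, exact = TRUE)
  expect_equal(r55$pvalue, 2 / 252, tolerance = 1e-12)

  same <- differential_with_reps(c(0.3, 0.3), c(0.3, 0.3))
  expect_equal(same$pvalue, 1)
  expect_false(same$significant)
})

test_that("significance requires both p < 0.05 and |dTR| > 0.2", {
  # clear rank separation but tiny effect: p small, delta small
  a <- c(0.30, 0.31, 0.32, 0.33)
  b <- c(0.40, 0.41, 0.42, 0.43)
  r <- differential_with_reps(a, b)
  expect_lt(r$pvalue, 0.05)
  expect_false(r$significant)
  # big delta, hopeless p
  r2 <- differential_with_reps(c(0.1, 0.9), c(0.5, 0.6))
  expect_gt(r2$pvalue, 0.05)
  expect_false(r2$significant)
})

test_that("condition exchange flips the TR difference but not the p-value", {
  set.seed(5)
  for (i in 1:20) {
    a <- runif(3); b <- runif(3)
    r1 <- differential_with_reps(a, b)
    r2 <- differential_with_reps(b, a)
    expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-12)
    expect_equal(r1$tr1 - r1$tr2, -(r2$tr1 - r2$tr2), tolerance = 1e-12)
    expect_equal(r1$delta, r2$delta)
  }
})

test_that("chi-squared path flags planted differential events, not self-comparisons", {
  cfg <- sim_config(n_genes = 120L, depth = 50, n_decoys = 20L,
                    differential = list(n_diff = 25L, n_same = 25L,
                                        n_replicates = 2L), seed = 31L)
  pair <- simulate_ipa_pair(cfg)
  catalog <- build_catalog(pair$annotation, db_sites = data.frame(
    chrom = pair$sites$chrom, pos = pair$sites$pos,
    strand = pair$sites$strand))
  covA <- pair$samples[[1]][[1]]
  covB <- pair$samples[[2]][[1]]
  evA <- detect_sample(pair$annotation, catalog, covA)
  evB <- detect_sample(pair$annotation, catalog, covB)
  res <- differential_no_reps(pair$annotation, evA, evB, covA, covB)
  expect_true(all(res$test == "chi_squared"))
  expect_true(all(res$significant ==
                    (res$pvalue < 0.05 & res$delta > 0.2)))
  # planted differential events are recovered as significant
  m <- match_events(res, pair$truth[pair$truth$differential, ])
  expect_gte(sum(res$significant[m$pairs$call_idx]),
             0.8 * sum(pair$truth$differential))
  # self-comparison yields no significant events
  self <- differential_no_reps(pair$annotation, evA, evA, covA, covA)
  expect_equal(sum(self$significant), 0L)
})

test_that("replicate path is null-calibrated on a no-effect dataset", {
  cfg <- sim_config(n_genes = 150L, depth = 50, n_decoys = 0L,
                    differential = list(n_diff = 0L, n_same = 60L,
                                        n_replicates = 3L), seed = 37L)
  pair <- simulate_ipa_pair(cfg)
  res <- differential_replicates(pair$annotation, pair$truth,
                                 pair$samples[[1]], pair$samples[[2]])
  n <- nrow(res)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lte(mean(res$significant), 0.05 + 3 * se)
  expect_true(all(res$test == "wilcoxon"))
})
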