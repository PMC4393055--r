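test_that("within-condition statistic is exactly 1 for homogeneous counts", {
  for (reps in list(c(5, 5), c(0, 0), c(7, 7, 7), c(0, 0, 0, 0), c(123, 123))) {
    r <- log_lambda_within(reps)
    expect_identical(r$log_statistic, 0)
    expect_identical(r$p_value, 1)
    expect_false(r$reject)
  }
})

test_that("within-condition statistic matches direct likelihood arithmetic", {
  # (1,3): Lambda1 = 4^4 / (2^4 * 1^1 * 3^3) = 256/432, direct from the
  # likelihood-ratio definition
  r <- log_lambda_within(c(1, 3))
  expect_equal(r$log_statistic, log(256 / 432), tolerance = 1e-12)
  expect_equal(r$statistic, -2 * log(256 / 432), tolerance = 1e-12)
  expect_equal(r$p_value,
               pchisq(-2 * log(256 / 432), df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_identical(r$df, 1L)

  # second oracle: brute-force likelihood ratio from the Poisson pmf itself
  reps <- c(4, 9, 2)
  lik <- function(lams) prod(dpois(reps, lams))
  direct <- log(lik(rep(mean(reps), 3)) / lik(reps))
  expect_equal(log_lambda_within(reps)$log_statistic, direct, tolerance = 1e-12)
})

test_that("within statistic is non-positive and permutation-invariant", {
  set.seed(21)
  for (i in 1:25) {
    reps <- rpois(sample(2:6, 1), lambda = sample(c(0, 3, 40, 900), 1))
    r <- log_lambda_within(reps)
    expect_lte(r$log_statistic, 0)
    expect_equal(log_lambda_within(sample(reps))$log_statistic,
                 r$log_statistic, tolerance = 1e-12)
  }
  expect_error(log_lambda_within(c(5)), class = "poisde_domain_error")
  expect_error(log_lambda_within(c(1.5, 2)), class = "poisde_domain_error")
})

test_that("between-condition statistic is exactly 1 when per-replicate means agree", {
  cases <- list(c(10, 1, 10, 1), c(0, 1, 0, 1), c(0, 3, 0, 2),
                c(6, 2, 9, 3), c(100, 4, 25, 1))
  for (cs in cases) {
    r <- log_lambda3_between(cs[1], cs[2], cs[3], cs[4])
    expect_identical(r$log_statistic, 0)
    expect_identical(r$p_value, 1)
  }
})

test_that("between-condition statistic matches direct likelihood arithmetic", {
  # x = 2, m = 1, y = 8, n = 1: Lambda3 = (1/2)^2 (1/2)^8 10^10 / (2^2 8^8)
  direct <- 2 * log(0.5) + 8 * log(0.5) + 10 * log(10) - 2 * log(2) - 8 * log(8)
  r <- log_lambda3_between(2, 1, 8, 1)
  expect_equal(r$log_statistic, direct, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(-2 * direct, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # brute-force profile-likelihood oracle on the joint Poisson model
  x <- 14; m <- 3; y <- 4; n <- 2
  l0 <- (x + y) / (m + n)
  direct2 <- dpois(x, m * l0, log = TRUE) + dpois(y, n * l0, log = TRUE) -
    dpois(x, x, log = TRUE) - dpois(y, y, log = TRUE)
  expect_equal(log_lambda3_between(x, m, y, n)$log_statistic, direct2,
               tolerance = 1e-12)
})

test_that("between-condition statistic is symmetric and validated", {
  r1 <- log_lambda3_between(17, 2, 140, 3)
  r2 <- log_lambda3_between(140, 3, 17, 2)
  expect_identical(r1$log_statistic, r2$log_statistic)
  expect_error(log_lambda3_between(3, 0, 4, 1), class = "poisde_domain_error")
  expect_error(log_lambda3_between(-1, 1, 4, 1), class = "poisde_domain_error")
})

test_that("within_screen summarizes homogeneity and nests across levels", {
  # perfectly homogeneous matrix: 100% similar everywhere
  mat <- matrix(rep(c(8, 8, 8), each = 4), ncol = 3, byrow = FALSE)
  cm <- make_cm(cbind(mat, 5), c("a", "a", "a", "b"))
  scr <- within_screen(cm, "a")
  expect_equal(unname(scr$percent_similar), rep(100, 4))

  # simulated data: the percent-similar column is non-increasing in level
  sim <- simulate_counts(simulation_design(800, m = 4, n = 2,
                                           lambda_min = 10, lambda_max = 1000,
                                           seed = 31))
  scr2 <- within_screen(sim$counts, "cond1", levels = c(0.01, 0.025, 0.05, 0.10))
  expect_true(all(diff(unname(scr2$percent_similar)) <= 0))
  expect_identical(nrow(scr2$results), 800L)

  expect_error(within_screen(cm, "nope"), class = "poisde_mapping_error")
  expect_error(within_screen(cm, "b"), class = "poisde_domain_error")
})

test_that("within_screen is calibrated on null Poisson replicates", {
  sim <- simulate_counts(simulation_design(5000, m = 5, n = 1,
                                           lambda_min = 20, lambda_max = 2000,
                                           seed = 33))
  scr <- within_screen(sim$counts, "cond1", levels = 0.01)
  # expect ~99% similar, within 3 Monte-Carlo standard errors
  se <- 100 * sqrt(0.01 * 0.99 / 5000)
  expect_gt(unname(scr$percent_similar), 99 - 3 * se)
})

test_that("de_lrt covers every gene once and has expected power and nulls", {
  set.seed(35)
  null_gene <- rpois(4, 100)
  de_gene <- c(rpois(2, 100), rpois(2, 400))      # 4-fold change
  flat <- c(12, 12, 12, 12)                       # x/m = y/n exactly
  cm <- make_cm(rbind(null_gene, de_gene, flat), c("a", "a", "b", "b"))
  res <- de_lrt(cm, level = 0.01)
  expect_identical(nrow(res), 3L)
  expect_identical(res$gene_id, gene_ids(cm))
  expect_true(res$de[2])
  expect_false(res$de[3])
  expect_identical(res$p_value[3], 1)
})

test_that("de_lrt empirical null rejection tracks the level", {
  des <- simulation_design(5000, m = 2, n = 2, lambda_min = 20,
                           lambda_max = 2000, seed = 37)
  rates <- type1_experiment(des, levels = c(0.01, 0.025, 0.05, 0.10),
                            method = "lrt")
  for (i in seq_len(nrow(rates))) {
    l <- rates$level[i]
    se <- sqrt(l * (1 - l) / 5000)
    expect_lt(abs(rates$rejection_rate[i] - l), 3 * se + 0.005)
  }
  expect_true(all(diff(rates$rejection_rate) > 0))
})

test_that("Benjamini-Hochberg adjustment is available behind a flag", {
  sim <- simulate_counts(simulation_design(300, seed = 39, lambda_min = 20,
                                           lambda_max = 500))
  res <- de_lrt(sim$counts, level = 0.05, adjust = "BH")
  expect_true("p_adjusted" %in% names(res))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
  expect_identical(res$de, res$p_adjusted <= 0.05)
})
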