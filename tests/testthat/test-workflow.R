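test_that("genes are categorized by detection pattern", {
  expect_identical(categorize(0, 0), 1L)
  expect_identical(categorize(0, 50), 2L)
  expect_identical(categorize(50, 0), 2L)
  expect_identical(categorize(7, 11), 3L)
  expect_identical(categorize(0, 3), NA_integer_)   # too weak to call absence
  expect_identical(categorize(3, 4), NA_integer_)   # low/low: indeterminate
  expect_identical(categorize(3, 40), NA_integer_)

  # vectorized, preserving order
  expect_identical(categorize(c(0, 0, 7, 0), c(0, 50, 11, 3)),
                   c(1L, 2L, 3L, NA))
})

test_that("with a zero presence threshold categories split zero/non-zero", {
  grid <- expand.grid(x = 0:3, y = 0:3)
  cat0 <- categorize(grid$x, grid$y, present_min = 0)
  expect_identical(cat0[grid$x == 0 & grid$y == 0], rep(1L, 1))
  expect_true(all(cat0[xor(grid$x == 0, grid$y == 0)] == 2L))
  expect_true(all(cat0[grid$x > 0 & grid$y > 0] == 3L))
  expect_false(anyNA(cat0))
})

test_that("fold change uses pseudo-counted per-replicate means", {
  expect_identical(fold_change(9, 3, 9, 3), 0)
  expect_equal(fold_change(20, 1, 5, 1), log2(20.5 / 5.5))
  expect_equal(fold_change(20, 1, 5, 1), 1.898, tolerance = 1e-3)
  expect_equal(fold_change(5, 2, 80, 2), -fold_change(80, 2, 5, 2))
  expect_true(is.finite(fold_change(0, 2, 500, 2)))
})

# the five pooled-count pairs of the published miRNA worked example,
# split so that condition pools reproduce them with m = n = 2
mirna_example_matrix <- function() {
  x <- c(15117, 3711, 180, 7, 16)
  y <- c(6236, 2044, 67, 11, 30)
  mat <- cbind(x - x %/% 2, x %/% 2, y - y %/% 2, y %/% 2)
  rownames(mat) <- c("let-7g", "miR-192", "miR-27a", "miR-140-5p", "miR-30b*")
  colnames(mat) <- c("n1", "n2", "h1", "h2")
  count_matrix(mat, c(n1 = "normal", n2 = "normal", h1 = "hl60", h2 = "hl60"))
}

test_that("the Bayesian workflow reproduces the worked-example calls", {
  res <- run_de(mirna_example_matrix(), method = "bayes", level = 0.01, present_min = 5)
  expect_identical(res$category, rep(3L, 5))
  expect_identical(res$x_pooled, c(15117, 3711, 180, 7, 16))
  expect_identical(res$de, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(res$tested))
  expect_true(all(res$interval_lo <= res$interval_hi))
})

test_that("category-1 genes are untestable and category-2 called DE by absence", {
  mat <- rbind(zero = c(0, 0, 0, 0),
               absent = c(0, 0, 30, 25),
               weak = c(2, 1, 0, 0),
               both = c(10, 12, 50, 45))
  colnames(mat) <- c("a1", "a2", "b1", "b2")
  cm <- count_matrix(mat, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  res <- run_de(cm, method = "lrt", level = 0.01, present_min = 5)
  expect_identical(res$category, c(1L, 2L, NA, 3L))
  expect_identical(res$de, c(NA, TRUE, NA, TRUE))
  expect_identical(res$tested, c(FALSE, FALSE, FALSE, TRUE))
  expect_true(is.na(res$log2_fold_change[1]))
  expect_false(anyNA(res$log2_fold_change[-1][c(1, 3)]))

  # the flag routes category-2 genes through the test instead
  res2 <- run_de(cm, method = "lrt", level = 0.01, present_min = 5,
                 test_category2 = TRUE)
  expect_true(res2$tested[2])
  expect_false(is.na(res2$p_value[2]))
})

test_that("degenerate workflows behave", {
  zero <- make_cm(matrix(0, 4, 4), c("a", "a", "b", "b"))
  res <- run_de(zero, method = "lrt")
  expect_identical(res$category, rep(1L, 4))
  expect_false(any(res$tested))

  flat <- make_cm(matrix(20, 3, 4), c("a", "a", "b", "b"))
  res2 <- run_de(flat, method = "lrt", level = 0.1)
  expect_false(any(res2$de[res2$category == 3L]))

  expect_error(run_de(make_cm(matrix(5, 2, 3), c("a", "a", "b")), method = "bayes"),
               class = "poisde_unequal_replicates_error")
})

test_that("each input gene appears exactly once, independent of lane order", {
  sim <- simulate_counts(simulation_design(200, seed = 47, de_fraction = 0.2,
                                           fold = 6))
  res <- run_de(sim$counts, method = "lrt")
  expect_identical(res$gene_id, gene_ids(sim$counts))
  perm <- c(3, 1, 4, 2)
  shuffled <- count_matrix(sim$counts$counts[, perm],
                           lane_conditions(sim$counts)[perm])
  res2 <- run_de(shuffled, method = "lrt")
  expect_identical(res2$category, res$category)
  expect_identical(res2$de, res$de)
})

test_that("expression-strength histograms are proper and consistent", {
  sim <- simulate_counts(simulation_design(500, seed = 49))
  cm <- sim$counts
  all_ids <- gene_ids(cm)
  h <- expression_strength_summary(cm, all_ids, bins = 20)
  expect_equal(h$all, h$significant)
  expect_equal(sum(h$all$density), 1)
  expect_identical(length(h$breaks), 21L)

  some <- expression_strength_summary(cm, all_ids[1:50], bins = 20)
  expect_equal(sum(some$significant$density), 1)
  expect_identical(sum(some$significant$count), 50L)

  none <- expression_strength_summary(cm, character(0), bins = 20)
  expect_identical(sum(none$significant$count), 0L)

  expect_error(expression_strength_summary(cm, "not_a_gene"),
               class = "poisde_mapping_error")
})
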