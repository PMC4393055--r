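#' Categorize genes by detection pattern across two conditions
#'
#' Genes fall into three testing strata based on their pooled counts:
#' category 1 (zero in both conditions; nothing can be said), category 2
#' (zero in exactly one condition and at least `present_min` reads in the
#' other; absence in one condition is itself the biological signal), and
#' category 3 (at least `present_min` reads in both; eligible for a
#' statistical test). Pairs that fit none of these -- a positive count below
#' `present_min` on either side -- are returned as `NA` ("indeterminate")
#' and excluded from testing rather than silently reassigned.
#'
#' @param x_pooled,y_pooled Non-negative integer vectors of pooled counts
#'   (recycled to a common length).
#' @param present_min Minimum pooled count regarded as reliable detection
#'   (default 5). With `present_min = 0` categories 2/3 reduce to the
#'   zero/non-zero partition.
#' @return Integer vector of categories in {1, 2, 3}, `NA` for
#'   indeterminate pairs.
#' @examples
#' categorize(0, 0)            # 1
#' categorize(0, 50)           # 2
#' categorize(7, 11)           # 3
#' categorize(0, 3)            # NA: detected too weakly to call absence DE
#' @export
categorize <- function(x_pooled, y_pooled, present_min = 5) {
  if (any(x_pooled < 0) || any(y_pooled < 0)) {
    abort_domain("pooled counts must be non-negative")
  }
  if (length(present_min) != 1 || present_min < 0) {
    abort_domain("'present_min' must be a single non-negative number")
  }
  k <- max(length(x_pooled), length(y_pooled))
  x <- rep_len(x_pooled, k)
  y <- rep_len(y_pooled, k)
  out <- rep(NA_integer_, k)
  out[x == 0 & y == 0] <- 1L
  out[(x == 0 & y >= present_min & y > 0) |
        (y == 0 & x >= present_min & x > 0)] <- 2L
  out[x > 0 & y > 0 & x >= present_min & y >= present_min] <- 3L
  out
}

#' Log2 fold change between pooled per-replicate means
#'
#' `log2((x/m + 0.5) / (y/n + 0.5))`: the per-replicate means with a 0.5
#' pseudo-count, so genes absent in one condition still get a finite
#' (large) fold. Antisymmetric under swapping the two conditions.
#'
#' @inheritParams de_bayes
#' @return Numeric log2 fold change(s); vectorized over counts.
#' @export
fold_change <- function(x_pooled, m, y_pooled, n) {
  if (any(x_pooled < 0) || any(y_pooled < 0)) {
    abort_domain("pooled counts must be non-negative")
  }
  log2((x_pooled / m + 0.5) / (y_pooled / n + 0.5))
}

#' Run the full two-condition differential-expression workflow
#'
#' Pools each gene's counts by condition, categorizes genes with
#' [categorize()], and then: category-1 genes are reported untestable;
#' category-2 genes are called differentially expressed by absence (no test
#' run) unless `test_category2 = TRUE` routes them through the chosen test;
#' category-3 genes are tested by the likelihood-ratio method or the
#' Bayesian method; indeterminate genes are reported but not tested. Log2
#' fold changes are reported for every categorized gene except category 1.
#'
#' @inheritParams normalize_tpm
#' @param method `"lrt"` (two-condition Poisson likelihood-ratio test) or
#'   `"bayes"` (pooled predictive acceptance interval; requires equal
#'   replicate numbers).
#' @param level For `"lrt"`, the significance level; for `"bayes"`, the
#'   per-tail mass alpha. In (0, 0.5).
#' @param present_min Presence threshold passed to [categorize()].
#' @param test_category2 Route category-2 genes through the test instead of
#'   calling them DE by absence.
#' @return A data frame with one row per input gene, in input order:
#'   gene_id, category, x_pooled, y_pooled, m, n, method, tested,
#'   statistic, p_value, interval_lo, interval_hi, de, log2_fold_change.
#' @export
run_de <- function(counts, method = c("lrt", "bayes"), level = 0.01,
                   present_min = 5, test_category2 = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  method <- match.arg(method)
  check_level(level)
  if (!all(is_whole(counts$counts))) {
    abort_domain("tests need integer counts; see round_counts()")
  }
  pooled <- pool_by_condition(counts)
  if (method == "bayes" && pooled$m != pooled$n) {
    abort_unequal_reps(
      "the Bayesian method requires equal replicate numbers in the two conditions (m = n)")
  }
  cat_ <- categorize(pooled$x, pooled$y, present_min)
  g <- length(cat_)
  out <- data.frame(
    gene_id = gene_ids(counts),
    category = cat_,
    x_pooled = pooled$x, y_pooled = pooled$y,
    m = pooled$m, n = pooled$n,
    method = method,
    tested = FALSE,
    statistic = NA_real_, p_value = NA_real_,
    interval_lo = NA_integer_, interval_hi = NA_integer_,
    de = NA,
    log2_fold_change = NA_real_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL

  not1 <- !is.na(cat_) & cat_ != 1L
  out$log2_fold_change[not1] <-
    fold_change(pooled$x[not1], pooled$m, pooled$y[not1], pooled$n)

  test_idx <- !is.na(cat_) & (cat_ == 3L | (cat_ == 2L & test_category2))
  if (!test_category2) out$de[!is.na(cat_) & cat_ == 2L] <- TRUE

  if (any(test_idx)) {
    if (method == "lrt") {
      loglam <- loglam3_vec(pooled$x[test_idx], pooled$m,
                            pooled$y[test_idx], pooled$n)
      stat <- -2 * loglam
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
      out$statistic[test_idx] <- stat
      out$p_value[test_idx] <- p
      out$de[test_idx] <- p <= level
    } else {
      xs <- pooled$x[test_idx]
      ys <- pooled$y[test_idx]
      ab <- interval_table(xs, level)
      out$interval_lo[test_idx] <- ab[, "a"]
      out$interval_hi[test_idx] <- ab[, "b"]
      out$de[test_idx] <- ys < ab[, "a"] | ys > ab[, "b"]
    }
    out$tested[test_idx] <- TRUE
  }
  attr(out, "conditions") <- pooled$conditions
  attr(out, "level") <- level
  out
}

# acceptance intervals for a vector of pooled counts, computed once per
# unique s (whole-transcriptome runs repeat small counts heavily)
interval_table <- function(s_values, alpha) {
  us <- unique(s_values)
  iv <- vapply(us, function(s) {
    r <- acceptance_interval(predictive_law(s, 2), alpha)
    c(a = r$a, b = r$b)
  }, numeric(2))
  t(iv)[match(s_values, us), , drop = FALSE]
}

#' Expression-strength distribution of a significant gene list
#'
#' Compares the distribution of expression strength, log10(1 + mean count
#' per gene across all lanes), between all genes and a significant subset.
#' A well-behaved differential-expression method yields a significant list
#' whose strength distribution roughly follows that of all genes; a method
#' that picks genes uniformly across strengths reflects its error model
#' more than the biology. Both histograms share bin edges spanning the full
#' gene set, and each is normalized to proportions summing to one (the
#' significant histogram is all zero when the set is empty).
#'
#' @inheritParams normalize_tpm
#' @param significant_genes Character vector of gene ids (subset of the
#'   matrix's gene ids).
#' @param bins Number of histogram bins (default 30).
#' @return List with `breaks` (bin edges) and data frames `all` and
#'   `significant` (bin_lo, bin_hi, count, density).
#' @export
expression_strength_summary <- function(counts, significant_genes, bins = 30) {
  stopifnot(inherits(counts, "count_matrix"))
  if (length(bins) != 1 || bins < 1 || !is_whole(bins)) {
    abort_domain("'bins' must be a positive integer")
  }
  unknown <- setdiff(significant_genes, gene_ids(counts))
  if (length(unknown) > 0) {
    abort_mapping(sprintf("unknown gene id(s): %s",
                          paste(utils::head(unknown, 5), collapse = ", ")))
  }
  strength <- log10(1 + rowMeans(counts$counts))
  names(strength) <- gene_ids(counts)
  rng <- range(strength)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  hist_of <- function(v) {
    if (length(v) == 0) {
      cnt <- integer(bins)
      dens <- numeric(bins)
    } else {
      cnt <- graphics::hist(v, breaks = breaks, plot = FALSE,
                            include.lowest = TRUE, right = TRUE)$counts
      dens <- cnt / sum(cnt)
    }
    data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
               count = cnt, density = dens)
  }
  list(breaks = breaks,
       all = hist_of(strength),
       significant = hist_of(strength[significant_genes]))
}
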