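#' Within-condition homogeneity test for one gene's replicate counts
#'
#' Tests whether the counts of one gene across technical replicates of a
#' single condition share a common Poisson mean. The log likelihood ratio
#' for H0: all replicate means equal, against unrestricted means, is
#'
#'   log Lambda = sum_j x_j (log(x/m) - log x_j),   x = sum_j x_j,
#'
#' with the convention 0 log 0 = 0. Under H0, -2 log Lambda is referred to a
#' chi-square distribution with m - 1 degrees of freedom (Wilks), giving a
#' p-value; small Lambda (large -2 log Lambda) rejects.
#'
#' @param reps Non-negative integer vector `x_1..x_m` of one gene's counts
#'   across the m >= 2 replicates of one condition.
#' @param level Significance level for the `reject` field (default 0.01).
#' @return An `lrt_result`: list with `log_statistic` (log Lambda, <= 0),
#'   `statistic` (-2 log Lambda), `df`, `p_value`, `reject`, `level`.
#' @examples
#' log_lambda_within(c(5, 5))    # identical counts: Lambda = 1, p = 1
#' log_lambda_within(c(1, 3))    # Lambda = 256/432
#' @export
log_lambda_within <- function(reps, level = 0.01) {
  check_replicates(reps)
  m <- length(reps)
  if (m < 2) abort_domain("homogeneity test needs at least 2 replicates")
  check_level(level)
  loglam <- loglam1(reps)
  new_lrt_result(loglam, df = m - 1L, level = level)
}

# log Lambda1 for one replicate vector; written so equal counts give an
# exact 0 (each term is x_j * (log(xbar) - log(x_j)) with identical args).
loglam1 <- function(x) {
  s <- sum(x)
  if (s == 0) return(0)
  xbar <- s / length(x)
  pos <- x > 0
  min(0, sum(x[pos] * (log(xbar) - log(x[pos]))))
}

# row-wise vectorized version for whole matrices (lanes of one condition)
loglam1_rows <- function(mat) {
  s <- rowSums(mat)
  lx <- mat
  lx[] <- 0
  pos <- mat > 0
  lx[pos] <- mat[pos] * log(mat[pos])
  out <- xlogx(s) - s * log(ncol(mat)) - rowSums(lx)
  out[s == 0] <- 0
  pmin(out, 0)
}

new_lrt_result <- function(log_statistic, df, level) {
  stat <- -2 * log_statistic
  structure(
    list(log_statistic = log_statistic,
         statistic = stat,
         df = as.integer(df),
         p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
         level = level,
         reject = stats::pchisq(stat, df = df, lower.tail = FALSE) <= level),
    class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf(
    "Poisson LRT: -2 log Lambda = %.4g on %d df, p = %.4g (%s at level %g)\n",
    x$statistic, x$df, x$p_value,
    if (x$reject) "reject" else "do not reject", x$level))
  invisible(x)
}

check_replicates <- function(x) {
  if (!is.numeric(x) || length(x) < 1) abort_domain("replicate counts must be a numeric vector")
  if (any(!is.finite(x)) || any(x < 0) || any(!is_whole(x))) {
    abort_domain("replicate counts must be non-negative integers")
  }
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1 || is.na(level) ||
      level <= 0 || level >= 0.5) {
    abort_domain("significance level must be a single number in (0, 0.5)")
  }
}

#' Two-condition Poisson likelihood-ratio test on pooled counts
#'
#' Pooled counts `x` (over m replicates of condition 1) and `y` (over n
#' replicates of condition 2) are modelled as independent Poisson with means
#' m*lambda and n*mu. The likelihood ratio for H0: lambda = mu is
#'
#'   Lambda3 = (m/(m+n))^x (n/(m+n))^y (x+y)^(x+y) / (x^x y^y),
#'
#' evaluated termwise in log space with 0 log 0 = 0; -2 log Lambda3 is
#' referred to chi-square with 1 degree of freedom. Lambda3 = 1 exactly when
#' the per-replicate means x/m and y/n coincide, and is symmetric under
#' swapping (x, m) with (y, n).
#'
#' @param x,y Pooled non-negative integer counts for the two conditions.
#' @param m,n Replicate numbers (>= 1) for the two conditions.
#' @inheritParams log_lambda_within
#' @return An `lrt_result` with `df = 1`.
#' @examples
#' log_lambda3_between(10, 1, 10, 1)  # equal means: Lambda3 = 1
#' log_lambda3_between(2, 1, 8, 1)
#' @export
log_lambda3_between <- function(x, m, y, n, level = 0.01) {
  for (v in list(x, y)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || !is_whole(v)) {
      abort_domain("pooled counts must be single non-negative integers")
    }
  }
  for (v in list(m, n)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1 || !is_whole(v)) {
      abort_domain("replicate numbers m and n must be positive integers")
    }
  }
  check_level(level)
  new_lrt_result(loglam3(x, m, y, n), df = 1L, level = level)
}

# log Lambda3, exact 0 when x/m == y/n: the expected pooled counts
# (x+y)m/(m+n) and (x+y)n/(m+n) are then exactly x and y (integer-divisible
# products), so each log difference cancels identically.
loglam3 <- function(x, m, y, n) {
  s <- x + y
  if (s == 0) return(0)
  ex <- s * m / (m + n)
  ey <- s * n / (m + n)
  term <- 0
  if (x > 0) term <- term + x * (log(ex) - log(x))
  if (y > 0) term <- term + y * (log(ey) - log(y))
  min(0, term)
}

loglam3_vec <- function(x, m, y, n) {
  s <- x + y
  ex <- s * m / (m + n)
  ey <- s * n / (m + n)
  tx <- ifelse(x > 0, x * (log(ex) - log(x)), 0)
  ty <- ifelse(y > 0, y * (log(ey) - log(y)), 0)
  out <- tx + ty
  out[s == 0] <- 0
  pmin(out, 0)
}

#' Screen all genes for replicate homogeneity within one condition
#'
#' Applies the within-condition likelihood-ratio test gene by gene to the
#' lanes of one condition and summarizes, for each requested level, the
#' percentage of genes whose counts are statistically similar across
#' replicates (p-value above the level). Because rejection regions nest,
#' the percentage is non-increasing in the level.
#'
#' @inheritParams normalize_tpm
#' @param condition Condition label whose lanes are screened (must have at
#'   least two lanes).
#' @param levels Numeric vector of significance levels.
#' @return A `within_screen` object: list with `results` (per-gene data
#'   frame: gene_id, log_statistic, statistic, df, p_value) and
#'   `percent_similar` (named vector, one entry per level).
#' @export
within_screen <- function(counts, condition,
                          levels = c(0.01, 0.025, 0.05, 0.10)) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!condition %in% counts$condition) {
    abort_mapping(sprintf("condition '%s' not present in sample sheet", condition))
  }
  for (l in levels) check_level(l)
  mat <- counts$counts[, counts$condition == condition, drop = FALSE]
  if (ncol(mat) < 2) abort_domain("chosen condition has fewer than 2 lanes")
  if (!all(is_whole(mat))) {
    abort_domain("homogeneity test needs integer counts; see round_counts()")
  }
  loglam <- loglam1_rows(mat)
  stat <- -2 * loglam
  df <- ncol(mat) - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  pct <- vapply(levels, function(l) 100 * mean(p > l), numeric(1))
  structure(
    list(results = data.frame(gene_id = gene_ids(counts),
                              log_statistic = loglam, statistic = stat,
                              df = df, p_value = p,
                              stringsAsFactors = FALSE),
         percent_similar = stats::setNames(pct, paste0(levels * 100, "%")),
         condition = condition,
         n_replicates = ncol(mat)),
    class = "within_screen")
}

#' @export
print.within_screen <- function(x, ...) {
  cat(sprintf(
    "Replicate homogeneity screen: condition '%s', %d replicates, %d genes\n",
    x$condition, x$n_replicates, nrow(x$results)))
  cat("percent of genes with similar counts:\n")
  print(round(x$percent_similar, 2))
  invisible(x)
}

#' Differential expression by the likelihood-ratio method
#'
#' Pools each gene's counts within the two conditions and applies the
#' two-condition Poisson likelihood-ratio test. P-values are reported raw by
#' default (set `adjust = "BH"` for Benjamini-Hochberg-adjusted calls).
#'
#' @inheritParams normalize_tpm
#' @inheritParams log_lambda_within
#' @param adjust Multiple-testing adjustment applied before calling genes:
#'   `"none"` (default) or `"BH"`.
#' @return A data frame with one row per gene: gene_id, x_pooled, y_pooled,
#'   m, n, log_statistic, statistic, df, p_value (plus `p_adjusted` when
#'   adjusted) and the logical call `de`.
#' @export
de_lrt <- function(counts, level = 0.01, adjust = c("none", "BH")) {
  stopifnot(inherits(counts, "count_matrix"))
  adjust <- match.arg(adjust)
  check_level(level)
  if (!all(is_whole(counts$counts))) {
    abort_domain("the test needs integer counts; see round_counts()")
  }
  pooled <- pool_by_condition(counts)
  loglam <- loglam3_vec(pooled$x, pooled$m, pooled$y, pooled$n)
  stat <- -2 * loglam
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  out <- data.frame(
    gene_id = gene_ids(counts),
    x_pooled = pooled$x, y_pooled = pooled$y,
    m = pooled$m, n = pooled$n,
    log_statistic = loglam, statistic = stat, df = 1L,
    p_value = p,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(p, method = "BH")
    out$de <- out$p_adjusted <= level
  } else {
    out$de <- p <= level
  }
  attr(out, "conditions") <- pooled$conditions
  out
}
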