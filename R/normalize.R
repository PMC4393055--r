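#' Count normalization: parts per million, trimmed mean of M-values, quantile
#'
#' Three lane-level normalizations for read-count matrices. `normalize_tpm`
#' divides each lane by its total count and scales to one million, so every
#' lane sums to 1e6. `normalize_tmm` estimates a relative scale factor per
#' lane from a doubly trimmed, precision-weighted mean of per-gene log2
#' ratios against a reference lane, then reports counts per million after
#' dividing by effective library size (total x factor). `normalize_quantile`
#' forces all lanes onto one common distribution, the per-rank median across
#' sorted lanes.
#'
#' @param counts A [count_matrix()].
#' @param trim_M Fraction of genes trimmed from each tail of the log-ratio
#'   (M) ranking before averaging (default 0.30).
#' @param trim_A Fraction trimmed from each tail of the average
#'   log-abundance (A) ranking (default 0.05).
#' @return A `normalization_result`: list with `normalized` (a real-valued
#'   `count_matrix`), `scale_factors` (named per-lane factors; `NULL` for
#'   quantile) and `method`.
#' @seealso [round_counts()] to feed normalized matrices to the integer-count
#'   tests.
#' @export
normalize_tpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  tot <- colSums(counts$counts)
  if (any(tot <= 0)) {
    abort_degenerate(sprintf(
      "lane(s) with zero total count: %s",
      paste(colnames(counts$counts)[tot <= 0], collapse = ", ")))
  }
  norm <- sweep(counts$counts, 2, tot, "/") * 1e6
  # factor is the per-lane divisor: library size in millions
  new_normalization_result(counts, norm, tot / 1e6, "tpm")
}

new_normalization_result <- function(orig, norm, factors, method) {
  out <- count_matrix(norm, orig$condition, raw = FALSE)
  structure(
    list(normalized = out,
         scale_factors = if (is.null(factors)) NULL else
           stats::setNames(as.numeric(factors), colnames(orig$counts)),
         method = method),
    class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("normalization_result (method = %s)\n", x$method))
  print(x$normalized)
  if (!is.null(x$scale_factors)) {
    cat("scale factors:\n")
    print(round(x$scale_factors, 4))
  }
  invisible(x)
}

#' Trimmed-mean-of-M-values scale factor between two lanes
#'
#' Computes `2^f` where `f` is the weighted mean of per-gene log2 ratios
#' `M_g = log2(test_g / ref_g)` after (i) discarding genes with a zero in
#' either lane, (ii) trimming the `trim_M` fraction from each tail of the M
#' ranking and the `trim_A` fraction from each tail of the average
#' log-abundance ranking. Weights are inverse approximate (binomial)
#' variances of `M_g`: `(N_t - t)/(N_t t) + (N_r - r)/(N_r r)` with `N` the
#' lane totals. Note the ratio is taken on the vectors as given; to estimate
#' a composition factor net of sequencing depth, pass depth-scaled lanes
#' (as [normalize_tmm()] does).
#'
#' @param test_lane,ref_lane Non-negative numeric vectors of equal length.
#' @inheritParams normalize_tpm
#' @return A single positive scale factor.
#' @export
tmm_scale_factor <- function(test_lane, ref_lane, trim_M = 0.30, trim_A = 0.05) {
  if (length(test_lane) != length(ref_lane)) {
    abort_domain("test and reference lanes must have the same length")
  }
  nt <- sum(test_lane)
  nr <- sum(ref_lane)
  if (nt <= 0 || nr <= 0) abort_degenerate("lane with zero total count")
  keep0 <- test_lane > 0 & ref_lane > 0
  t_ <- test_lane[keep0]
  r_ <- ref_lane[keep0]
  M <- log2(t_) - log2(r_)
  A <- (log2(t_) + log2(r_)) / 2
  w <- (nt - t_) / (nt * t_) + (nr - r_) / (nr * r_)
  # degenerate but legal when a single gene carries a lane's whole total
  if (all(w <= 0)) w[] <- 1 else w[w <= 0] <- min(w[w > 0])

  ng <- length(M)
  loM <- floor(ng * trim_M) + 1
  hiM <- ng + 1 - loM
  loA <- floor(ng * trim_A) + 1
  hiA <- ng + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (sum(keep) < 2) {
    abort_insufficient("fewer than 2 genes survive TMM trimming")
  }
  f <- sum(w[keep] * M[keep]) / sum(w[keep])
  2^f
}

#' @rdname normalize_tpm
#' @export
normalize_tmm <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  mat <- counts$counts
  if (ncol(mat) < 2) abort_domain("TMM normalization needs at least two lanes")
  tot <- colSums(mat)
  if (any(tot <= 0)) abort_degenerate("lane with zero total count")
  # depth-scaled lanes: factors then reflect composition only
  cpm <- sweep(mat, 2, tot, "/") * 1e6
  uq <- apply(cpm, 2, stats::quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(mat)), function(j) {
    if (j == ref) return(1)
    tmm_scale_factor(cpm[, j], cpm[, ref], trim_M = trim_M, trim_A = trim_A)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  norm <- sweep(mat, 2, tot * f, "/") * 1e6
  new_normalization_result(counts, norm, f, "tmm")
}

#' @rdname normalize_tpm
#' @export
normalize_quantile <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  mat <- counts$counts
  if (ncol(mat) < 2) abort_domain("quantile normalization needs at least two lanes")
  sorted <- apply(mat, 2, sort)
  reference <- apply(sorted, 1, stats::median)
  norm <- apply(mat, 2, function(lane) {
    o <- order(lane)
    grp <- cumsum(c(TRUE, diff(lane[o]) != 0))
    vals <- stats::ave(reference, grp) # mean reference value over tied ranks
    out <- numeric(length(lane))
    out[o] <- vals
    out
  })
  dimnames(norm) <- dimnames(mat)
  new_normalization_result(counts, norm, NULL, "quantile")
}

#' Round a normalized matrix back to integer counts
#'
#' The homogeneity and differential-expression tests are defined on integer
#' counts; this rounds a normalized matrix to the nearest integer (halves
#' away from zero) and flags the result as integral.
#'
#' @param norm A `normalization_result` or a `count_matrix`.
#' @return An integer-valued [count_matrix()].
#' @export
round_counts <- function(norm) {
  cm <- if (inherits(norm, "normalization_result")) norm$normalized else norm
  stopifnot(inherits(cm, "count_matrix"))
  if (any(!is.finite(cm$counts)) || any(cm$counts < 0)) {
    abort_domain("matrix must be finite and non-negative")
  }
  rounded <- floor(cm$counts + 0.5) # half away from zero on non-negatives
  count_matrix(rounded, cm$condition, raw = TRUE)
}
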