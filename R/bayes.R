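#' Predictive law of one replicate count given the others
#'
#' Under the Poisson model with a uniform prior on the mean, the conditional
#' distribution of one held-out replicate count, given a pooled count `s`
#' over the other `m - 1` replicates of the same condition, is
#'
#'   P(X = k | s) = choose(s + k, k) * ((m-1)/m)^(s+1) * (1/m)^k,
#'
#' a negative binomial with size `s + 1` and success probability
#' `(m - 1)/m`. For `m = 2` this is the classical Audic-Claverie law of a
#' second library given a first; larger `m` generalizes it to conditions
#' sequenced in several technical replicates.
#'
#' @param s Pooled count over the conditioning replicates (non-negative
#'   integer).
#' @param m Total number of replicates including the predicted one
#'   (integer >= 2).
#' @return A `predictive_law` object with fields `s`, `m`, `size`, `prob`.
#' @examples
#' law <- predictive_law(s = 7, m = 2)
#' exp(log_predictive_pmf(law, 0:5))
#' @export
predictive_law <- function(s, m) {
  if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s < 0 || !is_whole(s)) {
    abort_domain("pooled prior count 's' must be a single non-negative integer")
  }
  if (!is.numeric(m) || length(m) != 1 || !is.finite(m) || m < 2 || !is_whole(m)) {
    abort_domain("replicate count 'm' must be an integer >= 2")
  }
  structure(list(s = s, m = m, size = s + 1, prob = (m - 1) / m),
            class = "predictive_law")
}

#' @export
print.predictive_law <- function(x, ...) {
  cat(sprintf(
    "predictive law: held-out replicate given pooled count s = %d over %d of %d replicates\n",
    x$s, x$m - 1, x$m))
  cat(sprintf("negative binomial (size = %d, prob = %g); mean = %g\n",
              x$size, x$prob, x$size * (1 - x$prob) / x$prob))
  invisible(x)
}

#' Log predictive probability of a held-out replicate count
#'
#' @param law A [predictive_law()].
#' @param x_next Non-negative integer count(s) for the held-out replicate.
#' @return Log probabilities (vectorized over `x_next`).
#' @export
log_predictive_pmf <- function(law, x_next) {
  stopifnot(inherits(law, "predictive_law"))
  if (any(!is.finite(x_next)) || any(x_next < 0) || any(!is_whole(x_next))) {
    abort_domain("'x_next' must contain non-negative integers")
  }
  stats::dnbinom(x_next, size = law$size, prob = law$prob, log = TRUE)
}

#' Acceptance interval of a predictive law
#'
#' Finds the integer interval holding at least `1 - 2 alpha` of the
#' predictive mass: `a` is the smallest integer whose cumulative predictive
#' mass reaches `alpha`, and `b` the largest integer whose upper-tail mass
#' `P(X >= b)` is still at least `alpha`. Both endpoints belong to the
#' acceptance region, so an observation is flagged only when it falls
#' strictly outside `[a, b]`, where each rejection tail carries less than
#' `alpha` probability. Used both for replicate-consistency checks
#' ([within_consistency()]) and for the pooled two-sample call
#' ([de_bayes()]).
#'
#' @inheritParams log_predictive_pmf
#' @param alpha Per-tail mass, in (0, 0.5).
#' @return An `acceptance_interval`: list with integers `a <= b`, `alpha`
#'   and the attained `coverage` P(a <= X <= b).
#' @examples
#' acceptance_interval(predictive_law(7, 2), alpha = 0.01)
#' @export
acceptance_interval <- function(law, alpha) {
  stopifnot(inherits(law, "predictive_law"))
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 0.5) {
    abort_domain("'alpha' must be a single number in (0, 0.5)")
  }
  size <- law$size
  prob <- law$prob
  a <- stats::qnbinom(alpha, size = size, prob = prob)
  # largest b with P(X >= b) >= alpha, i.e. P(X <= b - 1) <= 1 - alpha;
  # start above the (1 - alpha) quantile and walk down (ties included)
  b <- stats::qnbinom(1 - alpha, size = size, prob = prob) + 2
  while (b > a &&
         stats::pnbinom(b - 1, size = size, prob = prob) > 1 - alpha) {
    b <- b - 1
  }
  coverage <- stats::pnbinom(b, size = size, prob = prob) -
    (if (a > 0) stats::pnbinom(a - 1, size = size, prob = prob) else 0)
  structure(list(a = as.integer(a), b = as.integer(b), alpha = alpha,
                 coverage = coverage),
            class = "acceptance_interval")
}

#' @export
print.acceptance_interval <- function(x, ...) {
  cat(sprintf("acceptance interval [%d, %d], alpha = %g per tail (coverage %.4f)\n",
              x$a, x$b, x$alpha, x$coverage))
  invisible(x)
}

#' Replicate-consistency check by leave-one-out predictive intervals
#'
#' For each replicate p of one gene's counts, builds the predictive law
#' from the other m - 1 replicates (pooled count s = sum of the rest) and
#' checks whether the held-out count falls inside its acceptance interval.
#' The gene is declared consistent when every replicate passes, making the
#' verdict independent of replicate order.
#'
#' @param reps Non-negative integer vector of one gene's counts across the
#'   m >= 2 replicates of one condition.
#' @inheritParams acceptance_interval
#' @return A `within_consistency` object: list with logical `consistent`
#'   and a per-replicate data frame `detail` (replicate, value, s, a, b,
#'   pass).
#' @export
within_consistency <- function(reps, alpha = 0.01) {
  check_replicates(reps)
  m <- length(reps)
  if (m < 2) abort_domain("consistency check needs at least 2 replicates")
  detail <- do.call(rbind, lapply(seq_len(m), function(p) {
    s <- sum(reps[-p])
    iv <- acceptance_interval(predictive_law(s, m), alpha)
    data.frame(replicate = p, value = reps[p], s = s,
               a = iv$a, b = iv$b,
               pass = reps[p] >= iv$a & reps[p] <= iv$b)
  }))
  structure(list(consistent = all(detail$pass), detail = detail, alpha = alpha),
            class = "within_consistency")
}

#' @export
print.within_consistency <- function(x, ...) {
  cat(sprintf("replicate consistency at alpha = %g per tail: %s\n", x$alpha,
              if (x$consistent) "consistent" else "NOT consistent"))
  print(x$detail, row.names = FALSE)
  invisible(x)
}

#' Two-sample differential-expression call by the Bayesian method
#'
#' Treats the two pooled counts as a pair of replicates: the acceptance
#' interval of the two-replicate predictive law conditioned on the
#' condition-1 pooled count `x_pooled` is computed at per-tail mass `alpha`,
#' and the gene is called differentially expressed when the condition-2
#' pooled count falls outside it. The method requires equal replicate
#' numbers (m = n) so that the two pooled counts share the same Poisson
#' scale under the null.
#'
#' @param x_pooled,y_pooled Pooled non-negative integer counts for the two
#'   conditions.
#' @param m,n Replicate numbers per condition; must be equal.
#' @inheritParams acceptance_interval
#' @return A `bayes_de` object: list with logical `de`, the
#'   `acceptance_interval`, and the inputs.
#' @examples
#' de_bayes(3711, 2044, m = 2, n = 2, alpha = 0.01)  # outside: DE
#' de_bayes(7, 11, m = 2, n = 2, alpha = 0.01)       # inside: not DE
#' @export
de_bayes <- function(x_pooled, y_pooled, m, n, alpha = 0.01) {
  for (v in list(x_pooled, y_pooled)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || !is_whole(v)) {
      abort_domain("pooled counts must be single non-negative integers")
    }
  }
  if (m != n) {
    abort_unequal_reps(
      "the Bayesian method requires equal replicate numbers in the two conditions (m = n)")
  }
  iv <- acceptance_interval(predictive_law(x_pooled, 2), alpha)
  structure(
    list(de = y_pooled < iv$a || y_pooled > iv$b,
         interval = iv, x_pooled = x_pooled, y_pooled = y_pooled,
         m = m, n = n, alpha = alpha),
    class = "bayes_de")
}

#' @export
print.bayes_de <- function(x, ...) {
  cat(sprintf(
    "Bayesian two-sample call: x = %d, y = %d, interval [%d, %d] -> %s\n",
    x$x_pooled, x$y_pooled, x$interval$a, x$interval$b,
    if (x$de) "differentially expressed" else "not differentially expressed"))
  invisible(x)
}
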