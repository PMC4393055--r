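#' Design object for the synthetic Poisson count generator
#'
#' Describes a two-condition technical-replicate experiment under the same
#' model the tests assume: each gene g has a latent mean lambda_g drawn
#' log-uniformly from `[lambda_min, lambda_max]`, and the count in lane j is
#' Poisson with mean `lambda_g * size_factor_j`, times `fold` in condition-2
#' lanes for the spiked differentially expressed fraction.
#'
#' @param n_genes Number of genes.
#' @param m,n Technical replicates (lanes) in conditions 1 and 2.
#' @param lambda_min,lambda_max Range of the log-uniform law of per-gene
#'   means (defaults 5 and 5000, spanning weakly to strongly expressed
#'   genes on the read-count scale).
#' @param size_factors Positive per-lane library-size factors, length
#'   `m + n` (default all 1).
#' @param de_fraction Fraction of genes spiked as differentially expressed
#'   (default 0: a null dataset).
#' @param fold Fold change applied to condition-2 means of spiked genes.
#' @param seed Integer seed; all randomness is derived from it.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_genes, m = 2, n = 2,
                              lambda_min = 5, lambda_max = 5000,
                              size_factors = NULL,
                              de_fraction = 0, fold = 1, seed = 1) {
  if (n_genes < 1 || !is_whole(n_genes)) abort_domain("'n_genes' must be a positive integer")
  if (m < 1 || n < 1 || !is_whole(m) || !is_whole(n)) {
    abort_domain("'m' and 'n' must be positive integers")
  }
  if (lambda_min <= 0 || lambda_max < lambda_min) {
    abort_domain("need 0 < lambda_min <= lambda_max")
  }
  if (is.null(size_factors)) size_factors <- rep(1, m + n)
  if (length(size_factors) != m + n || any(size_factors <= 0)) {
    abort_domain("'size_factors' must be positive and of length m + n")
  }
  if (de_fraction < 0 || de_fraction > 1) abort_domain("'de_fraction' must be in [0, 1]")
  if (fold <= 0) abort_domain("'fold' must be positive")
  if (!is_whole(seed)) abort_domain("'seed' must be an integer")
  structure(
    list(n_genes = as.integer(n_genes), m = as.integer(m), n = as.integer(n),
         lambda_min = lambda_min, lambda_max = lambda_max,
         size_factors = size_factors, de_fraction = de_fraction,
         fold = fold, seed = as.integer(seed)),
    class = "simulation_design")
}

# Per-gene substream seed: a fixed affine map of (seed, gene index) modulo
# the Mersenne prime 2^31 - 1, so gene g's draws do not depend on how many
# genes the design has (adding genes never reshuffles existing ones).
gene_seed <- function(seed, g) {
  s <- as.numeric(seed) %% 2147483647
  # products stay below 2^53, so the double arithmetic is exact
  as.integer((s * 48271 + as.numeric(g) * 1299709) %% 2147483647)
}

#' Simulate a two-condition Poisson count matrix with known truth
#'
#' @param design A [simulation_design()].
#' @return List with `counts` (an integer [count_matrix()], lanes named
#'   `cond1_rep*` / `cond2_rep*`) and `truth` (data frame: gene_id, lambda,
#'   de, fold).
#' @examples
#' sim <- simulate_counts(simulation_design(100, seed = 42))
#' sim$counts
#' head(sim$truth)
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  g <- design$n_genes
  k <- design$m + design$n
  is_cond2 <- c(rep(FALSE, design$m), rep(TRUE, design$n))
  mat <- matrix(0L, nrow = g, ncol = k)
  lambda <- numeric(g)
  de <- logical(g)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (i in seq_len(g)) {
    set.seed(gene_seed(design$seed, i))
    lambda[i] <- exp(stats::runif(1, log(design$lambda_min), log(design$lambda_max)))
    de[i] <- stats::runif(1) < design$de_fraction
    mean_i <- lambda[i] * design$size_factors
    if (de[i]) mean_i[is_cond2] <- mean_i[is_cond2] * design$fold
    mat[i, ] <- stats::rpois(k, mean_i)
  }
  rownames(mat) <- sprintf("gene_%05d", seq_len(g))
  colnames(mat) <- c(sprintf("cond1_rep%d", seq_len(design$m)),
                     sprintf("cond2_rep%d", seq_len(design$n)))
  cond <- stats::setNames(ifelse(is_cond2, "cond2", "cond1"), colnames(mat))
  list(
    counts = count_matrix(mat, cond, raw = TRUE),
    truth = data.frame(gene_id = rownames(mat), lambda = lambda, de = de,
                       fold = ifelse(de, design$fold, 1),
                       stringsAsFactors = FALSE))
}

#' Empirical type-I error of the tests on simulated null data
#'
#' Simulates a null dataset (the design must have `de_fraction = 0`), runs
#' the chosen test on every gene, and reports the fraction of genes
#' rejected at each level together with its Monte-Carlo standard error.
#' For a well-calibrated test the rate tracks the level.
#'
#' @param design A [simulation_design()] with `de_fraction = 0`.
#' @param levels Significance levels (LRT) or per-tail masses (Bayes).
#' @param method `"lrt"` or `"bayes"` (the latter needs `m == n`).
#' @return Data frame: level, rejection_rate, mc_se, n_genes.
#' @export
type1_experiment <- function(design, levels = c(0.01, 0.025, 0.05, 0.10),
                             method = c("lrt", "bayes")) {
  stopifnot(inherits(design, "simulation_design"))
  method <- match.arg(method)
  if (design$de_fraction != 0) {
    abort_domain("type-I experiment requires a null design (de_fraction = 0)")
  }
  for (l in levels) check_level(l)
  sim <- simulate_counts(design)
  pooled <- pool_by_condition(sim$counts)
  rate <- if (method == "lrt") {
    p <- stats::pchisq(-2 * loglam3_vec(pooled$x, pooled$m, pooled$y, pooled$n),
                       df = 1, lower.tail = FALSE)
    vapply(levels, function(l) mean(p <= l), numeric(1))
  } else {
    if (pooled$m != pooled$n) {
      abort_unequal_reps("Bayesian method needs m = n replicates")
    }
    vapply(levels, function(l) {
      ab <- interval_table(pooled$x, l)
      mean(pooled$y < ab[, "a"] | pooled$y > ab[, "b"])
    }, numeric(1))
  }
  data.frame(level = levels,
             rejection_rate = rate,
             mc_se = sqrt(rate * (1 - rate) / design$n_genes),
             n_genes = design$n_genes)
}
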