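---
title: "Poisson models for RNA-Seq differential expression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson models for RNA-Seq differential expression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poisde)
```

## The model

A gene's read count in one sequencing lane is treated as Poisson: the reads
of any single gene are a small fraction of the lane total, so the binomial
sampling of reads onto genes is well approximated by independent Poisson
draws. For a gene with counts $x_1,\dots,x_m$ over the $m$ technical
replicates of one condition, replicate $j$ has its own mean $\lambda_j$;
technical consistency is the hypothesis $\lambda_1=\dots=\lambda_m$.
Between two conditions the pooled counts $x=\sum_j x_j$ and $y=\sum_j y_j$
are independent Poisson with means $m\lambda$ and $n\mu$, and differential
expression is $\lambda \neq \mu$.

Everything downstream inherits the model's central limitation: a Poisson
count has variance equal to its mean. Biological replicates — and even some
technical protocols — are overdispersed relative to that, which is why
negative-binomial methods exist. The tests here are tests of *technical*
variation and of differential expression *given* near-Poisson behaviour;
applied to overdispersed data they will reject too often. This is a scope
decision, not an oversight: the package models technical replication, and
the simulator (below) generates exactly the data the model describes, so
calibration results on simulated data certify internal consistency, not
robustness to overdispersion.

## The likelihood-ratio method

The within-condition statistic compares the likelihood maximized under a
common mean ($\hat\lambda = x/m$) with the unrestricted maximum
($\hat\lambda_j = x_j$):

$$\log \Lambda_1 = \sum_j x_j\,\bigl(\log(x/m) - \log x_j\bigr), \qquad
  0\log 0 := 0 .$$

The two-condition statistic profiles the shared mean
$(x+y)/(m+n)$ against the per-condition estimates $x/m$, $y/n$:

$$\log \Lambda_3 = x\bigl(\log e_x - \log x\bigr) +
                   y\bigl(\log e_y - \log y\bigr),\qquad
  e_x = \tfrac{(x+y)m}{m+n},\; e_y = \tfrac{(x+y)n}{m+n}.$$

**Calibration.** The statistics are referred to $\chi^2$ distributions via
Wilks' theorem: $-2\log\Lambda_1 \sim \chi^2_{m-1}$,
$-2\log\Lambda_3 \sim \chi^2_1$. This is an asymptotic choice and the one
standard for Poisson likelihood ratios; an exact conditional (binomial)
calibration would be an alternative at very small counts, and is out of
scope here. Simulated-null tests in the suite confirm the empirical
rejection rate tracks the nominal level to within Monte-Carlo error for
means of 20 and above; below that, the $\chi^2$ tail is mildly distorted by
discreteness, which is one reason the workflow's presence filter (below)
exists.

**Numerical form.** Both statistics are computed as differences of
logarithms of *identical* quantities whenever the null fits perfectly: when
all replicate counts are equal, and when $x/m = y/n$ (in which case $e_x$
equals $x$ exactly — the products involved are integer-divisible, so even
the floating-point division is exact). Equal-mean inputs therefore give
$\log\Lambda = 0$ and $p = 1$ *exactly*, not merely to rounding; a final
clamp to $\log\Lambda \le 0$ removes any residual positive rounding dust in
non-degenerate cases. Multiple-testing correction is off by default — the
levels reported by the screens are raw, per-gene levels — with
Benjamini–Hochberg available via `de_lrt(..., adjust = "BH")`.

## The Bayesian predictive method

With a uniform prior on the Poisson mean, the posterior after observing a
pooled count $s$ over $k$ replicates is Gamma($s+1$, rate $k$), and the
predictive law of one further replicate is negative binomial:

$$P(X = x \mid s) = \binom{s+x}{x}\Bigl(\frac{m-1}{m}\Bigr)^{s+1}
                    \Bigl(\frac{1}{m}\Bigr)^{x},$$

where $m$ counts all replicates including the predicted one. The package
evaluates this through `stats::dnbinom`/`pnbinom`/`qnbinom` (log-gamma
arithmetic and the incomplete-beta CDF internally); the test suite
independently re-derives the same numbers from the joint chain form
$\bigl(\sum x_i\bigr)!\,/\,\bigl(\prod x_i!\; m^{\sum x_i + 1}\bigr)$
to $10^{-10}$ relative accuracy.

**Acceptance interval.** For per-tail mass $\alpha$ the interval is
$[a, b]$ with

* $a$ = smallest integer whose cumulative predictive mass reaches $\alpha$,
* $b$ = largest integer whose upper-tail mass $P(X \ge b)$ is still at
  least $\alpha$,

both endpoints *inside* the acceptance region. Each rejection tail
($X < a$, $X > b$) then carries strictly less than $\alpha$, so coverage is
at least $1 - 2\alpha$ — verified by exhaustive summation in the suite. On a
discrete distribution there is no unique pair of integers "cutting exactly
$\alpha$"; neighbouring conventions (excluding the boundary point, or
splitting the level differently across tails) shift either endpoint by a
few counts at small $s$. The convention above is symmetric between the two
tails and conservative (never under-covers); published small-count interval
tables built with any of the neighbouring conventions agree with it to
within about three counts per endpoint, and the resulting accept/reject
calls are far less sensitive than the endpoints themselves.

**"1% level".** Significance levels are interpreted as per-tail mass:
$\alpha = 0.01$ gives a $1-2\alpha = 98\%$ acceptance interval. This is an
interpretation (the alternative, $\alpha = 0.005$ per tail for a 99%
interval, produces visibly wider intervals at all counts) and is recorded
here rather than asserted as the only reading.

**Replicate consistency** (`within_consistency`) runs a leave-one-out
sweep: every replicate is held out once and checked against the interval
built from the remaining $m-1$. A single described check of "the last"
replicate would depend on replicate ordering, which is arbitrary for
technical lanes; the sweep is order-invariant, and a gene passes only if
every replicate does.

**Two-sample call** (`de_bayes`): the two pooled counts are treated as a
two-replicate pair, requiring $m = n$ — under the null both are Poisson
with the same mean $m\lambda$ only when the replicate numbers match. The
likelihood-ratio route has no such restriction and is the fallback for
unbalanced designs.

## Normalizations

* **TPM** (`normalize_tpm`): counts scaled so each lane sums to $10^6$.
  This is total-count scaling (no transcript-length adjustment — the
  historical usage for count matrices). Reported scale factor: lane total
  in millions (the divisor).
* **TMM** (`normalize_tmm`): per-lane composition factors from a doubly
  trimmed, weighted mean of per-gene log2 ratios against a reference lane.
  Defaults: trim 30% from each tail of the M (log-ratio) ranking, 5% from
  each tail of the A (average log-abundance) ranking, precision weights
  from the binomial (delta-method) variance of M, reference lane the one
  whose upper quartile is closest to the mean upper quartile — the
  canonical choices for this estimator. Genes zero in either lane are
  dropped before trimming. Factors are rescaled to geometric mean 1 and
  applied as divisors together with library size, on a counts-per-million
  scale. The depth scaling happens *before* the trimmed mean, so the factor
  reflects composition only; the exported primitive `tmm_scale_factor`
  operates on the vectors as given (raw ratio), which is why a lane exactly
  doubled elementwise has factor 2 from the primitive but factor 1 from the
  full normalization. Our weighting differs from edgeR's
  `calcNormFactors` in using depth-scaled counts in the weight formula;
  on simulated data the factors agree within a fraction of a percent, and
  a suite test pins that agreement at 1%.
* **Quantile** (`normalize_quantile`): each lane's value is replaced by the
  reference value at its within-lane rank, where the reference at rank $r$
  is the *median* across lanes of the $r$-th smallest values. Ties within a
  lane get the mean of their tied ranks' reference values — deterministic
  and symmetric, at the cost that tied entries collapse to a common mean,
  so lanes share an exactly identical multiset only when they are
  tie-free. (The common mean-based variant differs only in using the mean
  instead of the median for the reference.)
* **Rounding** (`round_counts`): both tests are defined on integers, so
  normalized matrices are rounded half-away-from-zero before testing. The
  alternative (testing on reals via continuous gamma analogues) changes the
  methods themselves and was rejected.

## The gene-category workflow

Pooled counts put each gene in one of three strata: (1) zero in both
conditions — untestable; (2) zero in one condition and at least
`present_min` reads in the other — called DE *by absence*, without a test,
since absence of an expressed gene is itself the signal (a flag can route
these through the tests instead); (3) at least `present_min` in both —
tested. The default `present_min = 5` reflects the usual "reliable
detection" cut for count data. Pairs fitting none of the strata (a positive
count below `present_min` on either side) are reported as *indeterminate*
and excluded from testing rather than silently pushed into a stratum —
silent reclassification would distort the tested-gene denominator. Fold
changes are $\log_2\bigl((x/m + 0.5)/(y/n + 0.5)\bigr)$; the 0.5
pseudo-count keeps category-2 folds finite and is a package choice, stated
here because several conventions circulate.

`expression_strength_summary` histograms $\log_{10}(1 + \text{mean count})$
for all genes and for a significant list on shared bins (proportions per
bin). A sound method's significant list roughly follows the overall
strength distribution; a method whose list is flat across strengths is
reflecting its error model, not the biology.

## The simulator

`simulate_counts` draws per-gene means $\lambda_g$ log-uniformly on
$[\lambda_{\min}, \lambda_{\max}]$ (default $[5, 5000]$, spanning weak to
strong expression on the read-count scale) and counts
$x_{gj} \sim \text{Poisson}(\lambda_g \cdot s_j)$ with per-lane size
factors $s_j$ (default 1); a `de_fraction` of genes has its condition-2
mean multiplied by `fold`. Each gene draws from its own substream, seeded
by a fixed affine map of (seed, gene index) modulo $2^{31}-1$, so enlarging
a design never reshuffles the genes already present, and the caller's
random stream is left untouched.

What it emulates: Poisson technical replicates, library-size differences,
spiked fold changes with known truth. What it does not: overdispersion,
RNA-composition bias (a handful of very abundant genes dragging library
totals), gene-length effects, zero-inflation. Passing calibration tests on
this generator therefore demonstrates that the implementations match their
own model assumptions — not that the methods are robust on biological
replicates.

**Problem sizes.** The suite's calibration runs use 10,000 null genes with
$\lambda$ log-uniform on $[20, 2000]$ for the likelihood-ratio type-I check
(2 vs 2 lanes), 10,000 replicate pairs at $\lambda \in \{10, 100, 1000\}$
for predictive-interval coverage, and 4,000–5,000 genes for the
homogeneity-screen patterns. These sizes give Monte-Carlo standard errors
of about 0.1% on a 1% rate, comfortably inside the asserted bands, while
keeping the whole suite fast enough to run habitually.

## Degenerate inputs and numerical conventions

* $0\log 0 = 0$ and $0^0 = 1$ throughout: both statistics are continuous
  limits at zero counts; an all-zero gene yields $\Lambda = 1$, $p = 1$,
  and (in the workflow) category 1.
* All-zero *lanes* are an error for TPM/TMM (their scale is undefined), not
  silently patched.
* TMM requires at least two genes to survive trimming; fewer is a classed
  error (`poisde_insufficient_genes_error`) rather than a fallback factor.
* Acceptance intervals always satisfy $a \le b$; the predictive median lies
  inside by construction.
* Equal pooled counts are never called DE by either method, at any level.
* File round-trips are bit-exact: doubles are written with the shortest
  decimal representation that re-reads to the same value.

## Interfaces

Every operation is an ordinary function on an S3 `count_matrix`; the CLI
(`inst/cli/poisde`, or `poisde_main()` from R) is a thin adapter that
parses flags, calls the same functions, and exits 0/1/2 for
success/domain-failure/usage-error. Levels are accepted as decimals only —
`--level 1` is rejected with a pointer to `0.01`, since mixing percent and
decimal conventions is the classic way to run a screen at the wrong level.

## Known limitations

Equidispersion (see above); $m = n$ for the Bayesian two-sample call;
$\chi^2$ asymptotics at very small counts; no length or GC correction (the
package operates strictly downstream of counting); the quantile reference
needs at least two lanes and inherits the usual caveat that it erases
global distributional differences, biological or not.
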