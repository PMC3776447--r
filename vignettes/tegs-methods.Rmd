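---
title: "Gene set testing with working covariances: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene set testing with working covariances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tegs)
```

## The model and its assumptions

A gene set analysis asks whether a phenotype `x` (binary group membership or
a numeric exposure) is associated with the joint expression profile of a
named group of genes. `tegs` works under the multivariate linear model

$$Y_{ij} = \alpha_j + x_i \beta_j + \varepsilon_{ij}, \qquad
  \varepsilon_i \sim \mathrm{MVN}(0, \Sigma),$$

for subjects $i = 1, \dots, n$ and genes $j = 1, \dots, p$, with errors
independent across subjects but correlated across genes through the unknown
$\Sigma$. The null hypothesis is self-contained: $\beta = 0$, i.e. no gene in
the set is associated with the phenotype, judged without reference to genes
outside the set. (This is a different question from competitive enrichment,
which compares a set against the rest of the genome; the two are not
interchangeable and their powers are not directly comparable.)

A $p$-degree-of-freedom multivariate test loses power quickly as $p$ grows.
Instead, the $\beta_j$ are treated as draws from a common distribution with
mean 0 and variance $\tau$, so $\beta = 0$ collapses to the one-dimensional
variance-component hypothesis $\tau = 0$. The score statistic for $\tau$
under a *working* covariance $V$ for the errors reduces, after profiling out
the intercepts (whose null MLE is the plain sample mean whatever covariance
is assumed), to

$$Q = \lVert V^{-1} t \rVert^2, \qquad
  t = \sum_i (x_i - \bar{x})\,(Y_i - \bar{Y}).$$

The implementation never forms the stacked $np \times np$ design; the
$p$-dimensional reduction above is algebraically identical (the test suite
verifies this against literal stacked-matrix evaluation on every small
instance) and costs $O(p^3 + np^2)$ per evaluation. For a binary phenotype
$Q = (n_1 n_2/n)^2\, d^\top V^{-2} d$ with $d$ the difference of the group
mean profiles. With $V = I$, $Q$ is the global test statistic of Goeman et
al. (2004), equivalently SKAT with a linear kernel; the package exposes this
as `global_test_statistic()` and verifies the equivalence to $10^{-12}$.

Under the null, $Q$ is a mixture of chi-squares
$\sum_j \lambda_j \chi^2_{1,j}$, with $\lambda_j$ the eigenvalues of
$c\,V^{-1}\Sigma V^{-1}$, where $c = \sum_i (x_i - \bar x)^2$ is the exact
finite-sample scale of $t$ for the statistic as defined ($c = n_1 n_2/n$ for
binary designs). Their sum equals $E_{H_0}(Q) = \mathrm{tr}(c\,V^{-2}\Sigma)$
— an identity the tests assert to $10^{-8}$.

## The working covariance menu

$V$ trades efficiency against estimability: validity never depends on getting
it right (the permutation null conditions on the data), but power improves as
$V$ approaches $\Sigma$. Estimation starts from the per-gene OLS residuals of
`Y ~ 1 + x` (exactly group-mean centering for binary `x`):

* `indpt` — identity; the global test. No estimation.
* `unstr` — the residual sample covariance (divisor $n-1$) plus a ridge: the
  5th percentile of the gene-wise sample variances added to the diagonal.
  The ridge keeps the estimator positive definite even when $p \ge n$, the
  regime gene sets live in.
* `cpsym` — exchangeable: common covariance = mean off-diagonal of the ridge
  estimator, common variance = mean diagonal.
* `f2`, `f-adpt` — factor-analysis structures from the eigendecomposition of
  the ridge estimator: keep the top $k$ eigencomponents ($k = 2$, or for
  `f-adpt` the smallest $k$ reaching 80% of total variance, capped at
  $\min(p, n-1)$, the rank of the residual covariance), then restore the
  input diagonal with a gene-specific uniqueness term.
* `supplied` — any positive definite matrix (a known covariance, or one
  estimated from pilot data).

Numerical details that matter and are deliberate:

* **Percentile definition.** Linear interpolation between order statistics
  (R's type 7), inclusive endpoints. For $p = 1$ the "5th percentile of one
  variance" is that variance.
* **Covariance divisor.** $n - 1$ on residuals, with no per-gene
  degrees-of-freedom correction for the fitted slope; the ridge term
  dominates stabilization and the statistic's p-values are invariant to any
  common rescaling of $V$.
* **Compound symmetry diagonal.** Only the common covariance is prescribed
  by the construction; the diagonal uses the mean ridge variance, making the
  result exactly exchangeable (two distinct eigenvalues). Keeping gene-wise
  variances instead would break exchangeability; that variant is not
  exposed.
* **Factor truncation.** Eigendecomposition of a symmetric PSD matrix equals
  its SVD; components are ordered by decreasing eigenvalue with ties broken
  by index, and eigenvector sign is irrelevant (outer products). Truncation
  inflates retained off-diagonals slightly — for a rank-1-plus-diagonal
  input $aa^\top + dI$, the kept component is $(\lVert a\rVert^2 + d)
  aa^\top / \lVert a \rVert^2$ — which is inherent to spectral truncation
  with diagonal restoration, not an implementation artifact.
* **Uniqueness floor.** The diagonal-restoring term is floored at $10^{-8}$
  of the mean diagonal so a gene fully captured by the factors cannot make
  the estimate singular.

## Null distribution machinery

**Permutation.** The phenotype labels are permuted; for every permutation the
residuals and the working covariance are re-estimated from the permuted
pairing, because $V$ is a covariance *conditional on* `x`. The p-value is
$(1 + \#\{Q^{(b)} \ge Q_{\mathrm{obs}}\})/(B+1)$ — the convention that counts
the observed statistic, guarantees validity, and never returns 0. Ties count
as exceedances (conservative). The re-estimation loop is the computational
bottleneck and is implemented in compiled code (RcppArmadillo); the test
suite pins the compiled path to the composed R estimators column by column.
A permutation whose covariance estimation fails is retried with a fresh
draw; more than 1% failures aborts the run. All randomness flows from the
user's seed.

**Satterthwaite scaled chi-square.** $\kappa = \mathrm{Var}(Q)/2E(Q)$ and
$\nu = 2E(Q)^2/\mathrm{Var}(Q)$ from the permutation sample moments give a
$\kappa\chi^2_\nu$ null whose tail extends far below $1/B$. The calibration
caveat is real and reproduced by the acceptance tests: at nominal levels of
$5\times 10^{-3}$ and below the scaled chi-square tail rejects more often
than permutation under the null, so extreme Satterthwaite p-values should be
treated as anti-conservative.

**Normal mixture refinement.** The probits of the per-permutation
Satterthwaite p-values (each computed from the single $(\kappa, \nu)$ fit to
all $B$ draws — one fit, reused, rather than leave-one-out) are modelled by
a two-component normal mixture fitted by EM; the reported p-value is the
lower-tail mixture probability at the probit of the observed Satterthwaite
p-value (small p-values map to very negative probits — the one-sided
direction is implied by the tail being refined). p-values are clamped to
$[1/(10B), 1 - 1/(10B)]$ before the probit. EM uses a median-split
initialization plus 10 random restarts, a $10^{-6}$ variance floor, and runs
until the log-likelihood improves by less than $10^{-8}$; the iteration cap
is 10,000 because the two components are weakly separated on probit-normal
data and EM typically needs a few thousand iterations to meet that
tolerance — a 500-iteration cap would make the (single-normal) fallback the
common path. If no restart converges the fitter falls back to a single
normal with a warning.

**q-values.** Storey's estimator with $\hat\pi_0$ at $\lambda = 0.5$,
floored at $1/m$ so tiny collections cannot report an FDR of exactly zero;
$\hat\pi_0 = 1$ (or `method = "bh"`) reproduces Benjamini–Hochberg exactly.

## Power calculations

Design-stage power uses the theoretical moments
$E_{H_0}(Q) = \mathrm{tr}(M)$, $\mathrm{Var}_{H_0}(Q) = 2\,\mathrm{tr}(M^2)$
for $M = c\,V^{-1}\Sigma V^{-1}$, and
$E_{H_A}(Q) = E_{H_0}(Q) + c^2 \beta^\top V^{-2}\beta$; matching
$E_{H_A}(Q) = (\nu + \delta)\kappa$ gives the noncentrality $\delta$ (floored
at 0 against floating-point undershoot), and power is the upper tail of
$\chi^2_\nu(\delta)$ beyond the central $1-\alpha$ quantile. At $\beta = 0$
this returns exactly $\alpha$. `power_curve()` sweeps effect scalings and
sample sizes; $\Sigma$ and $V$ can be estimated from pilot data via the
covariance module.

Two calibration gaps are documented rather than hidden. First, the testing
procedure estimates $(\kappa, \nu)$ by permutation while the power formula
uses theoretical moments; on fixed data the permutation moments converge to
quantities that differ from the theoretical ones by data-sampling error
(noticeable at $n$ in the dozens). Second, the scaled noncentral chi-square
is a two-moment approximation to a mixture of noncentral chi-squares: in the
test suite's strongly-correlated design (exchangeable correlation 0.5) it is
essentially exact at small effects but a few percentage points optimistic in
the mid-power range; the acceptance check is run where the approximation is
sharp and the mid-power gap is bounded separately at 0.06.

## The synthetic-data generators

The simulation harness emulates two-group expression studies with known
truth: multivariate normal errors with compound-symmetry (`make_cov_cs`),
AR1 (`make_cov_ar1`), random two-factor (`make_cov_twofactor`, unit
diagonal, factors carrying half the variance by default, uniqueness floored
at 0.05), or a synthetic "unstructured" covariance built like a
ridge-stabilized sample covariance of 34 pseudo-samples from a
heterogeneous-variance factor model (`make_cov_unstructured_fixture` — a
seeded stand-in for covariances estimated from real cohorts, which are not
shipped). Effects are sparse signed blocks (`make_beta`) placed at the
leading genes; the test is equivariant to gene order, so placement is
immaterial and fixed placement eases debugging. The effect-size index
reported with experiment tables is $\sum_j |\beta_j| / \bar{\sigma}^2$ (the
sum of absolute effects over the mean true gene variance); a signed sum
would vanish for the balanced ± layouts the designs use.

The multi-set designs build 20 sets (ten of 10 genes, ten of 40; eight under
the alternative; 104 signal genes in total) with two-factor covariance
within each set; optionally, blocks of three sets share one two-factor
structure (cross-set correlation), and 4500 independent unit-variance null
genes can be appended to mimic genome-scale data. Because the off-set genes
are generated after the in-set genes, the same seed yields identical in-set
data with and without them — which is how the tests demonstrate the
self-contained-null property: per-set p-values are bit-identical when the
genome grows tenfold.

What the generators do *not* emulate: heavy-tailed or skewed expression,
mean–variance coupling, batch effects, and missingness. Passing tests
therefore certify the statistic's operating characteristics under the
multivariate normal model, not robustness to real-data artifacts;
rank-transforming or variance-stabilizing real inputs remains the user's
responsibility.

Default experiment sizes (2000 replicates for size, 500–1000 for power,
B = 500) keep a full calibration cell in the low minutes on one CPU and are
the sizes the bundled acceptance checks use; all are overridable.

## Interfaces and conventions

Expression is samples-by-rows internally; the GCT reader transposes on
ingestion. Each probe is treated as a distinct outcome (no collapsing of
probes mapping to one symbol). Sets are filtered to measured genes with a
default minimum size of 4. Binary phenotypes need at least two samples per
group; `tegs_run()` gives every set its own deterministic permutation stream
derived from the seed, so a set's p-value never depends on which other sets
are analyzed. Covariates can be regressed out gene-by-gene beforehand with
`adjust_for_covariates()` (ridge, intercept unpenalized — needed when $p$
approaches $n$). The thin command-line wrapper (`inst/cli/tegs.R`) mirrors
every flag in a `key=value` config file, command line winning.

## Known limitations

* Two phenotype classes only (or one numeric exposure); no multi-class
  designs.
* For $n$ in the hundreds, permutation is wasteful — a large-sample Monte
  Carlo null would be cheaper; not implemented here.
* The Satterthwaite tail is anti-conservative at extreme nominal levels
  (reproduced in the acceptance tests); prefer the permutation or mixture
  p-value when the decision threshold is far below $10^{-2}$.
* Analytic power inherits the two-moment approximation error described
  above; treat mid-power estimates as optimistic by up to a few points in
  strongly correlated designs.
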