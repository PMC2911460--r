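---
title: "Modeling expression heterogeneity with latent factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling expression heterogeneity with latent factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadex)
```

## The model

Let $Y$ be an $m \times n$ matrix of log-scale expression measurements
(genes by samples) and $x$ the covariate of interest (a phenotype, a
treatment, a group label). Per-gene significance analysis treats the $m$
tests as if they were independent, but expression data carry structured
variation — batch-like sample groupings, array geometry, probe chemistry,
uncontrolled biology — that correlates the tests and inflates the variance
of the number of false discoveries far beyond its independent-data value.

fadex models the covariance of the expressions, *conditional on* $x$, as

$$\Sigma \;=\; \Psi + B B',$$

where $\Psi$ is diagonal ($m$ gene-specific "uniquenesses") and $B$ is an
$m \times q$ matrix of loadings on $q \ll m$ latent factors. Equivalently,
for gene $k$,

$$y_k = \mu_k + \beta_k x + b_k Z' + \varepsilon_k,$$

with factor scores $Z$ ($n \times q$, unit-variance and independent of
$x$ by construction) and independent noise
$\varepsilon_k \sim N(0, \psi_k)$. Genes are conditionally independent
given the factors: everything the genes share beyond the design is
concentrated in $Z$. Subtracting the fitted common component gives the
*factor-adjusted* data

$$\tilde Y = Y - \hat B \hat Z',$$

which keeps the $x$-effect (the factors were fitted on $x$-residualized
data) but sheds the dependence. Downstream per-gene tests on $\tilde Y$
are closer to independent, which both stabilizes the false-discovery count
and unmasks genes whose association with $x$ was drowned by
heterogeneity.

The assumptions worth keeping in mind: effects are additive on the
(log) expression scale; the heterogeneity is low-rank (a handful of
sample-level influences, each touching many genes); and the factors are
independent of $x$. An unmeasured variable *correlated* with $x$ violates
the last assumption and will be partly absorbed into $\beta$, not into the
factors — this is a feature for inference on $x$, but it means the factors
cannot rescue a confounded design.

## Fitting: EM on residualized data

`residualize()` removes the $x$-effect gene by gene (ordinary least
squares on an intercept plus $x$, categorical covariates expanded to
indicators) and records the residual degrees of freedom
$d = n - \operatorname{rank}(X)$. `fit_em()` then runs the standard
Gaussian factor-analysis EM on the residuals:

* **E-step** — posterior moments of $Z$ given the data and the current
  $(B, \Psi)$, via the $q \times q$ system
  $G = (I_q + B'\Psi^{-1}B)^{-1}$; all computations stay in
  $O(mnq)$ per iteration and never form an $m \times m$ matrix.
* **M-step** — closed-form update of $B$ and of the diagonal of $\Psi$.

Numerical choices:

* **Initialization** is a principal-axis start: $B^{(0)}$ from the top-$q$
  SVD of the row-centered residuals scaled by the singular values, and
  $\psi^{(0)}$ the residual variances minus the initial communalities.
  This starts EM inside the basin of the dominant structure and typically
  converges in a handful of iterations.
* **Heywood guard** — every M-step floors $\psi_k$ at $10^{-4}$ times the
  gene's residual variance. Without it, genes whose variance is almost
  fully common drive $\psi_k \to 0$ and destabilize $\Psi^{-1}$.
* **Convergence** — relative log-likelihood change below `tol` (default
  $10^{-6}$); the trace is stored and is non-decreasing (EM monotonicity),
  which the test suite asserts across random datasets.
* **Degenerate genes** (zero residual variance) are excluded from the
  fit, reported in the `excluded` field, given zero loadings, and pass
  through adjustment unchanged.
* **Scores** are posterior means under the final parameters; they are
  shrunken (their sampling variance is $G$), which is the right scale for
  the adjustment $\hat B \hat Z'$.

## How many factors?

Too few factors leave dependence in the data; too many overfit and eat
genuine signal. The selection criterion targets exactly what dependence
breaks — the variance of the false-discovery count, which grows with the
sum of squared pairwise correlations between test statistics. For each
candidate $q$, `select_nbfactors()` fits the model, forms the
factor-adjusted residuals, and computes the mean squared off-diagonal
sample correlation

$$\mathrm{VI}(q) = \frac{1}{m(m-1)} \sum_{i \neq j} \hat r_{ij}^2 .$$

This is computed *exactly* for any $m$ in $O(mn^2)$: with unit-normalized
centered rows $X$, $\sum_{ij} \hat r_{ij}^2 = \lVert X'X \rVert_F^2$, an
$n \times n$ computation.

A subtlety matters at small $n$: under full independence the expected
value of $\mathrm{VI}(q)$ is not zero but $1/(d-q)$, because residuals
confined to a $(d-q)$-dimensional sample space (after removing the design
and $q$ fitted factors) are spuriously correlated at exactly that level.
The raw criterion therefore *increases* mechanically with $q$, and its
argmin systematically misses factors that touch only a modest share of the
genes. fadex centers the criterion at this null level and selects the
smallest $q$ whose centered value is at most `tau` — i.e. the smallest
model whose adjusted residuals are statistically indistinguishable from
independent — falling back to the argmin if no candidate qualifies.

The default `tau = 5e-4` is a fixed scale choice, not a fitted quantity:
across the design sizes this package targets (residual df at least ~12,
at least a few hundred genes), the null fluctuation of the centered
criterion sits well under $2.5\times 10^{-4}$ while a single unmodeled
grouping variable touching even ~10% of the genes contributes upwards of
$10^{-3}$. Both margins can be inspected via the returned
`criterion_centered` profile, and `tau` is exposed as an argument.

## Rotation and interpretation conventions

The likelihood fixes only the span of $B$; any orthogonal rotation of
$(B, Z)$ fits equally well. `varimax_rotate()` applies the VARIMAX
criterion (maximal variance of squared row-normalized loadings, Kaiser
normalization) so each factor concentrates on few genes, then applies two
conventions so results are comparable across runs: factors are ordered by
decreasing sum of squared loadings, and each factor's sign is set so its
largest-|loading| gene loads positively. $BB'$, the communalities and the
fitted likelihood are unchanged — only the labeling of the common space.

`factor_sample_association()` relates scores to external sample variables
(hatch, dam, weight, ...): an analysis-of-variance F-test across the
levels of a categorical variable, the correlation t-test for a continuous
one, both as the partial F-test of the variable in a linear model for the
scores. By default the model also contains the covariate of interest the
factors were conditioned on. The reason is structural: the scores are
linear functionals of $x$-residualized data, so when an external variable
is (by finite-sample chance) unbalanced across $x$, its residualized
pattern takes distinct values in each design cell and a *marginal*
one-way test mixes design imbalance into the within-group variance,
deflating the association for genuinely related variables. Testing the
variable *given* $x$ measures association on the same conditional scale
on which the factors are defined. `adjust_for = NULL` restores the plain
one-way test. Per-level Student t-tests (level versus rest) accompany
every categorical variable; levels with fewer than two samples are
omitted and flagged.

`factor_gene_association()` applies the identical engine to the loading
columns against gene features (oligonucleotide size, array block, row,
column). A numeric feature with at least 10 distinct values is treated as
continuous, otherwise as categorical — an explicit, testable rule. The
rotated loadings are used: rotation is part of the declared output.

`top_genes()` ranks genes by the correlation-scale loading
$\lambda_{jk} = b_{jk} / \sqrt{b_j b_j' + \psi_j}$, the model correlation
between gene and factor, bounded by 1. This is the only scale on which a
fixed cutoff (default 0.8) means the same thing for every gene; a raw
loading cutoff would conflate loading size with gene variance.

`pca_project()` provides the sample map used to contrast raw and adjusted
data (row-centered genes, samples scored on the top components, sign fixed
by the largest-coefficient gene).

## Enrichment

`enrich_table()` runs one exact upper-tail hypergeometric test per term:
the probability that at least $k$ of the $n$ list genes are annotated,
given $K$ annotated genes among the $N$ background genes. The background
defaults to all genes on the array — the choice of background is the
single most consequential parameter of enrichment analysis, and printed
p-values from different annotation sources are often consistent only with
slightly different effective backgrounds, so it is overridable. No
multiplicity correction is applied to the enrichment flag by default
(matching the raw-cutoff convention of the workflow); Benjamini–Hochberg
is available behind a flag.

## The synthetic study designs

`simulate_case()` generates the three illustrative scenarios used
throughout the tests: 1000 genes on 20 arrays of i.i.d. standard normal
noise, two equal primary groups with a constant `de_effect` on genes
1–100, and one or two independent grouping variables each adding
`het_effect` to 7 uniformly chosen arrays — on all genes (case 1), genes
70–170 (case 2), or genes 70–170 and 171–271 (case 3). Conventions the
generator fixes: the primary split is deterministic (first half versus
second half); the 7-sample sets are drawn independently per variable, so
the two case-3 sets may overlap; gene windows are 1-based inclusive.

The effect magnitudes are design constants of the study, not tuning
knobs: `de_effect = 1` gives per-gene power around one half at $n = 20$
(so raw and adjusted analyses visibly differ), and `het_effect = 2` — two
noise standard deviations — makes each heterogeneity variable a clearly
detectable factor at these sizes. Both are exposed as parameters.

`simulate_factor_model()` draws data exactly from the factor model with
known $(B, Z, \Psi)$ for parameter-recovery tests ("block" disjoint
supports or "dense" Gaussian loadings).

What these generators do *not* emulate: probe-level artifacts,
normalization residue, heavy-tailed or heteroscedastic noise, factors
correlated with the design, or annotation structure. Passing tests on
them demonstrates that the estimator does what it claims under its own
assumptions — not that those assumptions hold for any particular array
experiment.

## What the method cannot promise

* **Factor-score precision is information-limited.** The sampling noise
  of a factor's scores scales like $(1 + \sum_k b_k^2/\psi_k)^{-1/2}$: a
  factor supported on ~100 genes with unit-scale effects at $n = 20$
  carries score noise around 0.1, which bounds any downstream association
  F-statistic no matter how the test is run. Associations of such factors
  are unambiguous (p-values around $10^{-12}$–$10^{-15}$) but do not
  reach the double-precision reporting floor the way a genome-wide factor
  does; only factors with much larger information content pin the scores
  tightly enough for that.
* Two heterogeneity variables whose sample sets overlap substantially
  produce correlated factors that an orthogonal model can only represent
  as mixtures; VARIMAX separates them cleanly when their gene supports
  are disjoint, less so otherwise.
* The selection criterion guards against residual *pairwise* dependence;
  it does not certify the estimated $q$ when factors are weak (touching
  few genes with small effects), where no criterion can.

## Sizes used by the test suite

The packaged tests exercise the estimator at the scales the methods are
designed for while staying quick: the three illustrative cases at their
native 1000 × 20 over 20 seeds each; factor-number recovery at 400 genes
× 80 samples over 50 seeds per true $q \in \{1,2,3\}$; score recovery at
500 × 80; EM monotonicity over 50 random 80 × 16 datasets; a
$10^4$-permutation null for the correlation test; and exact-arithmetic
cross-checks of the hypergeometric tail. The full suite runs in well
under a minute on one CPU.

```{r example, eval = FALSE}
d <- simulate_case(1, seed = 7)
R <- residualize(d$expr, d$primary_group, x_name = "group")
select_nbfactors(R, q_max = 5)$q          # 1
fit <- varimax_rotate(fit_em(R, 1))
factor_sample_association(fit, data.frame(het = factor(d$het_vars[[1]])))
adj <- factor_adjust(d$expr, fit)
```
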