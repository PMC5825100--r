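---
title: "Phylogenetic path analysis of extra-pair paternity: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic path analysis of extra-pair paternity: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sempic)
```

## The scientific question

Extra-pair paternity (EPP) — the fraction of offspring sired outside the
social pair — varies enormously across socially monogamous passerines.
Candidate explanations (life-history "pace", sperm competition, breeding
density, breeding synchrony, sexual selection on song) are not competing
single predictors but a *web* of mutually correlated traits.  Path
analysis makes that web explicit: each hypothesis is a directed acyclic
graph (DAG) over nine observed variables, every arrow is a linear
regression coefficient, and the whole graph is confronted with the
species covariance matrix at once.  Because species are related by
descent, the same models are also fit on Felsenstein's phylogenetically
independent contrasts, which remove the pseudo-replication that shared
ancestry induces.

The nine variables, in the package's canonical order
(`trait_variables()`), are

| variable | meaning | analysis scale |
|---|---|---|
| `epp` | % extra-pair offspring | divided by 10 |
| `body_size` | body mass / size proxy | as supplied |
| `longevity` | maximum lifespan (yr) | as supplied |
| `male_feeding` | % male contribution to nestling feeding | divided by 10 |
| `testes_residual` | testes size corrected for body size | as supplied |
| `range_size` | breeding range area | natural log |
| `altitude_range` | altitudinal breadth | ln(x + 1) |
| `clutch_range` | within-species clutch-size range | as supplied |
| `song_complexity` | composite bioacoustic score | z-score sum |

`apply_transforms()` applies the third column exactly once (a
`transforms` attribute blocks double application).  The `+ 1` offset for
altitude exists because lowland specialists legitimately have an
altitudinal breadth of zero and `ln 0` is undefined; the offset is an
argument (`altitude_offset`) so sensitivity to it can be checked.

## The six shipped models

`shipped_models()` loads six DAGs from `inst/models/*.yaml`.  All six
share three structural commitments:

* every one of the eight predictors sends a **direct** arrow into `epp`;
  the models differ only in the arrows *among* predictors;
* no model regresses testes size on body size (testes are supplied
  already size-corrected); in model 4, where both are exogenous, they
  are allowed a free *covariance* instead;
* exogenous variables covary freely in every model (a uniform policy;
  it is the only one consistent with all six published degrees of
  freedom given the edge sets).

With $p = 9$ observed variables the sample covariance matrix has
$p(p+1)/2 = 45$ distinct moments.  A model with $e$ regression arrows,
$p$ residual/exogenous variances and $c$ free exogenous covariances has
$df = 45 - e - p - c$.  The shipped suite spans df
16, 11, 10, 15, 15, 12 and is validated at load time
(`load_model_suite()` refuses a file whose computed df, EPP edges,
forbidden edges or declared endogenous set are out of step).

Indirect (mediated) influence differs sharply across models.
`enumerate_indirect_paths()` counts directed simple paths with at least
two edges into a target (via `igraph::all_simple_paths`):

```{r paths, eval = FALSE}
sapply(shipped_models(), function(m)
  enumerate_indirect_paths(m, "epp")$count)
# model1 model2 model3 model4 model5 model6
#     15     37     39     31     19     53
```

## Estimation: maximum likelihood on a covariance structure

For a recursive system $y = By + \varepsilon$,
$\varepsilon \sim N(0, \Psi)$, the implied covariance matrix is

$$\Sigma(\theta) = (I - B)^{-1}\, \Psi\, (I - B)^{-\top},$$

with $B$ free exactly on the model's arrows and $\Psi$ free on the
diagonal plus the exogenous block.  `fit_ml()` minimizes the ML
discrepancy

$$F_{\mathrm{ML}}(\theta) = \ln|\Sigma(\theta)| +
  \operatorname{tr}\!\big(S\,\Sigma(\theta)^{-1}\big) - \ln|S| - p$$

by quasi-Newton (`nlminb`) with the **analytic gradient**: writing
$A = (I-B)^{-1}$ and $W = \Sigma^{-1}(\Sigma - S)\Sigma^{-1}$,

$$\frac{\partial F}{\partial B_{ts}} = 2\,(\Sigma W A)_{st}, \qquad
  \frac{\partial F}{\partial \Psi_{ii}} = (A^\top W A)_{ii}, \qquad
  \frac{\partial F}{\partial \Psi_{ij}} = 2\,(A^\top W A)_{ij}\ (i \ne j).$$

Start values come from a closed form: when the endogenous residual
block is diagonal and the exogenous block is saturated, the likelihood
factorizes equation by equation, so the ML solution is per-equation OLS
on mean-centred data with divisor-$N$ residual variances.  That closed
form doubles as an independent *oracle* in the test suite: for every
model in the shipped suite the iterative fitter must land on the OLS
solution to high precision.

Variances are bounded below at $10^{-10}$ (`bound_variances = TRUE`),
so a Heywood-case variance pins to the boundary instead of going
negative.  Standard errors come from the numeric Hessian of
$F_{\mathrm{ML}}$ (central differences applied to the analytic
gradient), $\widehat{\mathrm{vcov}} = (2/m)\,H^{-1}$ with $m$ the
$\chi^2$ multiplier below.  Non-convergence raises a classed error
(`sem_nonconvergence`) carrying the best parameter vector — it is never
silently returned as a fit.

### Conventions: $N$ versus $N-1$

Two defensible conventions exist for the $\chi^2$ multiplier and for
the covariance divisor.  The package defaults to

* sample moments with divisor $N$ (ML convention),
* $\chi^2 = N \cdot F_{\mathrm{ML}}$,
* $\mathrm{RMSEA} = \sqrt{\max(\chi^2 - df,\, 0) / (df \cdot N)}$,

and exposes `chisq_convention = "N-1"`, `divisor = "N-1"` and `rmsea_n`
for the alternatives.  On contrast data the sample size is the number
of contrasts ($n_\text{species} - 1$).  At the precision published in
comparative studies (two decimals) the two conventions give identical
RMSEA values for the fits this package targets, e.g.
$\sqrt{(30.04-12)/(12\cdot 35)} \approx \sqrt{(30.04-12)/(12\cdot 34)}
\approx 0.21$.

Model comparison uses $\mathrm{AIC} = -2\log L + 2k$ with the full
multivariate-normal log-likelihood (so AICs are comparable across
models fit to the same moments), plus CFI against the independence
model.

### Effects decomposition

For a DAG, total effects are
$(I-\hat B)^{-1} - I$ and indirect effects are total minus direct.
`effects()` on a fit returns the per-pair decomposition, its
standardized version ($B_{\mathrm{std}} = D^{-1} \hat B D$ with
$D = \mathrm{diag}(\hat\sigma)$ from the implied covariance), and
delta-method standard errors for indirect effects (numeric Jacobian of
the indirect map through the parameter covariance).  Rows are restricted
to pairs actually connected in the graph.  `r_squared()` reports
$1 - \hat\psi_{yy}/\hat\Sigma_{yy}$ for endogenous variables only.

## Independent contrasts

`pic_table()` wraps `ape::pic` and pins down the two things `ape`
leaves to the caller: row order (postorder — every daughter before its
parent) and subtraction direction (first daughter minus second, in
input order).  `contrasts_for_table()` applies the identical order and
direction to all nine columns, so cross-products between columns are
valid covariances.  Contrast-scale fits use `sample_moments(...,
center = "origin")`-style logic implicitly via mean-centring of the
contrasts; since contrasts have expectation zero, the distinction is
immaterial at the published precision and the default centring is used
throughout.

`parse_newick()` enforces what the pruning algorithm needs: one rooted
binary tree with strictly positive branch lengths.  Polytomies (and
unrooted inputs) are resolved deterministically
(`ape::multi2di(random = FALSE)`) and zero-length branches are replaced
by a small epsilon with a warning.

## The composite song score

`species_means()` averages each bioacoustic component over a species'
recordings (computing trill rate as notes per second per recording
first, then averaging — not the ratio of averages) and warns outside
the 2–5 recordings-per-species design range.  `composite_score()`
z-scores each of the eight components across species and sums.
Z-scoring makes the composite unit-free — re-expressing bandwidth in
kHz instead of Hz cannot move anyone's score — and weights every
component equally *in standard-deviation units*, which is the
operational meaning of "no component dominates".  A zero-variance
component carries no information and contributes 0, with a warning.
Min–max scaling is available as an alternative (`scaling = "minmax"`).

## The synthetic-data generator

Because the study's deposited trait table and phylogeny are not
re-distributable with the package, every statistical guarantee is
tested against a seeded generator whose ground truth is known exactly:

* `simulate_tree()` draws a Yule (pure-birth) tree by simulating the
  exponential epoch lengths directly ($\mathrm{Exp}(k\lambda)$ while
  $k$ lineages exist, plus a trailing $\mathrm{Exp}(n\lambda)$ epoch),
  so the expected root-to-tip depth $\sum_{k=2}^{n} 1/(k\lambda)$ is
  available in closed form for testing.
* `simulate_bm()` evolves a trait by Brownian motion along the tree, so
  its contrasts are i.i.d. $N(0, \sigma^2)$ by construction.
* `sim_truth()` converts a coefficient matrix into a full truth object
  by solving for residual variances that give every variable unit
  implied variance — supplied coefficients are therefore standardized
  effects, and impossible specifications (explained variance $\ge 1$)
  are rejected.
* `simulate_structural()` pushes independent Brownian residuals through
  $(I-B)^{-1}$, so the species data obey the structural equations
  *and* the phylogenetic correlation at once; `raw_like = TRUE` maps
  the latent scales onto plausible raw ranges (percentages via a
  logistic, sizes via exponentials) so the output survives the strict
  `read_trait_csv()` validation.

The test suite uses this generator at the sizes the guarantees demand:
100-replicate coefficient recovery at 500 tips, 50-replicate model
selection (the generating model must win by AIC $\ge 80\%$ of the
time), 200-replicate confidence-interval coverage and type-I error at
the study's own $n = 36$, and a $10^6$-draw Monte-Carlo check of the
implied-covariance algebra.

## Reproducing the published analysis

The empirical reproduction requires two files the package cannot ship:
the deposited nine-trait table for the 36 study species and the study
phylogeny.  `tests/testthat/test-acceptance.R` contains the
reproduction test; without the files it records an honest failure
(never a silent skip).  To run it, place the downloads at
`tests/testthat/deposited/traits.csv` (canonical column names) and
`tests/testthat/deposited/tree.nwk` and rerun the suite.  Everything
else — degrees of freedom, path counts, fit-index arithmetic, the
species inventory — is checked offline, and
`scripts/acceptance.R` recomputes the headline structural quantities
from scratch:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Limitations

* Observed-variable path analysis only: no latent variables, no mean
  structure, complete data required.
* Recursive (acyclic) models only; `path_model()` rejects cycles.
* The independence-model baseline for CFI frees only variances, the
  usual convention; alternatives exist.
* Contrast-scale standard errors treat the tree as known without
  error, as does the method itself.
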