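---
title: "Estimating and comparing symptom networks with symptomnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing symptom networks with symptomnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model

`symptomnet` treats a battery of questionnaire items — nine PHQ-9
depression items and seven GAD-7 anxiety items scored 0–3, and ten
binary TSQ PTSD items — as the nodes of a Gaussian graphical model
(GGM). Under a GGM, the zeros of the precision matrix $K = \Sigma^{-1}$
encode conditional independence, and each edge weight is the partial
correlation

$$w_{ij} = -\frac{\kappa_{ij}}{\sqrt{\kappa_{ii}\,\kappa_{jj}}},$$

the association between two symptoms after conditioning on all others.
Because $p = 26$ symptoms yield 325 candidate edges, the precision
matrix is estimated by the graphical lasso, maximizing the
$\ell_1$-penalized log-likelihood

$$\log\det K - \operatorname{tr}(SK) - \lambda \sum_{i \neq j} |\kappa_{ij}|$$

over a descending path of penalties, with the diagonal unpenalized
(`penalize_diagonal` in `glasso_config()` exposes this). The penalty is
chosen by the Extended Bayesian Information Criterion,

$$\mathrm{EBIC}_\gamma = -2\,l + E \log n + 4\,E\,\gamma \log p,$$

where $l$ is the Gaussian log-likelihood term with additive constants
dropped (so EBIC values are comparable only across fits to the same
data), $E$ the number of nonzero edges, and $\gamma$ the sparsity
hyperparameter. $\gamma = 0.5$ is the default used throughout the
psychometric-network literature; we expose it but make no claim that
any particular published analysis used another value.

The solver is a block coordinate-descent graphical lasso written in
C++ (see `src/glasso.cpp`), warm-started along the penalty path. A
sweep terminates when no covariance parameter moves by more than
`convergence_tol` (default $10^{-6}$). At $\lambda = 0$ the problem
reduces to inverting $S$, which is done directly. The unit tests pin
the solver to an independent numerical maximizer of the penalized
likelihood for $p \in \{2, 3\}$ at $10^{-5}$, and to the closed-form
soft-threshold solution at $p = 2$.

### Input correlations

Published analyses of this type rarely state their correlation input,
so three are provided via `correlation_matrix()`:

* `pearson` (default): product-moment correlations of the raw integer
  scores. Fast, deterministic, and the default because every downstream
  resampling stage re-runs it thousands of times.
* `spearman`: rank-based.
* `polychoric`: a two-step latent-threshold estimator. Thresholds are
  fixed at inverse-normal cumulative marginals; the latent correlation
  then maximizes the bivariate-normal cell likelihood by bounded scalar
  optimization on $(-0.999, 0.999)$. Binary pairs reduce to the
  tetrachoric case. The bivariate normal CDF uses 64-point
  Gauss–Legendre quadrature; tests compare against direct 2-D Simpson
  integration. Degenerate tables (an empty discordant cell) clamp at
  the bound with a warning.

Pearson on ordinal/binary data attenuates latent associations (by
roughly 5–10% for 0–3 items and substantially more for binary pairs);
polychoric removes that attenuation at the price of heavier computation
and noisier estimates. Either way, a non-positive-definite matrix is
repaired by eigenvalue clipping at $10^{-8}$ followed by
re-standardization (`nearest_pd_repair()`), iterated to idempotence and
flagged in the result.

## Centrality

`centrality_table()` reports, per node:

* **strength** $\sum_j |w_{ij}|$;
* **expected influence (EI)** $\sum_j w_{ij}$ — the one-step signed
  sum, so negatively connected symptoms subtract; on an all-positive
  network EI equals strength;
* **closeness** and **betweenness** on edge lengths $1/|w_{ij}|$, the
  standard distance transform in this literature. Closeness is the
  inverse of the *sum* (not the mean) of a node's geodesic distances
  and is set to 0 for any node with an unreachable partner; betweenness
  uses Brandes' accounting with fractional credit on tied geodesics and
  ignores disconnected pairs. Both conventions are declared rather than
  inferred from any published analysis, and both are pinned to an
  exhaustive path-enumeration oracle on small graphs.

z-standardized columns use the population SD across nodes; a
zero-variance index standardizes to 0. `rank_nodes()` breaks ties
lexicographically by node name so rankings are deterministic.

## Accuracy and stability

`bootstrap_edges()` resamples respondents with replacement at full
$n$, re-runs the entire estimation pipeline per replicate, and returns
percentile confidence intervals at `ci_level`. Percentile (rather than
BCa) intervals are the common choice in this workflow and are easy to
verify; a replicate whose estimation fails is dropped and counted, with
an error if more than 5% fail. The same draws back the bootstrapped
difference tests for edge pairs and node centralities: a difference is
flagged when the percentile interval of the per-replicate difference
excludes zero. No multiplicity correction is applied to these
descriptive difference tests, mirroring common practice; treat them as
exploratory.

`case_dropping_stability()` implements the case-dropping bootstrap: for
each drop proportion $d$ on a grid (default ten equal steps from 0.05
to 0.75), subsamples of size $\lfloor (1-d)n \rceil$ are drawn without
replacement and each subsample's centrality vector is correlated with
the full-sample one. The correlation-stability coefficient is the
largest $d$ at which at least 95% of subsamples correlate at least 0.7
with the full sample — so its value is always a grid member (0.75 is
the cap) or 0. Replicates with a zero-variance centrality vector have
no defined correlation and are dropped and counted; on small samples
this can flatter intrinsically sparse indices such as betweenness,
which is one reason the package reports the dropped count.

All resampling draws per-replicate sub-seeds from the master seed up
front, so serial and parallel execution (and partial re-runs) reproduce
identical replicates.

## Comparing groups

`nct_run()` implements the permutation Network Comparison Test between
two groups estimated with identical settings:

* **structure**: $M = \max_{i<j} |w^A_{ij} - w^B_{ij}|$;
* **global strength**: $S = \left| \sum |w^A| - \sum |w^B| \right|$
  over the upper triangle;
* **each edge**: $|w^A_{ij} - w^B_{ij}|$, Holm–Bonferroni corrected
  across tested edges.

Each permutation pools all rows, re-splits them at random into the
original group sizes, and re-estimates both networks. p-values use
add-one smoothing, $p = (1 + \#\{\text{permuted} \ge
\text{observed}\})/(1 + \text{iterations})$, so they are never exactly
zero and the test is slightly conservative. Per-edge tests default to
all pairs; `edge_selection = "observed"` restricts to edges nonzero in
either observed network, which lightens the Holm correction when the
networks are sparse. A permutation whose estimation fails is retried
once with a fresh split before erroring.

## The synthetic-data generator

Cohort data behind analyses of this kind are typically not publicly
deposited, so the generator is a first-class module rather than a test
fixture. `make_true_network()` builds a block-structured true
partial-correlation network over the three symptom communities:
within-block edges drawn at a given density and weight, plus a small
fixed set of bridge edges (mood–worry, anxiety–PTSD irritability, and
the sleep pair). The network is encoded directly as a unit-diagonal
precision matrix $K = I - P$, so stored partials round-trip exactly
through $K$; if $K$ is not comfortably positive definite all
off-diagonals are shrunk by a common factor until it is. The default
margin (smallest eigenvalue 0.4) is deliberately generous so that the
group-specific edge perturbations of `make_three_group_study()` cannot
push a group's network out of the feasible set — with the consequence
that realized default weights are somewhat below the nominal
`within_weight`.

`sample_group()` draws latent vectors from the implied unit-variance
multivariate normal and discretizes each item at fixed cut-points
(three for 0–3 items, one for binary), so marginal level frequencies
converge to normal orthant probabilities — a property the tests check
at $n = 50{,}000$ within three Monte-Carlo standard errors.
`make_three_group_study()` assembles the three-group study: shared base
network; per-group strengthened edges (PTSD edges for the
sexual-abuse-like group, suicide-incident edges for the
emotional-abuse-like group, anxiety edges for the physical-abuse-like
group, +0.25 each by default); group sizes 1191/1272/3479; and
per-group thresholds solved so the instrument sum-score means
approximate the published group profiles (PHQ-9 near 11.25/7.92/6.91
for EA/PA/SA). That calibration targets means only — it is a
convenience for realism, not a claim about the cohort's distribution.

What the generator deliberately does **not** emulate: item-level
measurement error beyond thresholding, covariates (age, sex),
respondent heterogeneity in thresholds, overlap between trauma groups,
and the strong internal consistency of the real instruments (the
sparse default network yields Cronbach's alpha around 0.4–0.5, versus
roughly 0.9 reported for the real scales). Passing tests therefore
demonstrate that the estimators behave correctly under the assumed
latent-Gaussian threshold model, not that any substantive conclusion
about real cohorts follows.

## Numerical choices and degenerate inputs

* Coordinate-descent dust: weights below $10^{-7}$ are treated as
  structural zeros when counting edges.
* EBIC ties along the path resolve to the larger penalty (the sparser
  model); selection is an exhaustive scan, never an early stop.
* A zero-variance item is an error naming the item, not a silent drop.
* Missing data are removed listwise at read time with a logged count,
  so every estimator's $n$ is unambiguous.
* A `lambda_path()` over an all-zero correlation matrix degenerates to
  $\{0\}$ with a warning.
* CTQ-SF subgroup flags (EA $\ge 13$, PA $\ge 10$, SA $\ge 8$ on 5–25
  subscale scores) are returned as independent booleans; how to
  allocate respondents positive for several trauma types into disjoint
  analysis groups is a substantive decision the package refuses to
  make silently.

## Problem sizes used by the test suite

The simulation-based checks run at sizes chosen to make their
statistical assertions sharp while keeping the suite practical on one
CPU: edge recovery at $n = 5000$ on a 10-node network; comparison-test
calibration over 200 repetitions of 200 permutations on an 8-node
network with 400 respondents per group (smaller groups make the EBIC
fit empty and the test statistic degenerate at an atom of zero);
comparison-test power at the full default study sizes with 2500
permutations; stability at $n = 50{,}000$ with 100 subsamples per drop
proportion. The acceptance script (`scripts/acceptance.R`) re-runs the
same computations end to end.

## Known limitations

* The two-step polychoric estimator is pairwise; the assembled matrix
  can be indefinite and is then PD-repaired, which perturbs entries
  slightly.
* Per-edge comparison power is limited by discretization: a +0.25
  latent perturbation on a binary–binary edge surfaces as an observed
  edge-weight difference near 0.08, so with many tested edges the
  weakest perturbed edges can land at the Holm boundary.
* Betweenness and closeness on estimated (hence sparse, noisy) networks
  are unstable at small $n$; the CS-coefficient machinery quantifies
  but does not fix this.
* No bridge-centrality indices, moderated networks, covariate
  adjustment, or paired-sample comparisons.
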