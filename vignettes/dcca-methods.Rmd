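---
title: "Differential canonical correlation analysis: model, screening and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential canonical correlation analysis: model, screening and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two omics blocks measured on the same $n$ samples — an $n \times p$ matrix
$\mathbf{X}$ (say, miRNA expression) and an $n \times q$ matrix $\mathbf{Y}$
(gene expression) — are often analysed with canonical correlation analysis
(CCA), which finds loadings $\mathbf{u} \in \mathbb{R}^p$,
$\mathbf{v} \in \mathbb{R}^q$ maximizing
$\mathrm{Cor}(\mathbf{Xu}, \mathbf{Yv})$. When a binary clinical grouping
$\mathbf{Z}$ (e.g. common vs. rare disease subtype) moderates the
$\mathbf{X}$–$\mathbf{Y}$ relationship, the interesting structure is not the
shared association but the *differential* one: feature pairs whose
co-variation changes sign or disappears between groups. Classic CCA and its
sparse variants average over this heterogeneity and can miss it entirely.

This package fits loadings that are rewarded both for overall association
and for between-group discrepancy:

$$
\max_{\mathbf{u}, \mathbf{v}}\;
\mathrm{Cor}(\mathbf{Xu}, \mathbf{Yv})
+ \lambda \left| \mathrm{Cor}(\mathbf{X}_0\mathbf{u}, \mathbf{Y}_0\mathbf{v})
- \mathrm{Cor}(\mathbf{X}_1\mathbf{u}, \mathbf{Y}_1\mathbf{v}) \right|,
$$

where subscripts denote the two group subsets and $\lambda \ge 0$ trades the
pooled association against the discrepancy.

## The relaxed objective and the optimizer

Writing the correlations through covariance matrices and relaxing all
variance normalizations to unit-norm constraints (the standard device in
sparse CCA) gives the criterion actually optimized, implemented in
`dcca_objective()`:

$$
\max_{\|\mathbf{u}\| = \|\mathbf{v}\| = 1}\;
\mathbf{u}^\top \Sigma_{XY} \mathbf{v}
+ \lambda \left| \mathbf{u}^\top (\Sigma_{X_0 Y_0} - \Sigma_{X_1 Y_1})
\mathbf{v} \right|.
$$

The absolute value splits the problem into two smooth branches indexed by
the sign $s \in \{+1, -1\}$ of the discrepancy form. Each branch maximizes
the bilinear form of $M_s = \Sigma_{XY} + s\lambda(\Sigma_{X_0 Y_0} -
\Sigma_{X_1 Y_1})$ over unit vectors — the operator-norm problem, whose
solution is the leading singular pair of $M_s$. `fit_dcca()` therefore
initializes each branch at the leading singular pair and runs the
power-iteration fixed point
$\mathbf{u} \leftarrow M_s \mathbf{v} / \alpha$,
$\mathbf{v} \leftarrow M_s^\top \mathbf{u} / \beta$ (the normalization
constants $\alpha, \beta$ are the Lagrange multipliers of the two unit-norm
constraints) until the relative objective change falls below `tol`
(default `1e-8`, `max_iter = 500`). Both branches are optimized
independently and the larger objective wins; this avoids lock-in when the
discrepancy form changes sign along the path. At an exactly zero bilinear
form the subgradient sign is taken as $+1$.

Two presentation conventions are applied after optimization. The loadings
are unit-norm, and the pair is reported with $\hat\rho_0 \ge \hat\rho_1$
(flipping $\mathbf{u}$ alone negates all three canonical correlations and
leaves the span unchanged). With $\lambda = 0$ the fit reduces exactly to
the leading singular pair of $\Sigma_{XY}$, which the test suite verifies
against a dense singular value decomposition.

### Standardization and covariances

Columns are centred and scaled to unit variance **on the pooled sample**
(denominator $n - 1$) before any covariance is formed; `fit_dcca()` does
this internally. Pooled standardization only fixes units: $\Sigma_{XY}$
becomes the pooled correlation matrix while the group matrices retain any
between-group mean or scale structure, which is what the group-specific
quadratic forms in the unrelaxed criterion require. Per-group
standardization is available (`standardize_columns(scope = "per_group")`)
but is not the default. Missing values are rejected rather than imputed —
imputation policy is upstream preprocessing, not part of this model.

## Choosing the tuning parameter

`select_lambda_cv()` picks $\lambda$ from a grid (default
$\{0, 0.25, 0.5, 1, 2, 4\}$, bracketing "plain CCA" to "strongly
differential") by $k$-fold cross-validation (default 5), stratified so both
groups appear in every fold. The held-out score is

$$
\left| \mathrm{Cor}_{\text{val}}(\mathbf{Xu}, \mathbf{Yv}) \right|
+ \left| \mathrm{Cor}_{\text{val}}(\mathbf{X}_0\mathbf{u},
\mathbf{Y}_0\mathbf{v}) -
\mathrm{Cor}_{\text{val}}(\mathbf{X}_1\mathbf{u}, \mathbf{Y}_1\mathbf{v})
\right|,
$$

computed from validation-fold correlations. Two details matter. First, the
score uses *correlations*, not covariances, and contains no $\lambda$
factor, so values are comparable across the grid (a $\lambda$-weighted
score would trivially select the largest $\lambda$). Second, the pooled
term enters in absolute value: the optimizer's loadings carry an arbitrary
joint sign, and the $\hat\rho_0 \ge \hat\rho_1$ reporting convention may
negate the pooled correlation; without the absolute value that sign
ambiguity leaks into the score and selection becomes erratic. Selection
uses the one-standard-error parsimony rule (as in `glmnet`): the smallest
$\lambda$ whose mean score is within one SE of the best wins. Without it,
cross-validation noise alone selects $\lambda > 0$ in a nontrivial
fraction of no-difference datasets, and a positive $\lambda$ then actively
fits spurious group discrepancy — which the Fisher-z difference test
downstream duly rejects far too often. With genuine differential signal
the discrepancy gain (about 2 units of held-out score) dwarfs one SE, so
positive $\lambda$ still wins essentially always.

## Screening by quasi-bicliques

When $\max(p, q) \gtrsim n$, or simply to concentrate the analysis on the
associated feature pairs, `screen_bicliques()` reduces both blocks before
fitting. The bipartite graph has the $p$ X-features and $q$ Y-features as
node sets and the thresholded association strengths as edges: the
biadjacency matrix is $A_{ij} = I(W_{ij} > r)$.

**Edge weights.** The default weight is
$W_{ij} = \max(|\mathrm{Cor}_0(X_i, Y_j)|, |\mathrm{Cor}_1(X_i, Y_j)|)$,
the larger of the two within-group absolute correlations. A pooled
correlation (available as `weight = "pooled"`) is blind to the most extreme
differential pattern: associations of opposite sign in equally sized groups
cancel to nearly zero in the pool, which would make the screen discard
exactly the pairs this method is designed to find. The group-wise maximum
keeps any pair that is active in at least one group.

**Threshold.** The default $r$ is the critical value of a two-sided
Fisher-z correlation test at per-edge level $0.005$,
$r = \tanh\!\left(z_{0.9975} / \sqrt{m - 3}\right)$, with $m$ the smaller
group size for group-max weights (the full $n$ for pooled). This adapts to
sample size and keeps the null edge density around 1% for the two-group
maximum. A fixed upper quantile of $W$ was considered and rejected: it
pins the retained edge *fraction* (e.g. 5% of all $p \times q$ pairs)
regardless of how much signal exists, which floods the graph with false
edges. False edges are not independent across cells, either: a noise X
feature that correlates by chance with a block's shared latent factor
lights up across the whole block width, so modest per-edge false rates
translate into whole false rows. The significance-based default keeps that
contagion rare; `r` remains a user override.

**Extraction.** Dense blocks are pulled out sequentially. The $k$-th
quasi-biclique maximizes
$\| A_k \|_{1,1} / (|N_x^k|\,|N_y^k|)^{\lambda_k}$ — edge count over block
area raised to a density exponent — over node subsets disjoint from all
previous blocks. `greedy_quasi_biclique()` uses deterministic local
search: seed at the admissible edge with the largest combined endpoint
degree (ties by weight, then lowest index), then repeatedly take the best
single-node addition or removal on either side while the objective
strictly increases. Degree seeding starts the search inside the densest
region, so large dense blocks are found before small ones; on planted
noiseless instances the test suite confirms the greedy optimum against
exhaustive enumeration.

**Tuning the exponent.** $\lambda_k < 1$ rewards growth, $\lambda_k > 1$
parsimony. For each block, $\lambda_k$ is selected from a grid (default
$0.5$ to $1.5$ in steps of $0.1$, bracketing the pure-density exponent 1)
by maximizing a Kullback–Leibler divergence: edges are modelled as a
two-component Bernoulli mixture — $\mathrm{Bernoulli}(\pi_1)$ inside the
candidate block, $\mathrm{Bernoulli}(\pi_0)$ outside — against a
structureless $\mathrm{Bernoulli}(\pi)$ reference, with all three
probabilities estimated by their sample proportions over the admissible
(not-yet-claimed) region. The divergence is evaluated cell-wise with
natural logarithms and probabilities clipped to $[10^{-6}, 1 - 10^{-6}]$
to avoid $\log 0$ on perfectly dense or empty regions. Ties prefer the
larger exponent (the more parsimonious block).

**Stopping.** Up to `max_blocks` (default 3) blocks are extracted; a new
block is discarded, and extraction stops, when it carries negligible
information: KL divergence below 5% of the largest KL among the blocks
already extracted (blocks are found in greedy-seed order, not KL order, so
the running maximum — the dominant block — is the meaningful reference),
density below twice the overall edge density, or fewer than 2 features on
either side (a width-1 "biclique" is a star around a single feature, not a
dense block). An empty screen is a legal outcome; the pipeline then fits
dCCA on all features, which is also the recommended route when
$\max(p, q) < n$ and noise is low.

## Inference on the fitted pair

`group_correlations()` returns $\hat\rho_g = \mathrm{Cor}(\mathbf{X}_g
\hat{\mathbf{u}}, \mathbf{Y}_g \hat{\mathbf{v}})$ per group.
`test_difference()` tests $\rho_0 = \rho_1$ with the two-sample Fisher-z
statistic
$z = (\operatorname{atanh}\hat\rho_0 - \operatorname{atanh}\hat\rho_1) /
\sqrt{1/(n_0 - 3) + 1/(n_1 - 3)}$ against the standard normal, two-sided
— the standard test for correlations estimated on disjoint subject sets.
Difference p-values for canonical correlations are often reported without
naming a test, so this choice is a deliberate design decision of this
package; the suite checks its type-I error on independent-score nulls.
Note the test is applied to correlations of *fitted* scores, so selection
effects of the fit are deliberately part of the measured false positive
rate. P-values across blocks are reported raw, without multiplicity
correction.

`classification_auc()` asks whether the canonical variables separate the
groups: logistic regression of the label on, per block, $\mathbf{Xu}_k$,
$\mathbf{Yv}_k$ *and their product*, then the in-sample ROC AUC
(orientation-corrected to $\ge 0.5$; a stratified cross-validated variant
is available via `cv_folds`). The product term is essential, not
decorative: when groups differ only in the correlation of the canonical
pair, the marginal distributions of $\mathbf{Xu}$ and $\mathbf{Yv}$ are
identical across groups and a linear logistic model on main effects is
blind (AUC $\approx 0.5$); the product's sign tracks the correlation and
carries the group signal.

## The simulation framework

`simulation_config()` / `generate_paired_data()` implement the generative
scheme the benchmarks use: $\mathbf{X} \sim N(\mathbf{0}, \Sigma_p)$,
$\mathbf{Y} \mid Z = g \sim N(\mathbf{X} B_g, \Sigma_q)$, with $B_g$ zero
outside dense disjoint blocks. Defaults are the benchmark design:
$p = 200$, $q = 400$, $n_0 = n_1 = 200$, blocks $10 \times 20$ and
$5 \times 10$. The three regimes are opposite-sign ($B_0 = +c$,
$B_1 = -c$ in blocks; noiseless correlations $+1/-1$), single-group
($B_0 = 0$; noiseless $0/-1$) and null ($B_0 = B_1$; no differential
signal). The coefficient magnitude, noise level and covariance structures
are free parameters of the design; this package fixes $c = 1$,
$\Sigma_p = I$, $\Sigma_q = \sigma^2 I$ with $\sigma = 0.5$ once — values
under which the within-group block correlations
($c/\sqrt{p_k c^2 + \sigma^2} \approx 0.31$ and $0.44$) are strong but
clearly not noiseless — and exposes all of them in the config (including
AR(1) structures). Replicate seeds are derived deterministically from the
master seed and recorded in the output, so every table is exactly
reproducible.

`run_replicate()` chains generate → screen → CV-tune → per-block fit.
"Selected" variables are the screening-retained features. The reported
$\hat\rho_g$, the difference test and the AUC use the leading block — the
one with the largest KL divergence — so each replicate contributes a
single summary; fitting a classifier on all blocks' variables would also
quietly inflate in-sample AUC. For the null
regime, `run_experiment()` reports the rejection fraction of the
difference test at $\alpha = 0.05$ as the false positive rate.

What the generator deliberately does *not* emulate: non-Gaussian margins
and heavy tails of real sequencing data, library-size and batch effects,
correlated background structure between inactive features, and unequal
group sizes typical of rare-subtype comparisons. Passing the simulation
benchmarks therefore demonstrates correctness of the machinery under the
stated model, not robustness to those real-data complications.

## Problem sizes used in the checks

The packaged acceptance script reruns the benchmarks at 25 replicates per
signal setting and 400 replicates for the null false-positive-rate study;
the test suite uses 1000 null replicates for calibration. A rejection
*rate* is the slowest-converging quantity here, so it gets the largest
replicate budget: the Monte-Carlo standard error is $\approx 0.008$ at
1000 replicates for a rate near 6%, comfortably inside the width of the
calibration band, while a full run stays in the minutes range on one
core. Unit and property tests use
smaller dimensions ($p, q \le 80$) where brute-force oracles — per-entry
covariance loops, exhaustive biclique enumeration up to $8 \times 8$,
closed-form singular pairs — are exact and fast.

## Known limitations

* Only the first canonical pair per block is extracted; no deflation for
  higher-order pairs.
* Sparsity comes entirely from screening; the loadings themselves are
  dense within a block (no $\ell_1$ shrinkage on $\mathbf{u}$,
  $\mathbf{v}$).
* Two groups only.
* The greedy biclique search is a local optimizer; on adversarial graphs
  it can return a sub-optimal block (the suite tracks, but does not
  assert, its approximation ratio on random instances).
* The difference test inherits the usual fragility of Fisher-z near
  $|\rho| = 1$ and is applied post-selection; its calibration is verified
  under the null generative model, not in general.
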