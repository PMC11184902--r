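# dcca — differential canonical correlation analysis for paired omics data

`dcca` detects *differential covariation* between two blocks of
high-dimensional features measured on the same samples — for example miRNA
expression (X, n × p) and gene expression (Y, n × q) — across two clinical
groups (Z ∈ {0, 1}, e.g. common vs. rare cancer subtype). Classic CCA finds
loadings **u**, **v** maximizing Cor(X**u**, Y**v**); it averages over
groups and misses associations that flip sign or vanish between them.
`dcca` instead maximizes

> Cor(X**u**, Y**v**) + λ · | Cor(X₀**u**, Y₀**v**) − Cor(X₁**u**, Y₁**v**) |

over unit-norm loadings, where the subscripts denote the group subsets and
λ ≥ 0 (chosen by stratified cross-validation) balances the pooled
association against the between-group discrepancy. The absolute-value term
splits the relaxed problem into two smooth branches, each solved as the
leading singular pair of Σ_XY ± λ(Σ_X0Y0 − Σ_X1Y1) by power iteration; the
better branch wins.

For ultra-high-dimensional inputs (max(p, q) ≳ n), a screening step first
extracts dense *quasi-bicliques* from the thresholded bipartite
feature-association graph: the k-th block maximizes
‖A_k‖₁,₁ / (|N_x^k||N_y^k|)^λ_k with the density exponent λ_k tuned per
block by a Kullback–Leibler criterion under a Bernoulli-mixture edge model.
dCCA is then fitted inside each retained block, and the between-group
difference of canonical correlations is tested with a two-sample Fisher-z
test. A simulation framework reproduces block-sparse differential
association benchmarks (selection precision/recall/F1, correlation bias,
classification AUC, null false-positive rate).

## Worked example

Simulated data with one planted 6 × 10 block whose association is positive
in group 0 and negative in group 1:

```r
library(dcca)
set.seed(42)
n <- 200; p <- 60; q <- 90
z <- rep(0:1, each = n / 2)
X <- matrix(rnorm(n * p), n, p)
B <- matrix(0, p, q); B[1:6, 1:10] <- 1
Y <- matrix(rnorm(n * q, sd = 0.5), n, q)
Y <- Y + ifelse(z == 0, 1, -1) * (X %*% B)

data <- standardize_columns(paired_omics(X, Y, z))
scr <- screen_bicliques(data)
scr
#> bipartite_screen: threshold r = 0.278
#>    1 biclique(s); 6 of 60 X features and 10 of 90 Y features retained
#>   block 1: 6 x 10, density 1.000, lambda_k 0.90, KL 297.8

sub <- subset_features(data, scr$retained_x, scr$retained_y)
cv <- select_lambda_cv(sub, seed = 1)
sols <- fit_all_blocks(data, scr, lam = cv$lambda)
sols[[1]]
#> dcca_solution (lambda = 0.5 , block 1 )
#>   rho_pooled = 0.1242, rho0 = 0.9909, rho1 = -0.9913
#>   objective = 3.314969 after 1 sweep(s)

test_difference(sols[[1]]$rho0, sols[[1]]$rho1, sum(z == 0), sum(z == 1))
#> Fisher-z test for a difference of canonical correlations
#>   rho0 = 0.9909 (n0 = 100), rho1 = -0.9913 (n1 = 100)
#>   z = 37.681, p = 0 -> reject at alpha = 0.05

classification_auc(sols[[1]], data)
#> [1] 0.9962
#> attr(,"note")
#> [1] "perfect separation"
```

Reading the output: the screen recovered exactly the planted features (6 of
60 X, 10 of 90 Y); the fitted canonical pair is strongly positively
correlated in group 0 (ρ̂₀ = 0.991) and strongly negatively in group 1
(ρ̂₁ = −0.991) while the pooled correlation is near zero — the signature of
an opposite-sign differential association; the Fisher-z test rejects
equality of the two correlations, and the canonical variables separate the
groups almost perfectly (AUC 0.996, driven by the product X**u** · Y**v**,
whose sign tracks the group-specific correlation — the logistic fit notes
the resulting quasi-perfect separation).

The same workflow runs from the shell via the installed script
(`system.file("scripts", "dcca", package = "dcca")`):

```sh
dcca fit --x X.tsv --y Y.tsv --z groups.tsv --out results/ --seed 7
dcca simulate --setting opposite_sign --replicates 100 --out table.tsv
```

Inputs are delimited text (TSV/CSV auto-detected) with a header row of
feature names and a first column of sample IDs; the group file has columns
`sample_id, group`.

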