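# lnside

Drug side-effect prediction via **linear neighborhood similarity**: an R
package for computational pharmacovigilance screens. It serves two tasks on
binary drug data:

* **SEND** — predict the side effects of a *new* drug from its binary
  descriptor vectors (chemical substructures, targets, enzymes,
  transporters, pathways, indications);
* **SEAD** — predict *missing* side effects of an approved drug from the
  side effects it is already known to have.

## The model

Each drug `i` is reconstructed as a convex combination of its `K` nearest
neighbors in feature space by solving, per drug, the constrained quadratic
program

```
min_w  w' (G + λI) w    s.t.  Σ_j w_j = 1,  w_j ≥ 0,
G[j,k] = (X_i − X_j)·(X_i − X_k)
```

whose optimal weights are the drug–drug similarities (λ = 0: *LN*
similarity; λ = 1: the regularized *RLN* variant, the default — for binary
data the reconstruction error is bounded by the feature dimension `p`, so a
unit ridge never dominates, and it keeps the program well posed when the
Gram matrix is singular). The rows stack into a sparse, row-stochastic,
zero-diagonal similarity matrix `W` over which known side-effect labels are
propagated:

```
Y' = (1 − α) (I − α W)^{-1} Y0
```

Three predictors build on this frame:

| Predictor  | Task | Input                               | Key defaults        |
|------------|------|-------------------------------------|---------------------|
| `LNSM`     | SEND | one feature view                    | RLN, K=400, α=0.8   |
| `LNSM-SMI` | SEND | several views, simplex weights θ    | RLN, K=400, auto δ  |
| `LNSM-MSE` | SEAD | the association profiles themselves | RLN, K=800, α=0.3   |

`LNSM-SMI` combines per-view similarity matrices as `Σ θ_i W_i`, where θ
minimizes `α Σ θ_i c_i + δ‖θ‖²` on the simplex with
`c_i = tr(Y0'(I − W_i)Y0)`; with the automatic δ the solution is the closed
form `θ_i = (c_max − c_i) / Σ_k (c_max − c_k)`, so informative views gain
weight and the worst view is excluded exactly.

The package also provides Jaccard/cosine/Gaussian baseline similarities,
the full multi-label metric set (Hamming loss, one-error, coverage, ranking
loss, average precision, micro/macro AUC and AUPR), both five-fold
cross-validation protocols (drug-wise for SEND, known-positive-wise for
SEAD), a cluster-structured synthetic data generator, and a command-line
interface.

## Worked example

Generate a synthetic bundle (200 drugs, 50 side-effect terms, 5 latent
clusters, one informative and one noise feature view) and cross-validate
the three predictors:

```r
library(lnside)
bundle <- generate_dataset(generator_config(seed = 7))
#> dataset_bundle: 200 drugs, 50 side-effect terms, 2 feature view(s)

send <- cross_validate_send(bundle, method = "lnsm",
                            sim_cfg = similarity_config("rln", k = 400),
                            alpha = 0.8, n_folds = 5, seed = 7)
round(unlist(send$mean[c("aupr", "auc", "one_error", "coverage")]), 4)
#>      aupr       auc one_error  coverage
#>    0.5262    0.8768    0.5100   24.6350

smi <- cross_validate_send(bundle, method = "lnsm_smi",
                           sim_cfg = similarity_config("rln", k = 400),
                           alpha = 0.8, n_folds = 5, seed = 7)
round(colMeans(smi$theta), 4)
#> view1 view2
#>     1     0

sead <- cross_validate_sead(bundle$associations,
                            sim_cfg = similarity_config("rln", k = 800),
                            alpha = 0.3, n_folds = 5, seed = 11)
round(unlist(sead$mean[c("aupr", "auc")]), 4)
#>   aupr    auc
#> 0.1918 0.8772
```

Reading the numbers: the SEND micro-AUPR of 0.53 sits far above the ~3%
positive rate of the pooled cells (a permuted-label null lands near 0.15),
so label propagation over the reconstruction graph recovers the planted
cluster structure. The integration weights put everything on the
informative view and exactly zero on the noise view. For SEAD the ranked
metrics are the meaningful ones (AUPR ≈ 6× the positive-rate baseline, AUC
0.88); at α = 0.3 propagated scores for unseen cells rarely cross 0.5, so
thresholded sensitivity is conservative by construction, while every
retained known positive keeps a score ≥ 1 − α = 0.7.

## Command line

```sh
inst/cli/lnside simulate --out-dir data --seed 1
inst/cli/lnside eval --task send --config data/bundle.json --report send.tsv --seed 1
inst/cli/lnside predict-sead --assoc data/associations.tsv --out sead.tsv
```

Subcommands: `simulate`, `similarity`, `predict-send`, `predict-sead`,
`eval`. All randomness flows from `--seed`; outputs are TSV and written
atomically; every run logs the package version, resolved parameters, input
checksums and seed.

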