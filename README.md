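# druggability

Most human proteins are not targeted by any approved drug, and picking the
wrong target is one of the costliest failure modes in drug development.
`druggability` is an R package for predicting a protein's *druggability* — a
score in [0, 1] for its propensity to be targeted by a therapeutic molecule —
from two complementary views of the protein:

- a **pooled sequence embedding** `F_pr = (1/L) Σ_i F(i,·)`, the mean of the
  per-residue embedding vectors `F ∈ R^{L×D}` of a protein language model
  (sequences are truncated to their N-terminal 1024 residues before
  embedding), and
- a **binary Gene Ontology vector** `GO_pr ∈ {0,1}^V`, with `GO_pr[i] = 1`
  iff the protein is annotated with the i-th term of a vocabulary spanning
  all three GO sub-ontologies (molecular function, cellular component,
  biological process).

The concatenation `R_pr = [F_pr ‖ GO_pr]` is reduced to its top-k features
(default k = 4000) by ranking the absolute weights of a linear SVM fitted on
standardized training data, and classified by a small neural network: three
hidden layers of 128/64/32 ReLU units with batch normalization, dropout 0.5
after the first two, an L2 penalty of 0.01 on the dense weights, trained with
Adam on binary cross-entropy (batch 32, learning rate 2·10⁻⁴ halving every 5
epochs to a floor of 2.5·10⁻⁵, early stopping with patience 5), ending in a
sigmoid output unit. Every data-dependent step — GO vocabulary,
standardization, feature selection, network — is fitted strictly inside the
training folds of the cross-validation, so reported performance is leak-free.

The package also provides:

- the full **evaluation battery**: AUC, AUPRC, precision, recall, accuracy,
  specificity, NPV, F1, MCC, Cohen's kappa, diagnostic odds ratio (with
  Haldane–Anscombe correction at zero cells), discriminant power
  `(√3/π)·ln(DOR)`, and a Bernoulli Kullback–Leibler divergence of prevalence
  versus mean score; lift curves; repeated stratified k-fold CV with
  t-distribution confidence intervals; a binomial random-label null check;
  an independent-set protocol; and Jeffries–Matusita feature separability
  `JM = √(2(1−e^{−B}))` per feature category;
- the **structure representations** used for sequence-versus-structure
  comparisons: binary CA–CA contact maps at a 7 Å threshold and centralized
  400-point clouds with uniform random-rotation augmentation, plus the
  PDB monomer-curation rules (single chain, no heteroatoms, altloc by
  occupancy, best structure by resolution subject to ≥50% coverage);
- a **synthetic-data generator** (class-shifted embedding dimensions,
  class-enriched GO terms, toy CA traces) so the entire pipeline is testable
  offline, and a deterministic seeded-hash embedding backend standing behind
  the same interface as a pretrained model;
- a **command-line interface** (`inst/cli/druggability.R`) with subcommands
  `simulate`, `embed`, `featurize`, `structure`, `train`, `predict`, `cv`,
  `evaluate`, `null-check` and `jm`.

## Worked example

```r
library(druggability)

# 200 synthetic proteins: 3-SD class shift on 10 of 64 embedding
# dimensions, 8 GO terms enriched in the positive class
data <- generate_dataset(sim_config(n_pos = 100, n_neg = 100, seed = 42))

cv <- cross_validate(data, folds = 5, runs = 1, k = 40,
                     dnn = dnn_config(seed = 1), seed = 7)
print(cv)
#> Cross-validation: 1 runs x 5 folds (k = 40)
#>   auc           0.907 +/- 0.082  [0.806, 1.009]
#>   auprc         0.920 +/- 0.079  [0.822, 1.018]
#>   precision     0.797 +/- 0.210  [0.537, 1.057]
#>   recall        0.880 +/- 0.091  [0.767, 0.993]
#>   accuracy      0.780 +/- 0.161  [0.580, 0.980]
#>   specificity   0.680 +/- 0.391  [0.194, 1.166]
#>   npv           0.876 +/- 0.081  [0.775, 0.977]
#>   f1            0.815 +/- 0.101  [0.690, 0.940]
#>   mcc           0.599 +/- 0.274  [0.258, 0.940]
#>   kappa         0.560 +/- 0.323  [0.159, 0.961]
#>   dor          71.181 +/- 81.527  [-30.048, 172.410]
#>   dp            1.926 +/- 0.866  [0.851, 3.002]
#>   dkl           0.006 +/- 0.009  [-0.006, 0.017]

round(jm_report(data), 3)
#> embedding     go_MF     go_CC     go_BP
#>     1.414     0.825     0.889     0.793
```

The summary is the mean ± SD over the five held-out folds with a
t-distribution 95% interval. An AUC of 0.91 at this small sample size says
the nested pipeline recovers the injected class signal; the JM report shows
the shifted embedding block is the most separable feature category
(saturating its √2 bound), with the three GO sub-ontology blocks clearly
separable as well. On pure-noise data (`effect_size = 0`, equal GO rates)
the same pipeline sits at AUC ≈ 0.5 — the feature selection inside the folds
buys no optimism.

From a shell, the same run is:

```sh
Rscript inst/cli/druggability.R simulate --seed 42 --out data/ --n-pos 100 --n-neg 100
Rscript inst/cli/druggability.R cv --data data/ --out metrics.json --folds 5 --runs 1 --k 40 --seed 7
```

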