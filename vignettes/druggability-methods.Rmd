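---
title: "Methods: druggability prediction from pooled embeddings and gene ontologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: druggability prediction from pooled embeddings and gene ontologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A protein is represented by two blocks. The sequence block is the mean of
its per-residue embedding vectors: for an embedding matrix $F \in
\mathbb{R}^{L' \times D}$ (one row per residue of the N-terminally truncated
sequence, $L' = \min(L, 1024)$),

$$F_{pr} = \frac{1}{L'} \sum_{i=1}^{L'} F(i,\cdot) \in \mathbb{R}^{D}.$$

The annotation block is a binary indicator vector over a GO vocabulary of
size $V$: $GO_{pr}[i] = 1$ iff term $i$ annotates the protein. The combined
representation is the concatenation $R_{pr} = [F_{pr} \,\|\, GO_{pr}]$,
embedding block first — the block order is fixed so selection-mask indices
remain portable across fits.

Classification proceeds in two fitted stages, both restricted to training
data:

1. **Feature selection.** Features are standardized (center and scale
   estimated on the training matrix; zero-variance features get scale 1 and
   therefore rank last), a linear soft-margin SVM ($C = 1$) is fitted, and
   the $k$ features with the largest absolute weights are kept (default
   $k = 4000$, capped at the representation width). Ties break toward the
   lower column index. We read "SVM feature selection" as this single-pass
   ranking rather than recursive elimination: it is the simplest
   well-defined variant, and $C$, the loss and the standardization are
   exposed in the configuration for anyone wanting a different one.
2. **Neural head.** A fully connected network
   dense(128) → BN → ReLU → dropout(0.5) → dense(64) → BN → ReLU →
   dropout(0.5) → dense(32) → BN → ReLU → dense(1) → sigmoid, with an L2
   penalty of 0.01 on all dense kernels, trained with Adam on binary
   cross-entropy, batch size 32. The learning rate is
   $\max(2.5\cdot10^{-5},\; 2\cdot10^{-4}/2^{\lfloor e/5\rfloor})$ at
   0-based epoch $e$, i.e. it starts at $2\cdot10^{-4}$, halves every 5
   epochs and reaches its floor after 15.

The sigmoid output is the druggability score in $[0, 1]$; confusion-based
metrics call a protein positive at score $\ge 0.5$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_tokens` | 1024 residues | truncation bound before embedding (memory bound of large language models on long sequences) |
| `dim` (D) | 1280 | embedding width; the synthetic backend accepts any width |
| `k` | 4000 | features kept by the SVM ranking |
| `cost` | 1.0 | SVM soft-margin constant for the ranking fit |
| `hidden_units` | 128, 64, 32 | neural head widths |
| `dropout_rate` | 0.5 | after hidden layers 1 and 2 only |
| `l2_penalty` | 0.01 | on dense kernels (not biases or BN parameters) |
| `batch_size` | 32 | minibatch size |
| `max_epochs` | 100 | hard cap; early stopping normally ends training first |
| `early_stop_patience` | 5 epochs | on the validation loss |
| `val_fraction` | 0.1 | stratified split of the training fold used only for early stopping |
| `threshold` | 0.5 | decision threshold for confusion metrics |
| contact `threshold` | 7 Å | CA–CA contact distance |
| `n_points` | 400 | fixed point-cloud size (≈ average chain length of curated structure sets) |

`max_epochs` and the early-stopping monitor are our choices: the training
recipe specifies the schedule and a patience of five epochs but neither the
epoch cap nor the monitored quantity, so we monitor the loss on a stratified
10% validation split of the training data and restore the best weights. The
layer order dense → BN → ReLU → dropout likewise fixes an ordering the
recipe leaves open ("batch normalization after each dense layer").

## Leak-free evaluation

`cross_validate()` repeats stratified $k$-fold assignment (`runs` times,
default 10 folds × 5 runs) and refits *everything* — GO vocabulary,
standardization, selection mask, network — inside each training fold. The GO
vocabulary is the lexicographically sorted union of terms over the training
records only, so $V$ is data-defined; out-of-vocabulary terms of a test
protein are ignored and an unannotated protein encodes to the zero vector
(prediction still works without GO data). Aggregation is mean ± SD over all
fold-level values with a t-distribution 95% interval. Stratification is our
choice (the protocol says only "10-fold"); it stabilizes class balance in
small folds.

Two checks guard the protocol: perturbing held-out features or labels after
fitting must leave every fitted object bit-identical, and on data with no
class signal the cross-validated AUC must stay in [0.45, 0.55] — nested
selection buys no optimism. `random_label_null()` repeats the whole CV on
binomial relabelings at the observed prevalence; `independent_test()` fits
once on a training set and evaluates once on an id-disjoint test set,
treating id overlap as an error.

## Metric conventions

- **AUC**: rank (Mann–Whitney) form, ties counted ½. **AUPRC**:
  step-interpolated average precision at the distinct score values.
- **DOR/DP**: when any confusion cell is zero, all four cells get +0.5
  (Haldane–Anscombe) for these two metrics only; rates with empty
  denominators are reported as `NA`, never silently as 0.
- **DKL**: the divergence is reported as
  $\mathrm{KL}(\mathrm{Bern}(\hat p)\,\|\,\mathrm{Bern}(\hat q))$ in nats,
  with $\hat p$ the label prevalence and $\hat q$ the mean predicted score
  (clipped to $[10^{-12}, 1-10^{-12}]$). This is a documented convention:
  the quantity is named in evaluation practice without a formula, and other
  definitions exist.
- **JM distance**: classes are modelled as diagonal-covariance Gaussians
  (variances floored at $10^{-6}$), $B$ is the Bhattacharyya distance and
  $JM = \sqrt{2(1-e^{-B})} \in [0, \sqrt 2]$. We compute it jointly per
  feature category (embedding block, and each GO sub-ontology block when
  namespaces are known) rather than per feature; the $\sqrt{\cdot}$ form is
  chosen over the $2(1-e^{-B})$ variant and stated here because both appear
  in the literature. Note that with many features and few samples the
  plug-in estimate is biased upward (estimated mean differences never
  vanish), so JM values should be compared between categories at equal
  dimension and sample size, not read as absolute separability.
- **Lift**: samples sorted by decreasing score (stable ties), near-equal
  deciles; lift = within-bin precision / prevalence.

## Structure representations

Contact maps use strict `<` at the 7 Å threshold with diagonal 1 — neither
is dictated by the definition; diagonal 1 makes the identity matrix the
degenerate one-residue case. Point clouds are centred, subsampled uniformly
without replacement (seeded, residue order preserved) when longer than
`n_points`, re-centred after subsampling so the centroid invariant holds
exactly, and zero-padded with a mask when shorter. Random rotations are
drawn uniformly on SO(3) by normalizing a 4-vector of standard normals to a
unit quaternion; augmentation multiplicity defaults to 3. PDB curation keeps
ATOM records of one chain (default: first chain in file order carrying
alpha carbons — monomer isolation names no chain rule, so we document one),
drops all HETATM records, resolves altlocs by highest occupancy (ties to
file order), and skips residues without a CA. `select_best_structure()`
filters candidates covering < 50% of the sequence, then prefers the best
(lowest) resolution with coverage as tie-break; coverage is an input, not
recomputed, because how it was originally measured is not specified.

## The synthetic generator

`generate_dataset()` emulates exactly the statistical structure the pipeline
assumes, and nothing more: (i) sequences uniform over the 20-letter
alphabet, lengths 50–200; (ii) pooled embeddings from the deterministic
seeded-hash backend, plus a class-dependent mean shift of `effect_size` ×
(per-dimension SD of the pooled embeddings) on `n_informative` designated
dimensions, injected at the embedding-cache level so downstream stages
cannot tell simulated from real caches; (iii) GO terms present with
probability `go_prob_pos` / `go_prob_neg` for enriched terms and a 5%
background otherwise, namespaces assigned cyclically to MF/CC/BP. Defaults —
300 + 300 proteins, 10 informative of 64 dimensions at 3 SD, 8 enriched of
40 terms at 0.6 vs 0.3 — are the package's standard study conditions: large
enough that a sound pipeline separates the classes decisively, small enough
to run in seconds.

What the generator does **not** emulate: evolutionary sequence structure,
correlated embedding dimensions, ontology graph structure (no ancestor
closure — annotations are used as given, matching the encoder), annotation
sparsity patterns of real proteomes, or any relationship between a sequence
and its embedding shift. Passing tests therefore demonstrate the pipeline's
statistical soundness (leak-freedom, calibration at the null, signal
recovery, determinism), not real-data performance; headline numbers from
curated drug-target corpora with a 650M-parameter embedder are out of reach
offline and are not asserted anywhere in the test suite.

The synthetic embedder maps each residue to a seeded standard-normal
expansion of the k-mer centred on it (window 3), giving zero mean and unit
variance per dimension over the k-mer alphabet, bit-identical under a fixed
`(sequence, seed, dim, window)` and shared across proteins through a cache.
A pretrained backend (checkpoint `esm2_t33_650M_UR50D`, hidden layer 33,
D = 1280) is config-gated: requesting it without the model installed raises
an error that points to the synthetic backend, and its begin/end special
tokens would be excluded from pooling — the pooled quantity is the average
of *amino acid* embeddings, though whether the original recipe included the
special tokens is not recorded.

## Numerical choices and degenerate inputs

- Batch-norm $\epsilon = 10^{-5}$; running statistics with momentum 0.9
  (inference uses running statistics, so scores are batch-size
  independent).
- He initialization for ReLU layers, $\sqrt{1/\text{fan-in}}$ for the
  output; Adam $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$.
- Cross-entropy probabilities clipped at $10^{-12}$.
- Sequences with zero standard residues have no amino-acid composition
  (error); extended letters B, J, O, U, X, Z are tolerated in records,
  flagged in metadata, accepted by the embedder, and excluded from AAC.
- An empty GO union is a valid size-0 vocabulary: the representation
  degenerates to the embedding block alone.
- Single-residue structures give the 1×1 contact map [1]; the toy-trace
  generator enforces 3.8 Å consecutive spacing and ≥ 4.0 Å non-consecutive
  separation by rejection with an explicit budget.
- All randomness flows from named, derived substreams of one master seed,
  and library internals restore the caller's RNG state.

## Problem sizes used by the test suite

Unit tests run the full nested pipeline at reduced sizes chosen as the
package's own fast defaults: 3–5 folds, single runs, and either the default
epoch budget (100 with early stopping) where convergence matters or 5–30
epochs where only mechanics are under test. The acceptance-style checks use
the standard study conditions above (n = 600 signal; n = 1000 pure noise;
100 selector replicates at 400 × 64; five random-label repetitions), which
complete in a few minutes on one CPU.

## Known limitations

- The neural head is a faithful but plain R implementation; it is fast at
  the tested scales (hundreds of samples, tens of selected features) but
  not intended for $k = 4000$ × tens of thousands of proteins.
- The pretrained embedding path is interface-only in offline settings; all
  shipped results use the synthetic backend.
- JM, DKL and the early-stopping monitor implement documented conventions
  where the underlying definitions are not fixed by the evaluation
  literature; comparisons against numbers computed under other conventions
  should account for that.
- GO annotations are used without ancestor closure or evidence-code
  filtering.
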