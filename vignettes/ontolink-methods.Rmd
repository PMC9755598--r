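---
title: "Predicting genetic interactions, dependencies and drug sensitivities with a variational graph auto-encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting genetic interactions, dependencies and drug sensitivities with a variational graph auto-encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontolink)
```

## The problem

Systematic screens of genetic interactions (GIs), cancer cell-line gene
dependencies and drug sensitivities are expensive and cover only a fraction
of the biologically interesting space. `ontolink` treats all three as *link
prediction* problems on heterogeneous graphs: genes connected by genetic
interactions, cell lines connected to genes by dependency or mutation
relations, and drugs connected to genes (targets) and to cell lines
(sensitivities — the prediction target of the full model). A variational
graph auto-encoder (VGAE) embeds every node and scores candidate links by an
inner-product decoder.

Three nested graph variants mirror how the data accumulate:

* **VGAE_G** — gene nodes, GI edges; the GI edges are themselves the
  prediction target.
* **VGAE_CD** — adds cell-line nodes connected to genes by dependency
  relations; dependencies are the target.
* **VGAE_DS** — adds drug nodes connected to genes by drug-target relations
  and to cell lines by sensitivity links (the target); cell-gene edges here
  are mutations rather than dependencies.

## Ontotype features

Every node carries a feature vector over Gene Ontology terms (the "ontotype"
representation). A gene's vector is the binary indicator of its GO terms
after propagation to all is_a/part_of ancestors (the true-path rule;
`propagate_to_ancestors()`, switchable off via `propagate = FALSE` since
leaf-only variants are also used in the literature). A gene *set* — a cell
line's mutated genes, a drug's targets — is represented by the sum of its
member gene vectors divided by the set size, so entries stay in [0, 1]. The
retained vocabulary is restricted to terms connected to at least one node of
the model graph, and all node types share one feature dimension. Annotations
with the IGI evidence code ("inferred from genetic interaction") are removed
by default to avoid circularity when GIs are the prediction target.

## The model

With adjacency $A$ on $n$ nodes, $\bar A = A + I$, $\bar D$ its degree
matrix and $\hat A = \bar D^{-1/2} \bar A \bar D^{-1/2}$, the encoder is a
learned input-normalization layer followed by a two-layer GCN with two
heads:

$$\bar X = X W_0 + b, \qquad
\mu = \sigma_2\!\big(\hat A\, \sigma_1(\hat A \bar X W_1)\, W_2\big), \qquad
\log \sigma^2 = \sigma_2\!\big(\hat A\, \sigma_1(\hat A \bar X W_1)\, W_3\big).$$

The normalization layer is a plain affine map (no batch statistics); it
projects the sparse high-dimensional ontotype space into the GCN width and
is learned end to end. Embeddings are sampled by the reparameterization
$Z = \mu + e^{\mathrm{logvar}/2} \odot \epsilon$, one draw per epoch, and
decoded as $\tilde A = \mathrm{sigmoid}(Z Z^\top)$. The loss is the weighted
binary cross-entropy between the training adjacency and $\tilde A$ plus a
KL term pulling each posterior toward $N(0, I)$.

Numerical and design choices (defaults in `vgae_config()`):

* $\sigma_1 = \mathrm{ReLU}$, $\sigma_2 = \mathrm{identity}$ — identity
  heads keep the log-variance unconstrained; both are configurable.
* Hidden widths 64/32, embedding dimension 16, learning rate 0.01, Adam,
  up to 200 full-batch epochs. Dropout (default 0) applies to each GCN
  layer's input with inverted scaling.
* The BCE positive weight defaults to the zero/one ratio of the training
  adjacency and the KL weight to $1/n$, the reference VGAE recipe.
* The reconstruction label is $A_{\mathrm{train}} + I$: the inner-product
  decoder has $\mathrm{diag}(ZZ^\top) = \lVert z_i \rVert^2 \ge 0$, so
  diagonal probabilities can never fall below one half and a zero-diagonal
  label would put an irreducible floor under the loss. With the augmented
  label, a wide model with the KL weight set to zero drives the loss to
  (numerically) zero on a tiny graph, which the test suite asserts.
* The BCE covers the full adjacency including masked (zeroed) held-out
  entries; `exclude_masked = TRUE` removes them from the loss instead.
* All losses are computed in logit form; no `log(0)` can occur.
* Inference is deterministic: candidate links are scored as
  $\mathrm{sigmoid}(\mu_i \cdot \mu_j)$.
* Gradients are hand-derived (the noise draw is treated as a constant, as
  usual for reparameterized objectives) and verified against central finite
  differences at relative error below $10^{-4}$.

### Early stopping and model selection

After every epoch the AUROC on a held-aside validation split (10% of the
training pairs) is computed from the posterior means; the returned model is
the best-validation snapshot and training stops after `patience = 20` epochs
without improvement. Two failure modes of the bare rule surfaced on small
benchmarks and motivated the `min_epochs = 100` burn-in (during which
neither the snapshot nor the stopping clock is active): with a validation
set of a few dozen pairs the epoch-wise argmax of validation AUROC is an
overfit estimator, so an initialization-noise spike in the first epochs can
beat the converged model; and when the target edge type occupies a small
fraction of the adjacency (drug–cell links are ~0.5% of the entries in the
full model) its reconstruction only starts improving after a plateau that a
bare patience rule mistakes for convergence. On the bundled benchmark the
burn-in moved held-out AUROC of the full model from the 0.47–0.68 range to
0.80–0.93 without changing any other setting.

## Evaluation protocol

`make_folds()` builds five-fold cross-validation plans over the positive
target pairs; each fold's complement is split 90/10 into train and
validation pairs. For imbalanced tasks, neutral pairs are resampled to the
positive count (`balanced_negatives()`), optionally with 10 repetitions.
Held-out positives (test and validation) are masked out of the adjacency
before training (`mask_target_edges()`), and a leakage assertion verifies on
every fold that no held-out positive remains. For GI data with explicit
neutral pairs the neutrals are the negative pool; otherwise negatives are
sampled non-edges of the target type. The `cell_line_disjoint_cv` design
instead partitions cell lines across folds so no cell line appears in more
than one of train/validation/test. Metrics are AUROC (rank form, ties one
half) and AUPRC (step-wise summation over descending thresholds); folds are
averaged unweighted. `stratify_by_sparsity()` reports metrics separately for
low- and high-sparsity pairs (median split on the sparsity of the summed
endpoint rows).

The comparison baseline (`rf_baseline()`) is the non-graph ontotype method:
each candidate pair is the elementwise sum of its endpoint feature rows, fed
to a random forest trained per fold on exactly the same splits. Because no
decision-tree package is available in the target environment, a compact
bagged-CART forest (Gini splits, per-node feature subsampling) is
implemented in the package; it behaves as expected (chance on constant
features, well above chance on planted signal).

## The synthetic benchmark

`make_benchmark()` generates an offline world that exercises every reader
and every model path: a random rooted term tree serialized as OBO, GAF
annotations with IDA/IMP/IGI evidence codes in proportions 0.6/0.3/0.1 (so
the IGI filter is exercised), and all four edge sets. Edges are planted with
probability

$$p = \alpha + (1 - \alpha)\,(1 - e^{-\beta s}),$$

where $s$ is the Jaccard similarity of the endpoint term supports,
$\alpha$ the background rate and $\beta$ the signal strength; $\beta = 0$
gives pure noise at rate $\alpha$.

Two generator design choices matter and were fixed a priori from a ceiling
analysis, not tuned against test outcomes:

* **Planted modules.** Genes belong to `n_modules` (default 15) functional
  modules; each module owns a pool of leaf terms and its genes draw their
  direct annotations from that pool. Without this structure the Jaccard
  similarity of independently annotated genes is nearly constant, every pair
  gets almost the same edge probability, and no method can beat AUROC 0.5 —
  the generator would be unable to state a recoverable signal at all.
  Leaf-pool sampling also keeps the term draws leaf-biased, so ancestor
  propagation changes the feature matrix and is genuinely tested.
* **Similarity on direct supports.** The planting similarity uses the
  direct (unpropagated) term sets: after propagation all genes share the
  root lineage, which floors the similarity near 0.1 and hence every edge
  probability near $0.3$ at $\beta = 4$, drowning the signal in background
  positives. The *model* still sees propagated features — recovery of a
  signal defined on direct annotations through propagated features is part
  of what the benchmark measures.

Defaults (300 genes, 30 cell lines, 20 drugs, `terms_per_gene = 6`,
`mutations_per_cell = 2`, `targets_per_drug = 2`, $\beta = 4$,
$\alpha = 0.02$) give generative AUROC ceilings (scoring pairs by their true
edge probability) of about 0.87/0.90/0.91 for the G/CD/DS tasks; the VGAE
reaches 0.85–0.91 held-out, and with $\beta = 0$ the GI pipeline sits at
chance (0.48–0.53 across seeds).

What a green benchmark does **not** establish: the generator plants a
single, clean similarity mechanism. Real GI/dependency/sensitivity data have
heavy-tailed degree distributions, correlated annotation noise, batch
structure and far sparser ontotype coverage; absolute AUROC values here say
nothing about performance on the real databases, only that the
implementation recovers a known signal and that the protocol is leak-free.
The drug-sensitivity task of the default world has only ~100 positive pairs,
so its per-seed metrics carry sampling noise of several AUROC points; the
acceptance checks therefore average over seeds, and the chance-level control
is asserted on the GI task, whose ~900 null positives make the
$0.5 \pm 0.05$ band statistically resolvable.

## Reproducibility

Every random step (ontology, annotations, edge draws, fold shuffles,
negative sampling, weight initialization, per-epoch noise, dropout) flows
from explicit integer seeds; identical (config, seed) produce byte-identical
bundle files, identical training histories and identical evaluation
reports. `scripts/acceptance.R --seed N --out path.json` re-runs the
three-variant pipeline on the default world from a single seed.

## Known limitations

* Full-batch training with dense $n \times n$ decoding limits graphs to a
  few thousand nodes; the real 20k-gene graphs of the source databases would
  need minibatched or subsampled decoding, which is out of scope.
* The hand-rolled forest is a faithful but small CART ensemble, not a tuned
  reference implementation.
* Hyperparameters are exposed but no search is automated beyond accepting a
  grid in configuration; the defaults follow the standard VGAE settings.
* Mutation "harmfulness" is a caller-supplied allow-list of variant-class
  strings; the package ships no source-specific vocabulary.
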