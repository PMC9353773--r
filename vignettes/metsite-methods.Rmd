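---
title: "Methods: models, attribution and design choices in metsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, attribution and design choices in metsite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metsite` predicts whether a tumour expression profile is primary or has
metastasised to bone, brain, lung or liver, and explains the prediction at
neuron and gene resolution. This vignette documents the models, the numerical
conventions, and the choices made where the design was genuinely open. It
states no empirical claim that the test suite and `scripts/acceptance.R` do
not themselves compute.

## Input model and preprocessing

Inputs are continuous log-scale expression matrices (genes × samples) with
per-sample class labels from `{primary, bone, brain, lung, liver}`. Probe-level
matrices are supported through a probe→gene map; summarization from raw scans
is out of scope.

**Quantile normalization** (`quantile_normalize`) forces every sample onto the
distribution of per-rank means. Ties within a column receive the mean of the
rank-means their ranks span — with a tie at ranks *i..j*, all tied entries get
`mean(mu[i:j])`. This is the standard convention (it agrees with
`limma::normalizeQuantiles`, which the tests use as an independent
cross-check). The operation is idempotent on tie-free data. Whether
normalization runs before or after probe collapse is not dictated by the
method; `run_pipeline` collapses first and normalizes second, and both
operations are exported so either order can be composed by hand.

**Probe collapse** (`collapse_probes`) keeps, per gene, the probe with the
highest mean across samples. Ties are broken by the lexicographically smallest
probe id so builds are deterministic. Gene order follows first appearance in
probe order.

**SMOTE** (`smote_oversample`) balances a two-class dataset by synthesising
minority samples `x_i + u (x_nn - x_i)` with `u ~ U(0,1)` and `x_nn` one of
the `k = 5` nearest minority neighbours (Euclidean distance; `k` mirrors the
default of the reference implementation of the algorithm). Synthetic samples
are flagged, originals are never modified. Two scopes are supported:

* `train` (default): oversampling happens inside training partitions only —
  cross-validation folds and held-out sets never contain synthetic points.
  This is the evaluation-valid choice.
* `all`: the whole dataset is oversampled before modelling, replicating the
  protocol of applying SMOTE once, ahead of all training. Under this scope
  evaluation folds can contain synthetic points, which optimistically biases
  AUC; it exists for faithful replication and is logged as such.

For the five-class model every minority class is oversampled within itself up
to the majority count.

**Standardization** (`standardize`) produces per-gene z-scores and returns the
fitted means/sds so that held-out or external data is always transformed with
*training* statistics; the parameters travel inside saved model archives.
Zero-variance genes get `sd = 1` (their z-scores are exactly zero) and are
reported via a message.

## The dense-network engine

One minimal engine (`init_network`, `forward`, `train`) covers the three
architectures used: the autoencoder (500–100–500, relu), the binary
classifier (64–32–8, relu, sigmoid output) and the multi-class model
(100–100–100, relu, softmax over the classes). Glorot-uniform initialisation,
zero biases, deterministic per seed.

Training is minibatch Adam (lr `1e-3`, β₁ 0.9, β₂ 0.999, ε `1e-8`, batch 32 —
conventional values; the method prescribes the optimizer, not its
hyperparameters) with

* an L2 penalty contributing `λ w` to every weight gradient (`λ = 1e-4` by
  default; only "an L2 penalty" is prescribed),
* inverted dropout on hidden layers during training only (rate 0.10, from the
  stated 10% dropout),
* early stopping on a 10% validation split with patience 10 and restoration
  of the best-validation weights (the method names the technique; the
  split, patience and restore policy are this package's concretisation), and
* losses: MAE for the autoencoder, binary or categorical cross-entropy for
  the classifiers (the softmax/cross-entropy pairing is standard; the
  method fixes the softmax output but not the loss).

Epoch budgets default to 500 for the autoencoder and 100 for classifiers,
the method's stated budgets; with early stopping the effective number is usually
far smaller. Analytic gradients are exposed via `loss_and_gradients` and
audited against central finite differences in the tests (≤ 1e-5 relative
error for all three losses).

The autoencoder's output activation is configurable. The architecture is
described with relu on every layer; `site_gene_selection` defaults to a *linear* output
because reconstruction targets in the synthetic cohorts (and any centred
data) take negative values that relu cannot emit. On strictly positive
matrices relu reproduces the textual architecture exactly.

## DeepLIFT: contributions and relevance

`deeplift_attribute` implements the rescale rule for dense networks: affine
layers propagate multipliers through the weights (linear rule); a
nonlinearity contributes the multiplier `Δpost / Δpre`; multipliers compose
by the chain rule; and the contribution of input *g* is
`(x_g - x0_g) · m_{g→target}`. When `|Δpre| < 1e-9` the multiplier falls back
to the derivative at the reference (0/1 for relu), which keeps the chain
finite without breaking completeness in the limit. Completeness — per-sample
contributions summing to the target's activation delta — is the defining
invariant and is enforced to 1e-6 relative error in the acceptance tests
(observed errors are at machine precision).

Choices the method leaves open, resolved here:

* **Reference.** The per-gene training mean (`make_reference(..., "train_mean")`)
  is the default: for expression data "how does this sample differ from the
  average profile" is the meaningful question, and the DeepLIFT authors advise
  a domain-meaningful baseline. An all-zero and a custom reference are
  provided for replication.
* **Softmax.** Attribution targets the pre-softmax *logit* of the class.
  Attributing through the softmax itself is ill-conditioned (multipliers blow
  up as probabilities saturate) and breaks the conservation property; the
  logit choice is recorded in the result object (`target_is_logit`).
* **Rescale only.** The RevealCancel rule is not implemented; rescale is the
  reference tool's default for dense relu networks.

`neuron_relevance` starts from the class-output delta and defines the
relevance of neuron *i* in layer *L* as the sum of its incoming contribution
scores from all neurons of layer *L+1*. Summing over *all* next-layer neurons
(rather than only the essential ones) makes relevance exactly conserved —
every layer's relevances add up to the class delta per sample — which is the
property the tests verify. Per-sample scores are retained for the t-tests.

## Phase 1: gene ranking and the ten-gene search

`rank_genes` scores gene *g* as the mean of `|contribution of g|` over all
samples and all bottleneck neurons (the middle hidden layer by default).
Ranking is descending with lexicographic gene-id tie-break.

The autoencoder is trained per site on that site's primary+metastasised
samples, on the expression values *as normalized* — not z-scored. This
matters: per-gene standardization equalises every gene's delta scale, and a
sufficiently trained autoencoder then reconstructs uninformative genes as
faithfully as signature genes, so attribution cannot separate them. On the
original scale, differential genes carry larger deltas and attract more of
the learned representation; the planted-signal recovery measured by the
acceptance tests (≥ 80% of planted genes in the top decile, 10 seeded
cohorts) holds under this convention and degrades severely under prior
z-scoring. The supervised classifiers, in contrast, always standardize with
training-fold statistics.

`iterative_search` evaluates panels of `k = 10, 20, …, max_k` top-ranked
genes by stratified 5-fold cross-validation of the binary classifier (AUC =
normalized Mann–Whitney U, ties 0.5), with SMOTE and standardization fitted
inside each training fold. The method reports single AUC values without
naming an evaluation protocol; stratified 5-fold CV with the fold dispersion stored
alongside is this package's protocol, and `best_k` is the smallest `k`
attaining the maximum mean AUC. `max_k` defaults to `min(200, n_genes)`,
comfortably above the panel sizes at which the search saturates in practice
(tens of genes).

## Phase 2: the site model and its interpretation

`assemble_panel` merges per-site gene lists into an order-preserving,
deduplicated panel with provenance. `train_site_model` standardizes the
panel, balances classes (SMOTE, `train` scope), and fits the softmax network;
the panel, class levels and standardization statistics are stored with the
model (and in `save_model` archives, which serialize every double at 17
significant digits so a load reproduces the network bit-identically).

`evaluate_sites` reports one-vs-rest AUC per class from the probability
columns (macro average alongside), argmax-based accuracy / sensitivity /
specificity / precision / F1 per class, and the confusion matrix. Metrics
undefined for a class absent from the labels are `NA`, never imputed. Whether
phase-2 evaluation should use cross-validation or a fixed split is left
open by the method; `run_pipeline` holds out a stratified fraction (default 25%)
before any training and evaluates there, which keeps the full pipeline cheap
and leakage-free, while the search stage uses CV internally.

**Essential neurons.** The method prescribes a two-sided t-test at 0.05 on
relevance scores but not the null contrast. Implemented as a one-sample
t-test of each neuron's per-sample relevances against the layer-wide mean
relevance, with an explicit upper-tail filter (`mean > layer mean`) so
"essential" means significantly *above-average* relevance; both the contrast
and raw-vs-BH selection are arguments. Raw p < α is the default for fidelity
to the prescribed 0.05 rule; BH-adjusted p-values are always reported. Degenerate neurons
(zero variance) get p = 1 when they equal the layer mean and p = 0 otherwise.
**Essential genes** apply the same rule to a neuron's DeepLIFT input
contributions — the neuron's *activation* delta is back-propagated. **Enrichment** is an offline one-sided
Fisher/hypergeometric test against user-supplied GMT collections with BH
adjustment across sets, computed locally so results are reproducible
offline with no web service.

## The synthetic cohort generator

`simulate_cohort` emulates the structure of the microarray cohorts the method
targets: Gaussian log-scale noise per gene (optionally equicorrelated in
blocks of 10), a disjoint planted gene set per site shifted by
`effect_size × noise sd` in that site's samples, and primary-vs-site class
imbalance. The default fixture — 1000 genes, 20 planted per site, effect 2 sd,
200 primary / 60 per site — mirrors the class imbalance typical of the
largest public cohorts of this kind (around 220 primary vs 72 metastasised) at a size small enough for continuous
testing, with an effect size a practitioner would call a strong but realistic
two-standard-deviation signature. These defaults are the study conditions of
the acceptance tests and are not tuned per run.

What the generator does *not* emulate: batch effects, probe saturation,
heavy-tailed intensity distributions, correlated signatures across sites, or
any relationship between panel genes and real biology. Passing tests
therefore demonstrate that the machinery recovers planted structure under the
stated noise model — not that the selected genes would generalise across real
cohorts or platforms, which is a substantially harder problem.

## Problem sizes, determinism, limitations

The test and acceptance runs use deliberately scaled problem sizes chosen as
part of the package's own test design: autoencoders train for up to 60 epochs
under early stopping in the recovery sweeps (recovery is already stable
there), search classifiers for 30–40 epochs, and the determinism check runs a
compact two-site pipeline (100 genes). Every stochastic step — initialisation,
shuffling, dropout, splits, SMOTE, simulation — draws from a seed derived
deterministically from one global seed via `stage_seed`, so re-running any
configuration reproduces every artifact byte for byte (`manifest.json` stores
md5 checksums to make this checkable).

Known limitations: pure-R training is practical up to a few thousand genes
and a few hundred samples, not RNA-seq-scale feature spaces; `smote_scope =
"all"` intentionally reproduces a leakage-prone protocol; attribution is
implemented for dense feedforward networks only; and the t-test treats
per-sample relevance scores as exchangeable draws, which ignores within-class
correlation structure — consistent with the interpretability procedure it
implements.
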