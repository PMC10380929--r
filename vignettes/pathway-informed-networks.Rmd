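---
title: "Pathway-informed neural networks: model, attribution and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-informed neural networks: model, attribution and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinnet)
```

## The model

Case/control classification from bulk expression profiles faces a familiar
tension: deep classifiers fit these data well but are hard to interpret,
while interpretable linear screens ignore gene interactions. This package
resolves the tension structurally, by building curated pathway membership
into the classifier's first hidden layer.

Let $g \in \mathbb{R}^n$ be one sample's expression vector (min-max scaled
to $[0,1]$ per gene) and $M \in \{0,1\}^{m \times n}$ the binary
pathway-membership matrix over $m$ gene sets, $M_{ij} = 1$ iff gene $j$
belongs to pathway $i$. The network has two parallel first-layer branches:

* a **pathway branch** $p = \tanh(((W_p \circ M)\,g) \cdot u)$, where
  $\circ$ is the element-wise product and
  $u_i \in \{1,\ 1/n_i,\ 1/\sqrt{n_i}\}$ is a per-pathway scalar on the
  pre-activation ($n_i$ = pathway size, mode `inverse_sqrt` by default);
* a **fully connected branch** $f = \tanh(W_f g + b_f)$ that captures
  signal outside curated pathways.

Each branch is layer-normalized (learned gain/shift, $\varepsilon =
10^{-5}$), concatenated as $[\mathrm{LN}(p); \mathrm{LN}(f)]$, passed
through dropout (rate 0.3), a 64-node tanh hidden layer, dropout again,
and a 2-logit softmax head trained with cross-entropy. The pathway branch
carries no bias, so its pre-activation is exactly the masked weighted sum.

Two design points deserve emphasis:

* **The mask is applied inside every forward pass** ($W_p \circ M$), not
  by one-time zeroing. Masked positions therefore receive exactly zero
  gradient under any optimizer, and the exclusion property
  $\partial p_i / \partial g_j = 0$ for $M_{ij} = 0$ holds identically at
  all times. The tests verify this bit-exactly after 50 training epochs.
* **Per-branch layer normalization, no batch normalization.** The two
  branches have very different sparsity, hence very different activation
  scales; normalizing each branch per sample before concatenation puts
  them on a common footing, and keeps evaluation-mode forward passes
  deterministic (no running batch statistics).

Dropout placement (after the concatenated layer and after the hidden
layer, symmetric) is a documented package choice; so is Glorot-uniform
initialization computed from the full matrix fan-in/fan-out, including for
the masked matrix.

The unmasked baseline (`build_baseline_dnn()`) replaces the pathway branch
with a single fully connected first layer of width 128–4096 and keeps
every other component identical, so any performance or interpretability
difference is attributable to the pathway prior alone. The
feature-selection MLP (`build_mlp()`) with widths $\{n, n/2, n/4, 2\}$ is
realized in the same pipeline, reusing its normalization and dropout.

## Training protocol

`cross_validate()` runs stratified 10-fold cross-validation with an 8:1:1
train/validation/test split: samples are dealt per class into ten
partitions; fold $k$ tests on partition $k$, validates on the next
partition (cyclically), and trains on the rest, so every part preserves
the class ratio and the union of test folds covers each sample exactly
once.

Within a fold, the training portion only is SMOTE-balanced
(`smote_oversample()`): synthetic minority samples are drawn on segments
$x_i + \alpha (x_{nb} - x_i)$, $\alpha \sim U(0,1)$, toward one of the
$k = 5$ nearest minority neighbours, until the classes are exactly equal.
Balancing strictly after splitting — never before — keeps synthetic points
out of validation and test sets. Each grid point (branch width
$\in \{32, 64, 128\}$, learning rate $\in \{10^{-4}, 5\times10^{-4},
10^{-3}\}$) trains with Adam (mini-batch 64), a plateau scheduler on the
validation AUC (factor 0.5, patience 5, floor $10^{-6}$), and early
stopping after 10 epochs without a validation-AUC improvement, restoring
the best-epoch weights; the grid point with the best validation AUC is
selected and test AUC/F1 are computed once, afterwards. The epoch cap
defaults to 200. ReduceLROnPlateau settings, the SMOTE neighbourhood size
and the 0.5 F1 threshold are package defaults, stated here because no
single canonical value exists.

Everything is deterministic given (data, seed): fold assignment, SMOTE
draws, initialization, shuffling and dropout all derive their seeds from
one global seed via `derive_seed()` (a string-hash fold into 31 bits).

## Attribution with exact summation-to-delta

`attribute_genes()` and `attribute_pathway_nodes()` implement the
DeepLIFT rescale rule with a multi-sample reference — the Deep SHAP
estimator. The reference is a class-balanced random subset of the training
data (default up to 100 samples); the reference output $\bar y$ is the
model's mean case-class probability over it. For each (sample, reference)
pair, multipliers are propagated from the output to the inputs and the
contribution of node $i$ is $C_i = m_i \cdot (x_i - \bar x_i)$, averaged
over references; attributions then satisfy completeness
$\sum_i C_i = y - \bar y$.

The implementation makes completeness hold to machine precision rather
than approximately, by decomposing every non-elementwise operation into
steps that each satisfy exact summation-to-delta:

* the two-class softmax case probability is rewritten as
  $\sigma(z_1 - z_0)$ — an exact identity — and the scalar sigmoid gets
  the rescale multiplier $\Delta\sigma / \Delta d$;
* $\tanh$ units use the standard rescale multiplier
  $\Delta\text{out}/\Delta\text{in}$ with a midpoint-gradient fallback
  when $|\Delta\text{in}| < 10^{-7}$;
* layer normalization is **not** linearized: it is split into centering
  (linear), element-wise squaring (rescale multiplier $c + \bar c$), the
  variance mean (linear), and $1/\sqrt{v + \varepsilon}$ (scalar rescale),
  whose composition reproduces the exact output difference. A
  frozen-statistics linearization — the common shortcut — leaves a
  second-order completeness residual that can exceed useful tolerances
  precisely when evaluation and reference samples differ most, which is
  the regime attribution cares about; the exact decomposition removes the
  issue entirely. The acceptance checks observe completeness errors at
  the $10^{-15}$ level against a $10^{-3}$ contract.

Pathway-node attribution treats the concatenated branch activations
$(p, f)$ as the input layer of the downstream sub-network; completeness is
taken over the full concatenated layer (the package reports the pathway
columns and keeps the rest available), since layer normalization couples
nodes within a branch and a pathway-only sum would not close.

One subtlety the tests document: with layer normalization active, a
pathway node whose outgoing hidden weights are all zero can still carry a
small attribution, because it shifts its branch's shared normalization
statistics. That is a property of the architecture, not an attribution
artifact; the corresponding dead-node-gets-zero check is therefore run on
a normalization-free fixture.

**Importance scores.** For each of the ten fold models, each node's score
is the mean absolute attribution over the fold's *test* samples; scores
are z-scored across nodes within the fold; the importance score is the
per-node mean of the ten z-scores. Downstream analyses consume these
scores: `known_gene_test()` (one- and two-sided Mann–Whitney rank-sum of
known disease genes vs the rest; exact p below 25 observations, normal
approximation with tie correction otherwise), and
`size_importance_correlation()` (Pearson r between mask row sums and
pathway importance).

**Feature selection.** `feature_selection_experiment()` rotates ten
stratified parts through test / feature-selection / validation roles
(seven parts train), scores genes by single-model importance on the
feature-selection part, keeps the top 10% (boundary ties are all kept and
logged), and retrains the $\{n, n/2, n/4, 2\}$ MLP on selected, random
size-matched, and all genes. Using a held-out part for selection keeps the
test part untouched by both training and gene ranking.

## The synthetic cohort generator

`sim_config()` / `generate_expression()` emulate the statistical shape the
classifier expects: per-gene Gaussian noise (optionally equicorrelated
through a shared per-sample factor), overlapping pathways with sizes
uniform in a range, a handful of *signal pathways* in which a fixed number
of member genes (distinct across pathways) receive a mean shift in cases,
class-imbalanced labels, and min-max scaling of every gene to $[0,1]$.
The benchmark conditions (`default_benchmark()`) are: 300 samples, case
fraction 0.33 (a 1:2 imbalance that makes SMOTE do real work, matching
the order of imbalance in blood cohorts), 1,000 genes, 50 pathways of
10–60 genes, 5 signal pathways × 4 signal genes = 20 truth genes, effect
size 1.5 noise-sd units, independent background
(`background_corr = 0`). These values are fixed study conditions, not
tuning knobs; a logistic-regression oracle on the truth genes certifies
each generated cohort is separable (CV AUC ≥ 0.85) before the network is
asked to separate it.

What the generator deliberately does **not** model: probe-level noise,
batch effects, heavy-tailed expression, gene–gene correlation beyond
equicorrelation, and label noise. Passing tests on these cohorts
demonstrate that the implementation is correct and that the
architecture/attribution machinery recovers planted structure — they do
not certify performance on real microarray or RNA-seq cohorts, where
effect sizes are far smaller and correlation structure far richer.

## Numerical and validation choices

* Quartiles (IQR filtering and probe collapse) use linear interpolation
  between order statistics (type 7); IQR ties break by first occurrence,
  making runs reproducible. The probe-collapse IQR is recomputed on the
  filtered matrix.
* Min-max scaling maps constant genes to 0; the default fits on all
  samples (matching dataset-level preprocessing), with
  `fit_on = "train_only"` available to avoid test-set leakage in new
  analyses — in that mode held-out values may leave $[0,1]$ unless
  clipped.
* AUC uses the trapezoidal rule with a fixed score direction (case
  probability), equivalent to the normalized Mann–Whitney U with
  half-credit ties; the test suite checks this equivalence against an
  explicit pair-counting oracle.
* Validation scale: the heavy cross-seed experiments in the test suite
  and acceptance script run 10-fold cross-validation with a fixed
  single-point grid (width 64, learning rate $5\times10^{-4}$; width 128
  for the baseline so both models face identical budgets), an epoch cap
  of 30 and reference size 60; the normalization-mode ablation uses 20
  replicates of a 150-sample, 300-gene, 30-pathway cohort. These sizes
  are the package's validation scale — large enough for every directional
  claim, small enough to re-run routinely.

## Known limitations

* **The pathway prior biases importance toward pathway members.** Even on
  null cohorts (no planted signal), genes belonging to at least one
  pathway receive systematically larger absolute attributions than genes
  outside every pathway, because members reach the output through both
  branches. The unmasked baseline shows no such shift under the identical
  protocol, so this is a property of the prior, not of the attribution
  machinery. Consequence: a known-gene enrichment test against an
  all-gene background conflates "the model learned these genes" with
  "these genes are in pathways"; when the known set is pathway-covered,
  compare against a pathway-member background (or interpret the
  enrichment accordingly).
* On cohorts with planted signal this strong, the unmasked baseline also
  recovers the truth genes essentially perfectly; the known-gene rank-sum
  p-value saturates its floor for both models, so the synthetic benchmark
  demonstrates *recovery* cleanly but separates the two architectures'
  interpretability only weakly. Subtler regimes (smaller effects,
  correlated background) would be needed to re-create a clear
  pathway-prior advantage.
* The pathway branch stores a dense weight matrix with a mask; at
  $n \approx 10^4$ genes this is adequate, and no sparse storage is
  attempted.
* Layer-norm coupling means pathway-node attributions are not strictly
  local to a node (see above); interpret pathway scores as contributions
  of the node within its normalized branch.
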