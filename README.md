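# pinnet

Pathway-informed neural networks for interpretable case/control
classification from gene-expression matrices.

Deep classifiers separate disease from control expression profiles well but
rarely say *which* genes and biological processes drive the prediction.
`pinnet` builds curated gene-set membership directly into the classifier:
the first hidden layer contains one node per pathway, connected only to its
member genes through a binary mask on the weight matrix, alongside a fully
connected branch for signal outside curated pathways. Backpropagation-based
attribution then scores genes and pathway nodes, turning the classifier
into a biomarker-ranking instrument. The package is aimed at
transcriptomics researchers who want a classifier whose explanations line
up with pathway biology, and at methodologists who want a fully testable,
dependency-light reference implementation.

## The model

For a sample $g \in \mathbb{R}^n$ (min-max scaled expression, $n$ genes)
and a pathway membership matrix $M \in \{0,1\}^{m \times n}$:

$$p = \tanh\big(((W_p \circ M)\,g) \cdot u\big), \qquad
  f = \tanh(W_f\,g + b_f)$$

where $u_i = 1/\sqrt{n_i}$ normalizes each pathway node by its size
$n_i = \sum_j M_{ij}$ (modes $1$ and $1/n_i$ are available for ablation).
The branches are layer-normalized, concatenated, and passed through
dropout, a 64-node tanh hidden layer, and a softmax head. Training uses
SMOTE-balanced mini-batches, Adam with a plateau scheduler, grid search on
a validation split, and early stopping on validation AUC inside stratified
10-fold (8:1:1) cross-validation.

Interpretation uses the DeepLIFT rescale rule averaged over a
class-balanced reference set (the Deep SHAP estimator): per sample,
attributions satisfy summation-to-delta, $\sum_i C_i = y - \bar y$ — in
this implementation to machine precision, including through layer
normalization. Per fold, mean absolute attributions are z-scored across
nodes; the per-node mean of the ten fold z-scores is its **importance
score**.

A synthetic-cohort generator (`sim_config()`, `default_benchmark()`)
plants differential signal inside designated pathways so the whole
pipeline — preprocessing, masking, training, attribution, gene recovery —
is testable without any external data.

## Worked example

Generate the benchmark cohort (300 samples, 1,000 genes, 50 pathways, 20
planted disease genes), build the mask, cross-validate the classifier and
rank genes:

```r
library(pinnet)

bench <- default_benchmark(seed = 42)
mask <- build_mask(
  filter_pathways(bench$pathways, feature_names(bench$data), min_genes = 10),
  feature_names(bench$data))
mask
#> <pinnet_mask> 50 pathways x 1000 genes (norm_mode = inverse_sqrt)
#>   pathway sizes: min 10 / mean 36.9 / max 60

cv <- cross_validate(bench$data, mask,
                     grid = tibble::tibble(width = 64L, lr = 5e-4),
                     opts = train_opts(max_epochs = 30, seed = 42), seed = 42)
glance(cv)
#> # A tibble: 1 × 5
#>   n_folds mean_test_auc sd_test_auc mean_test_f1 sd_test_f1
#>     <int>         <dbl>       <dbl>        <dbl>      <dbl>
#> 1      10         0.908      0.0842        0.663      0.168

imp <- cv_importance(cv, bench$data, layer = "genes", ref_size = 60, seed = 42)
dplyr::arrange(imp[, c("node_id", "importance")], dplyr::desc(importance))
#> # A tibble: 1,000 × 2
#>   node_id importance
#>   <chr>        <dbl>
#> 1 g143          5.83
#> 2 g978          5.73
#> 3 g803          5.07
#> 4 g476          4.42
#> 5 g646          3.99

known_gene_test(imp, bench$truth$signal_genes)
#> # A tibble: 1 × 6
#>   n_known n_background     U p_greater p_two_sided direction
#>     <int>        <int> <dbl>     <dbl>       <dbl> <chr>
#> 1      20          980 19586  9.82e-15    1.96e-14 known_higher
```

The cross-validated test AUC of 0.91 shows the network separates the
cohort; all five top-ranked genes (`g143`, `g978`, `g803`, `g476`,
`g646`) are planted truth genes, and the rank-sum test confirms the 20
planted genes score far above the 980 background genes — the
interpretability claim made quantitative. `autoplot(imp, highlight =
bench$truth$signal_genes)` draws the ranking; `tidy(cv)` returns per-fold
metrics.

A command-line wrapper over the same functions lives at
`inst/cli/pinnet.R` (subcommands `simulate`, `preprocess`, `mask`, `run`),
and `run_pipeline()` executes a whole configured run with a content-hashed
artifact manifest.

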