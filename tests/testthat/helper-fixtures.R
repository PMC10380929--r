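# Shared fixtures: tiny datasets, collections and models built in code, and
# independent oracles used across the suite.

# A 3-sample x 4-probe matrix with a missing entry.
tiny_probe_data <- function() {
  as_dataset(matrix(c(1.0, NA, 3.0,
                      0.5, 0.6, 0.7,
                      2.0, 4.0, 6.0,
                      1.0, 1.0, 1.0), nrow = 3,
                    dimnames = list(NULL, c("p1", "p2", "p3", "p4"))))
}

# A 2-pathway collection over 4 genes.
tiny_collection <- function() {
  tibble::tibble(pathway = c("P1", "P2"), description = c("a", "b"),
                 genes = list(c("g1", "g2"), c("g2", "g3", "g4")))
}

tiny_mask <- function(norm_mode = "inverse_sqrt") {
  build_mask(tiny_collection(), paste0("g", 1:4), norm_mode = norm_mode)
}

# Small fitted model on a small planted-signal cohort; memoised per options.
small_sim <- function(seed = 11, effect_size = 1.5, n_samples = 120,
                      n_genes = 60, n_pathways = 8) {
  cfg <- sim_config(n_samples = n_samples, case_fraction = 1 / 3,
                    n_genes = n_genes, n_pathways = n_pathways,
                    pathway_size_range = c(5, 12), n_signal_pathways = 2,
                    n_signal_genes_per_pathway = 3, effect_size = effect_size,
                    seed = seed)
  pw <- generate_pathways(cfg)
  sim <- generate_expression(cfg, pw)
  mask <- build_mask(filter_pathways(pw, feature_names(sim$data), 3),
                     feature_names(sim$data))
  list(data = sim$data, truth = sim$truth, mask = mask, pathways = pw, cfg = cfg)
}

# Independent scalar-loop oracle for the full forward pass (no matrix ops
# shared with the implementation).
oracle_forward <- function(model, x) {
  cfg <- model$cfg; prm <- model$params
  m <- cfg$n_pathways
  act <- function(z) if (cfg$activation == "tanh") tanh(z) else z
  p <- numeric(m)
  if (m > 0) {
    for (i in seq_len(m)) {
      s <- 0
      for (j in seq_len(cfg$n_genes)) {
        s <- s + prm$Wp[i, j] * model$mask$M[i, j] * x[j]
      }
      p[i] <- act(s * model$u[i])
    }
  }
  f <- numeric(cfg$n_fc)
  for (i in seq_len(cfg$n_fc)) {
    s <- prm$bf[i]
    for (j in seq_len(cfg$n_genes)) s <- s + prm$Wf[i, j] * x[j]
    f[i] <- act(s)
  }
  ln <- function(v, g, b) {
    if (!cfg$use_layernorm) return(v)
    mu <- mean(v); va <- mean((v - mu)^2)
    g * (v - mu) / sqrt(va + 1e-5) + b
  }
  h0 <- c(if (m > 0) ln(p, prm$ln_g_p, prm$ln_b_p) else NULL,
          ln(f, prm$ln_g_f, prm$ln_b_f))
  h <- numeric(cfg$n_hidden)
  for (i in seq_len(cfg$n_hidden)) {
    h[i] <- act(sum(prm$Wh[i, ] * h0) + prm$bh[i])
  }
  z <- c(sum(prm$Wo[1, ] * h) + prm$bo[1], sum(prm$Wo[2, ] * h) + prm$bo[2])
  exp(z - max(z)) / sum(exp(z - max(z)))
}

# Rank-statistic AUC oracle: Mann-Whitney U / (n1 * n0) with half credit
# for ties, via explicit pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (a in pos) for (b in neg) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

# Brute-force Mann-Whitney U for group x against group y.
oracle_u <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# Logistic-regression separability oracle: stratified CV AUC using only the
# given genes (complete separation warnings are expected and harmless).
logistic_cv_auc <- function(data, genes, seed = 1, n_folds = 5) {
  X <- feature_matrix(data)[, genes, drop = FALSE]
  y <- data$label
  folds <- stratified_folds(y, n_folds = n_folds, seed = seed)
  aucs <- vapply(folds, function(f) {
    tr <- c(f$train_idx, f$val_idx)
    df <- data.frame(y = y[tr], X[tr, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = "binomial"))
    pred <- suppressWarnings(
      stats::predict(fit, newdata = data.frame(X[f$test_idx, , drop = FALSE]),
                     type = "response"))
    evaluate_scores(pred, y[f$test_idx])$auc
  }, numeric(1))
  mean(aucs)
}
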