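# Attribution and interpretability: DeepLIFT rescale-rule multipliers
# averaged over a balanced reference set (the Deep SHAP estimator), computed
# for gene inputs and for pathway-layer nodes; cross-fold importance
# scores; known-gene enrichment; pathway-size correlation; and the
# importance-based feature-selection experiment.
#
# Every step of the multiplier chain satisfies exact summation-to-delta:
# linear maps propagate multipliers through their weights, elementwise
# nonlinearities use the rescale rule (delta-out / delta-in), and layer
# normalization is decomposed into centering (linear), elementwise square
# (rescale), mean (linear) and inverse square root (scalar rescale), so the
# per-sample attributions sum to y - y_ref to machine precision for every
# reference, and hence to y - y_bar on average.

# Rescale multiplier with gradient fallback where delta_in ~ 0.
rescale_mult <- function(delta_out, delta_in, grad_mid, tol = 1e-7) {
  small <- abs(delta_in) < tol
  out <- delta_out / delta_in
  out[small] <- grad_mid[small]
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Multipliers through one layer-normalized branch, from the branch
# activation a to the LN output, for one evaluation sample against R
# references. Exact: sum_i m[r, i] * (a_s[i] - a_ref[r, i]) equals the
# actual LN output difference summed against r_out.
ln_branch_multipliers <- function(r_out, gamma, c_s, v_s, Cbar, vbar) {
  k <- length(c_s)
  s_s <- 1 / sqrt(v_s + LN_EPS)
  sbar <- 1 / sqrt(vbar + LN_EPS)
  s_mid <- (s_s + sbar) / 2
  m_s <- rescale_mult(s_s - sbar, v_s - vbar, -0.5 * s_mid^3)
  rg <- sweep(r_out, 2, gamma, "*")
  alpha <- rowSums(rg * Cbar)                       # per-reference scalar
  r_c <- rg * s_s +
    (alpha * m_s / k) * sweep(Cbar, 2, c_s, "+")    # term for delta(1/sd)
  r_c - rowMeans(r_c)                               # centering is linear
}

# Multipliers from the case-class probability down to the concatenated
# branch activations (p, f), for eval sample `s` against all references.
# Returns an R x (m + nf) matrix.
downstream_multipliers <- function(model, cache_e, cache_r, s) {
  cfg <- model$cfg; prm <- model$params
  m <- cfg$n_pathways; nf <- cfg$n_fc
  R <- nrow(cache_r$X)

  d_s <- cache_e$Zo[s, 2] - cache_e$Zo[s, 1]
  d_r <- cache_r$Zo[, 2] - cache_r$Zo[, 1]
  mid <- sigmoid((d_s + d_r) / 2)
  m_sig <- rescale_mult(sigmoid(d_s) - sigmoid(d_r), d_s - d_r, mid * (1 - mid))

  w_diff <- prm$Wo[2, ] - prm$Wo[1, ]
  r_h <- outer(m_sig, w_diff)                       # R x h

  dZh <- sweep(-cache_r$Zh, 2, cache_e$Zh[s, ], "+")
  dHh <- sweep(-cache_r$Hh, 2, cache_e$Hh[s, ], "+")
  if (cfg$activation == "tanh") {
    grad_mid <- 1 - tanh((sweep(cache_r$Zh, 2, cache_e$Zh[s, ], "+")) / 2)^2
    m_tanh_h <- rescale_mult(dHh, dZh, grad_mid)
  } else {
    m_tanh_h <- 1
  }
  r_h0 <- (r_h * m_tanh_h) %*% prm$Wh               # R x (m + nf)

  if (!cfg$use_layernorm) return(r_h0)
  out <- matrix(0, R, m + nf)
  if (m > 0) {
    out[, seq_len(m)] <- ln_branch_multipliers(
      r_h0[, seq_len(m), drop = FALSE], prm$ln_g_p,
      cache_e$lnp$C[s, ], cache_e$lnp$v[s], cache_r$lnp$C, cache_r$lnp$v)
  }
  out[, m + seq_len(nf)] <- ln_branch_multipliers(
    r_h0[, m + seq_len(nf), drop = FALSE], prm$ln_g_f,
    cache_e$lnf$C[s, ], cache_e$lnf$v[s], cache_r$lnf$C, cache_r$lnf$v)
  out
}

# Multipliers through a tanh branch pre-activation, eval row vs references.
branch_tanh_multipliers <- function(r_branch, A_e_row, A_r, Z_e_row, Z_r,
                                    activation) {
  if (activation != "tanh") return(r_branch)
  dA <- sweep(-A_r, 2, A_e_row, "+")
  dZ <- sweep(-Z_r, 2, Z_e_row, "+")
  grad_mid <- 1 - tanh(sweep(Z_r, 2, Z_e_row, "+") / 2)^2
  r_branch * rescale_mult(dA, dZ, grad_mid)
}

#' Balanced reference set for attribution
#'
#' Draws `size/2` case and `size/2` control samples (without replacement)
#' from the training data; the reference output is the mean case-class
#' probability of the model over the drawn set.
#'
#' @param model A fitted `pinnet_model`.
#' @param X,y Training samples and labels to draw from.
#' @param size Total reference size (even; default 100, capped by the data).
#' @param seed Seed for the draw.
#' @return List with `X_ref`, `idx`, `y_ref` (per-reference outputs) and
#'   `y_bar` (their mean).
#' @export
balanced_reference <- function(model, X, y, size = 100, seed = 1L) {
  y <- check_binary_labels(y)
  half <- floor(size / 2)
  n_min <- min(sum(y == 1), sum(y == 0))
  if (half > n_min) {
    abort(sprintf("reference size %d exceeds 2 x min class count (%d)",
                  size, 2 * n_min))
  }
  idx <- with_seed(seed, {
    c(sample(which(y == 1), half), sample(which(y == 0), half))
  })
  X_ref <- X[idx, , drop = FALSE]
  y_ref <- nn_forward(model, X_ref)$prob[, 2]
  list(X_ref = X_ref, idx = idx, y_ref = y_ref, y_bar = mean(y_ref))
}

new_attribution <- function(node_ids, C, y, y_bar, layer, C_full = NULL,
                            full_node_ids = NULL) {
  if (any(!is.finite(C))) {
    bad <- node_ids[unique(which(!is.finite(C), arr.ind = TRUE)[, 2])]
    abort(sprintf("non-finite attribution for node(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  total <- if (is.null(C_full)) rowSums(C) else rowSums(C_full)
  err <- abs(total - (y - y_bar)) / pmax(1, abs(y - y_bar))
  structure(list(node_ids = node_ids, C = C, y = y, y_bar = y_bar,
                 layer = layer, completeness_error = err,
                 C_full = C_full, full_node_ids = full_node_ids),
            class = "pinnet_attribution")
}

#' Gene-level Deep SHAP attributions
#'
#' Attributes the case-class probability of every evaluation sample to the
#' gene inputs, using DeepLIFT rescale multipliers computed against each
#' reference sample and averaged (the Deep SHAP estimator). Per sample,
#' the attributions sum to `y - y_bar` (summation-to-delta).
#'
#' @param model A fitted `pinnet_model` (evaluation mode is used).
#' @param X_eval Samples to explain (matrix or dataset tibble).
#' @param reference A [balanced_reference()] result (or a bare matrix of
#'   reference inputs).
#' @return A `pinnet_attribution`: `C` (samples x genes), `y`, `y_bar`,
#'   per-sample `completeness_error`.
#' @export
attribute_genes <- function(model, X_eval, reference) {
  if (!is.matrix(X_eval)) X_eval <- feature_matrix(X_eval)
  X_ref <- if (is.matrix(reference)) reference else reference$X_ref
  cfg <- model$cfg; prm <- model$params
  fe <- nn_forward(model, X_eval, keep_cache = TRUE)
  fr <- nn_forward(model, X_ref, keep_cache = TRUE)
  ce <- fe$cache; cr <- fr$cache
  m <- cfg$n_pathways; nf <- cfg$n_fc
  n_eval <- nrow(X_eval)
  C <- matrix(0, n_eval, cfg$n_genes,
              dimnames = list(rownames(X_eval), colnames(X_eval)))
  for (s in seq_len(n_eval)) {
    r_branch <- downstream_multipliers(model, ce, cr, s)
    r_gene <- branch_tanh_multipliers(
      r_branch[, m + seq_len(nf), drop = FALSE],
      ce$Fc[s, ], cr$Fc, ce$Zf[s, ], cr$Zf, cfg$activation) %*% prm$Wf
    if (m > 0) {
      r_zp <- branch_tanh_multipliers(
        r_branch[, seq_len(m), drop = FALSE],
        ce$P[s, ], cr$P, ce$Zp[s, ], cr$Zp, cfg$activation)
      r_gene <- r_gene + sweep(r_zp, 2, model$u, "*") %*% ce$WpM
    }
    dX <- sweep(-X_ref, 2, X_eval[s, ], "+")
    C[s, ] <- colMeans(r_gene * dX)
  }
  new_attribution(colnames(X_eval) %||% paste0("g", seq_len(cfg$n_genes)),
                  C, fe$prob[, 2], mean(fr$prob[, 2]), layer = "genes")
}

#' Pathway-node Deep SHAP attributions
#'
#' Treats the concatenated branch activations (pathway nodes p and fully
#' connected nodes f) as the input layer of the downstream sub-network and
#' attributes the case-class probability to them. Summation-to-delta holds
#' over the full concatenated layer; the pathway-node columns are returned
#' (the full attribution is kept in `C_full`).
#'
#' @inheritParams attribute_genes
#' @return A `pinnet_attribution` with `C` = pathway-node columns.
#' @export
attribute_pathway_nodes <- function(model, X_eval, reference) {
  if (model$cfg$n_pathways == 0) abort("model has no pathway branch")
  if (!is.matrix(X_eval)) X_eval <- feature_matrix(X_eval)
  X_ref <- if (is.matrix(reference)) reference else reference$X_ref
  m <- model$cfg$n_pathways; nf <- model$cfg$n_fc
  fe <- nn_forward(model, X_eval, keep_cache = TRUE)
  fr <- nn_forward(model, X_ref, keep_cache = TRUE)
  ce <- fe$cache; cr <- fr$cache
  n_eval <- nrow(X_eval)
  Cfull <- matrix(0, n_eval, m + nf)
  branch_e <- cbind(ce$P, ce$Fc)
  branch_r <- cbind(cr$P, cr$Fc)
  for (s in seq_len(n_eval)) {
    r_branch <- downstream_multipliers(model, ce, cr, s)
    dB <- sweep(-branch_r, 2, branch_e[s, ], "+")
    Cfull[s, ] <- colMeans(r_branch * dB)
  }
  pw_names <- model$mask$pathway_names %||% paste0("pw", seq_len(m))
  full_ids <- c(pw_names, paste0("fc", seq_len(nf)))
  colnames(Cfull) <- full_ids
  new_attribution(pw_names, Cfull[, seq_len(m), drop = FALSE],
                  fe$prob[, 2], mean(fr$prob[, 2]), layer = "pathways",
                  C_full = Cfull, full_node_ids = full_ids)
}

#' @export
print.pinnet_attribution <- function(x, ...) {
  cat(sprintf("<pinnet_attribution> %s: %d samples x %d nodes | max completeness error %.2e\n",
              x$layer, nrow(x$C), length(x$node_ids),
              max(x$completeness_error)))
  invisible(x)
}

#' Cross-fold importance scores
#'
#' Per fold, each node's score is the mean absolute attribution over the
#' fold's evaluated samples; scores are z-scored across nodes within the
#' fold, and the importance score is the per-node mean of the fold
#' z-scores.
#'
#' @param attributions List of `pinnet_attribution` objects (one per fold,
#'   same node set).
#' @return A `pinnet_importance` tibble: `node_id`, one `z_fold*` column
#'   per fold, and `importance`.
#' @export
importance_scores <- function(attributions) {
  ids <- attributions[[1]]$node_ids
  zs <- lapply(seq_along(attributions), function(i) {
    a <- attributions[[i]]
    if (!identical(a$node_ids, ids)) abort("node sets differ across folds")
    s <- colMeans(abs(a$C))
    if (sd(s) == 0) abort(sprintf("fold %d has constant attribution scores", i))
    (s - mean(s)) / sd(s)
  })
  Z <- do.call(cbind, zs)
  colnames(Z) <- paste0("z_fold", seq_along(zs))
  out <- dplyr::bind_cols(tibble::tibble(node_id = ids),
                          tibble::as_tibble(Z),
                          tibble::tibble(importance = rowMeans(Z)))
  class(out) <- c("pinnet_importance", class(out))
  out
}

#' Importance scores from a cross-validation run
#'
#' For every fold model, draws a balanced reference from the fold's
#' training samples, attributes the fold's test samples (gene inputs or
#' pathway nodes), and aggregates the per-fold z-scores into importance
#' scores.
#'
#' @param cv A `pinnet_cv` from [cross_validate()].
#' @param data The dataset tibble the CV was run on.
#' @param layer `"genes"` or `"pathways"`.
#' @param ref_size Balanced reference size (capped by the training class
#'   counts).
#' @param seed Seed for the reference draws.
#' @return A `pinnet_importance` tibble.
#' @export
cv_importance <- function(cv, data, layer = c("genes", "pathways"),
                          ref_size = 100, seed = 1L) {
  layer <- match.arg(layer)
  X <- feature_matrix(data)
  y <- check_binary_labels(data$label)
  attr_fun <- if (layer == "genes") attribute_genes else attribute_pathway_nodes
  atts <- lapply(seq_along(cv$models), function(k) {
    sp <- cv$splits[[k]]
    y_tr <- y[sp$train_idx]
    size <- min(ref_size, 2 * min(sum(y_tr == 1), sum(y_tr == 0)))
    size <- size - size %% 2
    ref <- balanced_reference(cv$models[[k]], X[sp$train_idx, , drop = FALSE],
                              y_tr, size = size,
                              seed = derive_seed(seed, paste0("ref", k)))
    attr_fun(cv$models[[k]], X[sp$test_idx, , drop = FALSE], ref)
  })
  importance_scores(atts)
}

#' Rank-sum comparison of known-gene importance
#'
#' Two-sample Wilcoxon (Mann-Whitney) rank-sum test of importance scores,
#' known genes vs all remaining genes. Exact p-values are used below 25
#' total observations (without ties), the normal approximation with tie
#' correction otherwise.
#'
#' @param importance A `pinnet_importance` tibble (gene layer).
#' @param known Character vector of known disease-gene ids.
#' @return One-row tibble: `n_known`, `n_background`, `U`, `p_greater`
#'   (one-sided, known > background), `p_two_sided`, `direction`.
#' @export
known_gene_test <- function(importance, known) {
  x <- importance$importance[importance$node_id %in% known]
  bg <- importance$importance[!importance$node_id %in% known]
  if (length(x) == 0 || length(bg) == 0) {
    abort("both the known-gene group and the background must be non-empty")
  }
  exact <- (length(x) + length(bg)) < 25
  g <- suppressWarnings(stats::wilcox.test(x, bg, alternative = "greater",
                                           exact = exact))
  t2 <- suppressWarnings(stats::wilcox.test(x, bg, alternative = "two.sided",
                                            exact = exact))
  tibble::tibble(n_known = length(x), n_background = length(bg),
                 U = unname(g$statistic), p_greater = g$p.value,
                 p_two_sided = t2$p.value,
                 direction = if (stats::median(x) >= stats::median(bg))
                   "known_higher" else "known_lower")
}

#' Correlation between pathway size and pathway importance
#'
#' Pearson correlation between the number of genes in each pathway (mask
#' row sums) and the pathway-node importance scores.
#'
#' @param mask A `pinnet_mask`.
#' @param pathway_importance A `pinnet_importance` tibble (pathway layer).
#' @return One-row tibble: `r`, `abs_r`, `n_pathways`.
#' @export
size_importance_correlation <- function(mask, pathway_importance) {
  sizes <- rowSums(mask$M)
  imp <- pathway_importance$importance[
    match(mask$pathway_names, pathway_importance$node_id)]
  if (sum(!is.na(imp)) < 3) abort("need at least 3 pathways")
  r <- cor(sizes, imp, use = "complete.obs")
  tibble::tibble(r = r, abs_r = abs(r), n_pathways = sum(!is.na(imp)))
}

#' Importance-based feature-selection experiment
#'
#' Splits the cohort into ten stratified parts and, rotating roles ten
#' times, trains the pathway-informed network on seven parts (one further
#' part serves as its validation set), scores genes by single-model
#' importance on a held-out feature-selection part, selects the top
#' `fraction` of genes (boundary ties are all kept), and trains a
#' `{n, n/2, n/4, 2}` multilayer perceptron on (i) the selected genes,
#' (ii) a size-matched random gene set and (iii) all genes, evaluating each
#' on the remaining test part.
#'
#' @param data Dataset tibble with `label`.
#' @param mask A `pinnet_mask`.
#' @param fraction Fraction of genes to select, default 0.10.
#' @param seed Seed for splits, training and the random gene arm.
#' @param opts [train_opts()] shared by all trained models.
#' @param grid Hyperparameter grid for the pathway model (defaults to a
#'   single point, width 64 at `opts$lr`).
#' @param n_repeats Number of role rotations, default 10.
#' @param ref_size Reference size for the importance attribution.
#' @return Tibble with columns `repeat_id`, `arm` (selected / random /
#'   all), `n_genes`, `auc`.
#' @export
feature_selection_experiment <- function(data, mask, fraction = 0.10,
                                         seed = 1L, opts = train_opts(),
                                         grid = NULL, n_repeats = 10,
                                         ref_size = 100) {
  check_fraction(fraction, "fraction", upper_open = FALSE)
  X <- feature_matrix(data)
  y <- check_binary_labels(data$label)
  n_sel_target <- max(1L, floor(fraction * ncol(X)))
  if (n_sel_target < 2 && fraction < 1) abort("fraction selects fewer than 2 genes")
  grid <- grid %||% tibble::tibble(width = 64L, lr = opts$lr)
  n_parts <- 10
  part <- integer(length(y))
  with_seed(derive_seed(seed, "fs_parts"), {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      part[idx] <- rep_len(seq_len(n_parts), length(idx))
    }
  })
  res <- vector("list", n_repeats)
  for (k in seq_len(n_repeats)) {
    test_p <- (k - 1L) %% n_parts + 1L
    sel_p <- k %% n_parts + 1L
    val_p <- (k + 1L) %% n_parts + 1L
    split <- list(fold = k,
                  train_idx = which(!part %in% c(test_p, sel_p, val_p)),
                  val_idx = which(part == val_p),
                  test_idx = which(part == test_p))
    sel_idx <- which(part == sel_p)
    o <- opts; o$seed <- derive_seed(seed, paste0("fs_train", k))
    fit <- train_fold(data, split, mask = mask, grid = grid, opts = o)
    y_tr <- y[split$train_idx]
    size <- min(ref_size, 2 * min(sum(y_tr == 1), sum(y_tr == 0)))
    ref <- balanced_reference(fit$model, X[split$train_idx, , drop = FALSE],
                              y_tr, size = size - size %% 2,
                              seed = derive_seed(seed, paste0("fs_ref", k)))
    att <- attribute_genes(fit$model, X[sel_idx, , drop = FALSE], ref)
    imp <- importance_scores(list(att))
    ord <- order(-imp$importance)
    thresh <- imp$importance[ord[min(n_sel_target, length(ord))]]
    selected <- imp$node_id[imp$importance >= thresh]
    if (length(selected) > n_sel_target) {
      message(sprintf("repeat %d: boundary ties kept, %d genes selected (target %d)",
                      k, length(selected), n_sel_target))
    }
    random_genes <- with_seed(derive_seed(seed, paste0("fs_rand", k)),
                              sample(colnames(X), length(selected)))
    arms <- list(selected = selected, random = random_genes,
                 all = colnames(X))
    for (arm in names(arms)) {
      genes <- arms[[arm]]
      auc <- fs_mlp_auc(X[, genes, drop = FALSE], y, split, o)
      res[[length(res) + 1L]] <- tibble::tibble(repeat_id = k, arm = arm,
                                                n_genes = length(genes),
                                                auc = auc)
    }
  }
  dplyr::bind_rows(res)
}

# Train the {n, n/2, n/4, 2} MLP on one split and return its test AUC.
fs_mlp_auc <- function(Xg, y, split, opts) {
  bal <- if (!is.null(opts$smote_k)) {
    smote_oversample(Xg[split$train_idx, , drop = FALSE], y[split$train_idx],
                     k_neighbors = opts$smote_k,
                     seed = derive_seed(opts$seed, "fs_smote"))
  } else {
    list(X = Xg[split$train_idx, , drop = FALSE], y = y[split$train_idx])
  }
  mlp <- build_mlp(ncol(Xg), seed = derive_seed(opts$seed, "fs_mlp"))
  fitted <- fit_network(mlp, bal$X, bal$y, Xg[split$val_idx, , drop = FALSE],
                        y[split$val_idx], opts)
  evaluate_model(fitted, Xg[split$test_idx, , drop = FALSE],
                 y[split$test_idx])$auc
}
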