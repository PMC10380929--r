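# A small fitted model shared across attribution tests.
fitted_fixture <- function(seed = 71, ...) {
  fx <- small_sim(seed = seed, ...)
  X <- feature_matrix(fx$data); y <- fx$data$label
  sp <- stratified_folds(y, seed = seed)[[1]]
  mod <- init_model(pinnet_config(ncol(X), nrow(fx$mask$M), n_fc = 8,
                                  seed = seed), fx$mask)
  fit <- fit_network(mod, X[sp$train_idx, ], y[sp$train_idx],
                     X[sp$val_idx, ], y[sp$val_idx],
                     train_opts(max_epochs = 12, seed = seed))
  c(fx, list(X = X, y = y, split = sp, model = fit))
}

test_that("balanced reference draws equal class counts and matches the forward oracle", {
  fx <- fitted_fixture()
  ref <- balanced_reference(fx$model, fx$X, fx$y, size = 10, seed = 3)
  expect_equal(sum(fx$y[ref$idx] == 1), 5)
  expect_equal(sum(fx$y[ref$idx] == 0), 5)
  expect_identical(balanced_reference(fx$model, fx$X, fx$y, 10, seed = 3)$idx,
                   ref$idx)
  # reference output is the mean forward output over the reference set
  expect_equal(ref$y_bar,
               mean(nn_forward(fx$model, ref$X_ref)$prob[, 2]),
               tolerance = 1e-12)
  expect_error(balanced_reference(fx$model, fx$X, fx$y, size = 10000), "exceeds")
})

test_that("gene attributions satisfy summation-to-delta on the full network", {
  fx <- fitted_fixture()
  ref <- balanced_reference(fx$model, fx$X[fx$split$train_idx, ],
                            fx$y[fx$split$train_idx], size = 20, seed = 5)
  att <- attribute_genes(fx$model, fx$X[fx$split$test_idx, ], ref)
  expect_equal(unname(rowSums(att$C)), unname(att$y - att$y_bar),
               tolerance = 1e-3)
  expect_true(all(att$completeness_error < 1e-3))
  # completeness holds per reference too, not just on the mean
  one_ref <- attribute_genes(fx$model, fx$X[fx$split$test_idx[1:3], ],
                             ref$X_ref[4, , drop = FALSE])
  y_one <- nn_forward(fx$model, ref$X_ref[4, , drop = FALSE])$prob[, 2]
  expect_equal(unname(rowSums(one_ref$C)), unname(one_ref$y - y_one),
               tolerance = 1e-9)
})

test_that("a sample attributed against itself gets all-zero attributions", {
  fx <- fitted_fixture()
  x1 <- fx$X[1, , drop = FALSE]
  att <- attribute_genes(fx$model, x1, x1)
  expect_equal(max(abs(att$C)), 0)
  attp <- attribute_pathway_nodes(fx$model, x1, x1)
  expect_equal(max(abs(attp$C_full)), 0)
})

test_that("linear-fixture attributions equal the closed form w * (x - x_ref)", {
  # identity activation, no layer norm: end-to-end linear map, for which the
  # rescale rule must reduce to weight * input-difference
  col <- tiny_collection()
  mask <- build_mask(col, paste0("g", 1:4))
  cfg <- pinnet_config(4, 2, n_fc = 3, n_hidden = 5, dropout_rate = 0,
                       seed = 13, activation = "identity",
                       use_layernorm = FALSE)
  mod <- init_model(cfg, mask)
  x <- matrix(runif(4), 1); xr <- matrix(runif(4), 1)
  att <- attribute_genes(mod, x, xr)
  # closed-form effective linear weights of the case-minus-control logit
  prm <- mod$params
  w_diff <- (prm$Wo[2, ] - prm$Wo[1, ]) %*% prm$Wh  # 1 x (m + nf)
  w_gene <- w_diff[, 1:2] %*% (sweep(prm$Wp * mask$M, 1, mod$u, "*")) +
    w_diff[, 3:5] %*% prm$Wf
  d_logit_attr <- as.numeric(w_gene) * as.numeric(x - xr)
  # the sigmoid head rescales every gene's share by the same factor
  dlog <- sum(d_logit_attr)
  scale <- (att$y - nn_forward(mod, xr)$prob[, 2]) / dlog
  expect_equal(as.numeric(att$C), d_logit_attr * as.numeric(scale),
               tolerance = 1e-9)
})

test_that("a gene dead to the whole network receives exactly zero attribution", {
  fx <- fitted_fixture()
  mask <- fx$mask
  free <- which(colSums(mask$M) == 0)[1]
  skip_if(is.na(free), "fixture has no pathway-free gene")
  mod <- fx$model
  mod$params$Wf[, free] <- 0  # also sever the fully connected branch
  ref <- balanced_reference(mod, fx$X[fx$split$train_idx, ],
                            fx$y[fx$split$train_idx], size = 10, seed = 2)
  att <- attribute_genes(mod, fx$X[fx$split$test_idx[1:5], ], ref)
  expect_equal(max(abs(att$C[, free])), 0)
})

test_that("pathway-node attributions are complete over the concatenated layer", {
  fx <- fitted_fixture()
  ref <- balanced_reference(fx$model, fx$X[fx$split$train_idx, ],
                            fx$y[fx$split$train_idx], size = 20, seed = 5)
  att <- attribute_pathway_nodes(fx$model, fx$X[fx$split$test_idx, ], ref)
  expect_equal(unname(rowSums(att$C_full)), unname(att$y - att$y_bar),
               tolerance = 1e-3)
  expect_equal(ncol(att$C), nrow(fx$mask$M))
  # a pathway node with all outgoing hidden weights zeroed contributes
  # nothing; without layer normalization the node is then fully dead (layer
  # norm would couple it to its branch mates through the shared statistics)
  mod0 <- init_model(pinnet_config(ncol(fx$X), nrow(fx$mask$M), n_fc = 8,
                                   seed = 1, use_layernorm = FALSE), fx$mask)
  mod0$params$Wh[, 1] <- 0
  att0 <- attribute_pathway_nodes(mod0, fx$X[fx$split$test_idx[1:4], ], ref$X_ref)
  expect_equal(max(abs(att0$C[, 1])), 0)
})

test_that("importance scores are the mean of per-fold z-scores", {
  # hand-computed 3-node, 2-fold example
  fake <- function(C) structure(list(node_ids = c("a", "b", "c"), C = C,
                                     y = rep(0, 2), y_bar = 0,
                                     layer = "genes",
                                     completeness_error = rep(0, 2)),
                                class = "pinnet_attribution")
  a1 <- fake(rbind(c(1, -2, 0), c(3, -2, 0)))  # colMeans(abs) = (2, 2, 0)
  a2 <- fake(rbind(c(0, 4, 2), c(0, 4, 2)))    # colMeans(abs) = (0, 4, 2)
  imp <- importance_scores(list(a1, a2))
  z1 <- (c(2, 2, 0) - mean(c(2, 2, 0))) / sd(c(2, 2, 0))
  z2 <- (c(0, 4, 2) - mean(c(0, 4, 2))) / sd(c(0, 4, 2))
  expect_equal(imp$importance, (z1 + z2) / 2)
  # identical folds: importance equals the single fold's z-score
  imp1 <- importance_scores(list(a1, a1))
  expect_equal(imp1$importance, z1)
  # node-order equivariance
  perm <- c(3, 1, 2)
  a1p <- fake(a1$C[, perm]); a1p$node_ids <- a1$node_ids[perm]
  a2p <- fake(a2$C[, perm]); a2p$node_ids <- a2$node_ids[perm]
  impp <- importance_scores(list(a1p, a2p))
  expect_equal(impp$importance[match(imp$node_id, impp$node_id)],
               imp$importance)
  # constant attribution within a fold is degenerate
  expect_error(importance_scores(list(fake(rbind(c(1, 1, 1), c(-1, -1, -1))))),
               "constant")
})

test_that("known-gene rank-sum test matches brute-force U and detects separation", {
  imp <- structure(tibble::tibble(node_id = paste0("g", 1:30),
                                  importance = c(rep(3, 5), rep(0, 25)) +
                                    seq(0, 0.29, by = 0.01)),
                   class = c("pinnet_importance", class(tibble::tibble())))
  res <- known_gene_test(imp, paste0("g", 1:5))
  expect_lt(res$p_greater, 0.001)
  expect_identical(res$direction, "known_higher")
  # brute-force pair-count oracle for U on small vectors
  known <- imp$importance[1:5]; rest <- imp$importance[6:30]
  expect_equal(unname(res$U), oracle_u(known, rest))
  expect_error(known_gene_test(imp, "zz"), "non-empty")
})

test_that("known-gene p-values are null-uniform when importance is unstructured", {
  set.seed(202)
  ps <- replicate(400, {
    imp <- tibble::tibble(node_id = paste0("g", 1:40), importance = rnorm(40))
    known_gene_test(imp, paste0("g", sample(40, 8)))$p_two_sided
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("size-importance correlation matches the textbook formula", {
  mask <- structure(list(M = rbind(rep(1, 5), c(1, 1, 1, 0, 0),
                                   c(1, 1, 0, 0, 0), c(1, 1, 1, 1, 0),
                                   c(1, 0, 0, 0, 0)),
                         pathway_names = paste0("P", 1:5),
                         gene_ids = paste0("g", 1:5)),
                    class = "pinnet_mask")
  imp <- tibble::tibble(node_id = paste0("P", 1:5),
                        importance = c(2.0, 1.1, 0.9, 1.7, 0.2))
  sizes <- c(5, 3, 2, 4, 1)
  r_hand <- sum((sizes - mean(sizes)) * (imp$importance - mean(imp$importance))) /
    sqrt(sum((sizes - mean(sizes))^2) * sum((imp$importance - mean(imp$importance))^2))
  out <- size_importance_correlation(mask, imp)
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  # importance proportional to size -> r = 1
  imp2 <- tibble::tibble(node_id = paste0("P", 1:5), importance = sizes * 2.5)
  expect_equal(size_importance_correlation(mask, imp2)$r, 1)
  expect_error(size_importance_correlation(mask, imp[1:2, ]), "at least 3")
})

test_that("feature selection recovers planted genes better than random genes", {
  fx <- small_sim(seed = 81, n_samples = 120, n_genes = 50, n_pathways = 6)
  res <- feature_selection_experiment(
    fx$data, fx$mask, fraction = 0.2, seed = 4,
    opts = train_opts(max_epochs = 10, seed = 4),
    grid = tibble::tibble(width = 16L, lr = 5e-4),
    n_repeats = 3, ref_size = 30)
  expect_setequal(unique(res$arm), c("selected", "random", "all"))
  expect_equal(nrow(res), 9)
  wide <- tidyr::pivot_wider(res[, c("repeat_id", "arm", "auc")],
                             names_from = "arm", values_from = "auc")
  expect_gte(sum(wide$selected >= wide$random), 2)
})
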