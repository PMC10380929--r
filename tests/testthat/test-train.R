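test_that("stratified folds preserve class ratios, partition all samples, reproduce", {
  y <- c(rep(1, 30), rep(0, 70))
  folds <- stratified_folds(y, seed = 4)
  expect_length(folds, 10)
  for (f in folds) {
    expect_equal(sum(y[f$test_idx]), 3)
    expect_equal(length(f$test_idx), 10)
    expect_equal(sum(y[f$val_idx]), 3)
    # parts are disjoint and cover everything
    expect_length(intersect(f$train_idx, c(f$val_idx, f$test_idx)), 0)
    expect_setequal(c(f$train_idx, f$val_idx, f$test_idx), seq_along(y))
  }
  # union of test folds = all samples, no overlap
  all_test <- unlist(lapply(folds, `[[`, "test_idx"))
  expect_setequal(all_test, seq_along(y))
  expect_equal(anyDuplicated(all_test), 0L)
  expect_identical(folds, stratified_folds(y, seed = 4))
  expect_false(identical(folds, stratified_folds(y, seed = 5)))
  expect_error(stratified_folds(c(rep(1, 5), rep(0, 50))), ">= 10")
})

test_that("SMOTE balances exactly and synthesizes convex combinations of neighbours", {
  set.seed(6)
  X <- matrix(rnorm(80 * 5), 80, 5)
  y <- c(rep(1, 20), rep(0, 60))
  out <- smote_oversample(X, y, k_neighbors = 5, seed = 3)
  expect_equal(sum(out$y == 1), 60)
  expect_equal(sum(out$y == 0), 60)
  # originals retained unmodified, in order
  expect_equal(unname(out$X[1:80, ]), unname(X))

  # geometric oracle: every synthetic point lies on a segment between two
  # real minority points; recover alpha from one coordinate and verify all
  minority <- X[y == 1, ]
  syn <- out$X[81:120, ]
  for (i in seq_len(nrow(syn))) {
    ok <- FALSE
    for (a in seq_len(nrow(minority))) {
      da <- syn[i, ] - minority[a, ]
      for (b in seq_len(nrow(minority))) {
        if (b == a) next
        dab <- minority[b, ] - minority[a, ]
        alpha <- sum(da * dab) / sum(dab * dab)
        if (alpha >= -1e-8 && alpha <= 1 + 1e-8 &&
            max(abs(da - alpha * dab)) < 1e-8) { ok <- TRUE; break }
      }
      if (ok) break
    }
    expect_true(ok, label = sprintf("synthetic point %d on a minority segment", i))
  }

  # already balanced -> unchanged
  yb <- rep(c(0, 1), 20)
  expect_identical(smote_oversample(X[1:40, ], yb, seed = 1)$X, X[1:40, ])
  expect_error(smote_oversample(X[c(1:4, 21:60), ], c(rep(1, 4), rep(0, 40))),
               "smaller k")
})

test_that("AUC equals the Mann-Whitney pair-counting oracle, with tie convention", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    y <- c(rep(1, 5), rep(0, n - 5))[sample(n)]
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(evaluate_scores(scores, y)$auc, oracle_auc(scores, y),
                 tolerance = 1e-12)
  }
  # perfect separation and constant scores
  expect_equal(evaluate_scores(c(.9, .8, .2, .1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(evaluate_scores(c(.9, .8, .2, .1), c(1, 1, 0, 0))$f1, 1)
  expect_equal(evaluate_scores(rep(.7, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(evaluate_scores(runif(4), c(1, 1, 1, 1)), "both classes")
})

test_that("early stopping halts after exactly patience stagnant epochs", {
  # validation set with identical duplicated features in both classes keeps
  # the validation AUC pinned at 0.5, so no epoch ever improves on epoch 1
  fx <- small_sim(seed = 31, n_samples = 60, n_genes = 10, n_pathways = 2)
  X <- feature_matrix(fx$data); y <- fx$data$label
  X_val <- rbind(rep(0.5, 10), rep(0.5, 10))
  y_val <- c(0, 1)
  mod <- init_model(pinnet_config(10, nrow(fx$mask$M), n_fc = 4, seed = 1),
                    fx$mask)
  fit <- fit_network(mod, X, y, X_val, y_val,
                     train_opts(max_epochs = 100, patience = 10, seed = 2))
  expect_equal(fit$epochs_run, 11)
  expect_equal(fit$best_epoch, 1)
})

test_that("training is deterministic and restores the best-epoch weights", {
  fx <- small_sim(seed = 41, n_samples = 80, n_genes = 20, n_pathways = 3)
  X <- feature_matrix(fx$data); y <- fx$data$label
  sp <- stratified_folds(y, seed = 1)[[1]]
  mod <- function() init_model(pinnet_config(20, nrow(fx$mask$M), n_fc = 8,
                                             seed = 5), fx$mask)
  o <- train_opts(max_epochs = 15, seed = 7)
  f1 <- fit_network(mod(), X[sp$train_idx, ], y[sp$train_idx],
                    X[sp$val_idx, ], y[sp$val_idx], o)
  f2 <- fit_network(mod(), X[sp$train_idx, ], y[sp$train_idx],
                    X[sp$val_idx, ], y[sp$val_idx], o)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  # restored weights reproduce the best validation AUC
  expect_equal(evaluate_model(f1, X[sp$val_idx, ], y[sp$val_idx])$auc,
               f1$best_val_auc)
  expect_equal(f1$best_val_auc, max(f1$history$val_auc))
})

test_that("masked weights receive no updates during training", {
  fx <- small_sim(seed = 51, n_samples = 60, n_genes = 15, n_pathways = 3)
  X <- feature_matrix(fx$data); y <- fx$data$label
  mod <- init_model(pinnet_config(15, nrow(fx$mask$M), n_fc = 4, seed = 3),
                    fx$mask)
  w0 <- mod$params$Wp
  fit <- fit_network(mod, X, y, X[1:10, ], y[1:10],
                     train_opts(max_epochs = 12, patience = 50, seed = 4))
  M <- fx$mask$M
  # raw masked entries untouched (zero gradient), so effective weights are 0
  expect_identical(fit$params$Wp[M == 0], w0[M == 0])
  expect_true(all((fit$params$Wp * M)[M == 0] == 0))
  # unmasked entries did move
  expect_gt(max(abs((fit$params$Wp - w0)[M == 1])), 0)
})

test_that("grid search selects on validation AUC and reports test metrics once", {
  fx <- small_sim(seed = 61, n_samples = 100, n_genes = 30, n_pathways = 4)
  sp <- stratified_folds(fx$data$label, seed = 2)[[1]]
  grid <- tibble::tibble(width = c(8L, 16L), lr = c(5e-4, 5e-4))
  out <- train_fold(fx$data, sp, fx$mask, grid = grid,
                    opts = train_opts(max_epochs = 10, seed = 3))
  expect_true(out$report$width %in% grid$width)
  expect_equal(out$report$best_val_auc, out$model$best_val_auc)
  expect_true(out$report$test_auc >= 0 && out$report$test_auc <= 1)
  expect_equal(nrow(out$report), 1)
})
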