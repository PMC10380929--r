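# Training machinery: stratified 10-fold splits (8:1:1), SMOTE class
# balancing, Adam with ReduceLROnPlateau and validation-AUC early stopping,
# grid search, and test-set evaluation (AUC, F1).

#' Stratified 10-fold train/validation/test splits
#'
#' Samples are dealt per class into `n_folds` stratified partitions. Fold k
#' uses partition k as the test set, the next partition (cyclically) as the
#' validation set, and the remaining partitions as the training set, giving
#' 8:1:1 proportions with the class ratio preserved in every part.
#'
#' @param labels 0/1 label vector.
#' @param n_folds Number of folds, default 10.
#' @param seed Seed controlling the within-class shuffles.
#' @return List of `n_folds` splits, each a list with `fold`, `train_idx`,
#'   `val_idx`, `test_idx` (row indices into `labels`).
#' @export
stratified_folds <- function(labels, n_folds = 10, seed = 1L) {
  y <- check_binary_labels(labels)
  counts <- table(y)
  if (any(counts < n_folds)) {
    abort(sprintf("every class needs >= %d samples for %d folds", n_folds, n_folds))
  }
  part <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      part[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  lapply(seq_len(n_folds), function(k) {
    val_part <- k %% n_folds + 1L
    list(fold = k,
         train_idx = which(part != k & part != val_part),
         val_idx = which(part == val_part),
         test_idx = which(part == k))
  })
}

#' SMOTE minority-class oversampling
#'
#' Balances the classes exactly by synthesizing minority samples on line
#' segments between a randomly chosen minority sample and one of its
#' `k_neighbors` nearest minority neighbours (Euclidean distance):
#' `x_new = x_i + alpha * (x_nb - x_i)` with `alpha ~ U(0, 1)`. Original
#' samples are retained unmodified and come first in the output.
#'
#' @param X Numeric matrix, samples x features.
#' @param y 0/1 labels.
#' @param k_neighbors Neighbourhood size, default 5.
#' @param seed Seed.
#' @return List with balanced `X` and `y`.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5, seed = 1L) {
  y <- check_binary_labels(y)
  counts <- table(factor(y, levels = c(0, 1)))
  if (counts[1] == counts[2]) return(list(X = X, y = y))
  minority <- if (counts["1"] < counts["0"]) 1L else 0L
  min_idx <- which(y == minority)
  if (length(min_idx) <= k_neighbors) {
    abort(sprintf("minority class has %d samples, <= k_neighbors = %d; use a smaller k",
                  length(min_idx), k_neighbors))
  }
  n_syn <- abs(diff(as.integer(counts)))
  Xm <- X[min_idx, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn_idx <- matrix(0L, nrow(D), k_neighbors)
  for (i in seq_len(nrow(D))) nn_idx[i, ] <- order(D[i, ])[seq_len(k_neighbors)]
  syn <- with_seed(seed, {
    base <- sample(seq_along(min_idx), n_syn, replace = TRUE)
    nb <- nn_idx[cbind(base, sample.int(k_neighbors, n_syn, replace = TRUE))]
    alpha <- runif(n_syn)
    Xm[base, , drop = FALSE] + alpha * (Xm[nb, , drop = FALSE] - Xm[base, , drop = FALSE])
  })
  rownames(syn) <- paste0("smote", seq_len(n_syn))
  list(X = rbind(X, syn), y = c(y, rep(minority, n_syn)))
}

#' Area under the ROC curve and F1 score
#'
#' AUC of the case-class score (trapezoidal, equivalent to the normalized
#' Mann-Whitney U with the half-credit tie convention); F1 of the case
#' class at the 0.5 threshold.
#'
#' @param scores Case-class probabilities or scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return One-row tibble with `auc` and `f1`.
#' @export
evaluate_scores <- function(scores, labels) {
  y <- check_binary_labels(labels)
  auc <- as.numeric(pROC::auc(response = y, predictor = as.numeric(scores),
                              levels = c(0, 1), direction = "<", quiet = TRUE))
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  tibble::tibble(auc = auc, f1 = f1)
}

#' Evaluate a model on a test set
#'
#' @param model A `pinnet_model`.
#' @param X_test,y_test Held-out samples and 0/1 labels.
#' @return One-row tibble with `auc` and `f1`.
#' @export
evaluate_model <- function(model, X_test, y_test) {
  evaluate_scores(nn_forward(model, X_test)$prob[, 2], y_test)
}

#' Training options
#'
#' @param lr Initial Adam learning rate.
#' @param batch_size Mini-batch size, default 64.
#' @param max_epochs Epoch cap, default 200.
#' @param patience Early-stopping patience: stop after this many epochs
#'   without a validation-AUC improvement, default 10.
#' @param sched_factor,sched_patience,min_lr ReduceLROnPlateau settings
#'   (monitor validation AUC, maximize): multiply the learning rate by
#'   `sched_factor` after `sched_patience` stagnant epochs, never below
#'   `min_lr`.
#' @param smote_k SMOTE neighbourhood size (`NULL` disables balancing).
#' @param seed Seed for shuffling, dropout and SMOTE.
#' @return A list of options for [fit_network()].
#' @export
train_opts <- function(lr = 5e-4, batch_size = 64, max_epochs = 200,
                       patience = 10, sched_factor = 0.5, sched_patience = 5,
                       min_lr = 1e-6, smote_k = 5, seed = 1L) {
  as.list(environment())
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Fit a network by Adam with early stopping on validation AUC
#'
#' Minimizes cross-entropy in mini-batches; after every epoch the
#' validation AUC is computed in evaluation mode. Training stops when the
#' validation AUC has not improved for `opts$patience` epochs (or at
#' `opts$max_epochs`), and the best-epoch weights are restored. A
#' plateau scheduler halves the learning rate after `opts$sched_patience`
#' stagnant epochs. Fully deterministic for fixed (data, options, model
#' seed).
#'
#' @param model A freshly initialized `pinnet_model`.
#' @param X,y Training samples (already SMOTE-balanced if desired).
#' @param X_val,y_val Validation samples.
#' @param opts Options from [train_opts()].
#' @return The fitted model, with a `history` tibble (epoch, train_loss,
#'   val_auc, lr) and `best_val_auc`/`epochs_run` attached.
#' @export
fit_network <- function(model, X, y, X_val, y_val, opts = train_opts()) {
  y <- check_binary_labels(y)
  prm <- model$params
  state <- list(t = 0,
                m = lapply(prm, function(p) p * 0),
                v = lapply(prm, function(p) p * 0))
  lr <- opts$lr
  best_auc <- -Inf
  best_params <- prm
  best_epoch <- 0L
  stall <- 0L; sched_stall <- 0L
  hist <- vector("list", opts$max_epochs)
  n <- nrow(X)
  with_seed(derive_seed(opts$seed, "fit"), {
    for (epoch in seq_len(opts$max_epochs)) {
      perm <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = opts$batch_size)) {
        idx <- perm[start:min(start + opts$batch_size - 1, n)]
        fw <- nn_forward(model, X[idx, , drop = FALSE], training = TRUE,
                         keep_cache = TRUE)
        loss <- cross_entropy(fw$prob, y[idx])
        if (!is.finite(loss)) {
          abort("non-finite training loss", class = "pinnet_diverged")
        }
        grads <- nn_backward(model, fw$cache, fw$prob, y[idx])
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params
        state <- upd$state
        losses <- c(losses, loss)
      }
      val_auc <- evaluate_model(model, X_val, y_val)$auc
      hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                      train_loss = mean(losses),
                                      val_auc = val_auc, lr = lr)
      if (val_auc > best_auc) {
        best_auc <- val_auc
        best_params <- model$params
        best_epoch <- epoch
        stall <- 0L; sched_stall <- 0L
      } else {
        stall <- stall + 1L
        sched_stall <- sched_stall + 1L
        if (sched_stall >= opts$sched_patience) {
          lr <- max(lr * opts$sched_factor, opts$min_lr)
          sched_stall <- 0L
        }
        if (stall >= opts$patience) break
      }
    }
  })
  model$params <- best_params
  model$history <- dplyr::bind_rows(hist)
  model$best_val_auc <- best_auc
  model$best_epoch <- best_epoch
  model$epochs_run <- nrow(model$history)
  model
}

#' Train one cross-validation fold with grid search
#'
#' For every grid point the training split is SMOTE-balanced, a fresh
#' network is trained with early stopping on the validation AUC, and the
#' grid point with the best validation AUC is selected (first on ties).
#' Test AUC/F1 are computed once, on the untouched test split, after model
#' selection. Grid points whose training diverges are skipped with a
#' warning.
#'
#' @param data Dataset tibble with `label`.
#' @param split One element of [stratified_folds()].
#' @param mask `pinnet_mask`, or `NULL` for the unmasked DNN baseline.
#' @param grid Tibble with columns `width` (fully connected branch width
#'   for the pathway model; first-layer width for the baseline) and `lr`.
#'   Defaults to the model's full search grid.
#' @param opts [train_opts()]; `opts$seed` drives all fold randomness.
#' @param norm_mode Pathway-size normalization mode.
#' @return List with `report` (one-row tibble: fold, width, lr,
#'   best_val_auc, epochs_run, test_auc, test_f1) and `model` (the selected
#'   fitted network).
#' @export
train_fold <- function(data, split, mask = NULL, grid = NULL,
                       opts = train_opts(), norm_mode = "inverse_sqrt") {
  X <- feature_matrix(data)
  y <- check_binary_labels(data$label)
  grid <- grid %||% default_grid(!is.null(mask))
  bal <- if (!is.null(opts$smote_k)) {
    smote_oversample(X[split$train_idx, , drop = FALSE], y[split$train_idx],
                     k_neighbors = opts$smote_k,
                     seed = derive_seed(opts$seed, paste0("smote", split$fold)))
  } else {
    list(X = X[split$train_idx, , drop = FALSE], y = y[split$train_idx])
  }
  best <- NULL
  for (gi in seq_len(nrow(grid))) {
    w <- grid$width[gi]; lr <- grid$lr[gi]
    o <- opts; o$lr <- lr
    o$seed <- derive_seed(opts$seed, paste0("fold", split$fold, "grid", gi))
    model <- if (!is.null(mask)) {
      init_model(pinnet_config(n_genes = ncol(X), n_pathways = nrow(mask$M),
                               n_fc = w, norm_mode = norm_mode, seed = o$seed),
                 mask)
    } else {
      build_baseline_dnn(ncol(X), n_hidden1 = w, seed = o$seed)
    }
    fitted <- tryCatch(
      fit_network(model, bal$X, bal$y,
                  X[split$val_idx, , drop = FALSE], y[split$val_idx], o),
      pinnet_diverged = function(e) {
        warn(sprintf("fold %d grid point (width=%d, lr=%g) diverged; skipped",
                     split$fold, w, lr))
        NULL
      })
    if (is.null(fitted)) next
    if (is.null(best) || fitted$best_val_auc > best$val_auc) {
      best <- list(model = fitted, val_auc = fitted$best_val_auc,
                   width = w, lr = lr)
    }
  }
  if (is.null(best)) abort("all grid points diverged")
  test_metrics <- evaluate_model(best$model, X[split$test_idx, , drop = FALSE],
                                 y[split$test_idx])
  report <- tibble::tibble(fold = split$fold, width = best$width, lr = best$lr,
                           best_val_auc = best$val_auc,
                           epochs_run = best$model$epochs_run,
                           test_auc = test_metrics$auc,
                           test_f1 = test_metrics$f1)
  list(report = report, model = best$model)
}

#' Default hyperparameter grids
#'
#' Pathway model: fully connected branch width in {32, 64, 128}; baseline
#' DNN: first-layer width in {128, 512, 1024, 4096}; learning rate in
#' {1e-4, 5e-4, 1e-3} for both.
#'
#' @param pathway_model Grid for the pathway-informed model (`TRUE`) or the
#'   baseline (`FALSE`)?
#' @return Tibble with columns `width` and `lr`.
#' @export
default_grid <- function(pathway_model = TRUE) {
  widths <- if (pathway_model) c(32L, 64L, 128L) else c(128L, 512L, 1024L, 4096L)
  tidyr::expand_grid(width = widths, lr = c(1e-4, 5e-4, 1e-3))
}

#' Stratified 10-fold cross-validation of the classifier
#'
#' Runs [train_fold()] on each of the 10 stratified 8:1:1 splits and
#' collects per-fold reports and fitted models.
#'
#' @inheritParams train_fold
#' @param n_folds Number of folds, default 10.
#' @param seed Seed for the fold assignment and all fold-level randomness.
#' @return A `pinnet_cv` object: list with `reports` (tibble, one row per
#'   fold), `models`, `splits`, `seed`.
#' @export
cross_validate <- function(data, mask = NULL, grid = NULL, opts = train_opts(),
                           n_folds = 10, seed = 1L,
                           norm_mode = "inverse_sqrt") {
  splits <- stratified_folds(data$label, n_folds = n_folds,
                             seed = derive_seed(seed, "folds"))
  opts$seed <- seed
  fits <- lapply(splits, function(sp) {
    train_fold(data, sp, mask = mask, grid = grid, opts = opts,
               norm_mode = norm_mode)
  })
  structure(list(reports = dplyr::bind_rows(lapply(fits, `[[`, "report")),
                 models = lapply(fits, `[[`, "model"),
                 splits = splits, seed = seed),
            class = "pinnet_cv")
}

#' @export
print.pinnet_cv <- function(x, ...) {
  cat(sprintf("<pinnet_cv> %d folds | mean test AUC %.3f | mean test F1 %.3f\n",
              nrow(x$reports), mean(x$reports$test_auc), mean(x$reports$test_f1)))
  invisible(x)
}
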