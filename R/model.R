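# The pathway-informed network (PINNet) and its unmasked relatives.
#
# Architecture (branch network): gene input g (length n) feeds two parallel
# branches — a pathway branch p = tanh(((Wp o M) g) * u) whose weight matrix
# is element-wise masked by the binary pathway membership matrix M and
# rescaled per pathway by the size-normalization u, and a fully connected
# branch f = tanh(Wf g + bf). Each branch is layer-normalized, the branches
# are concatenated, passed through dropout, a tanh hidden layer, dropout
# again, and a 2-logit softmax head. The unmasked DNN baseline and the
# feature-selection MLP are the same pipeline with the pathway branch
# removed. The mask is re-applied inside every forward pass, so masked
# weights can never leak in, whatever the optimizer does.

LN_EPS <- 1e-5

#' Network configuration
#'
#' @param n_genes Number of input genes (n).
#' @param n_pathways Number of pathway nodes (m); 0 gives the unmasked
#'   baseline.
#' @param n_fc Width of the fully connected branch (grid candidates 32, 64,
#'   128 for the pathway-informed model).
#' @param n_hidden Width of the second hidden layer; fixed at 64 for the
#'   classifier comparisons.
#' @param dropout_rate Dropout probability on the concatenated layer and the
#'   hidden layer, default 0.3.
#' @param norm_mode Pathway-size normalization mode (see
#'   [normalization_vector()]).
#' @param seed Seed for weight initialization.
#' @param activation `"tanh"` (default) or `"identity"` (linear test
#'   fixture).
#' @param use_layernorm Apply per-branch layer normalization before
#'   concatenation? Default `TRUE`; `FALSE` is a test fixture.
#' @return A `pinnet_config` list.
#' @export
pinnet_config <- function(n_genes, n_pathways, n_fc = 64, n_hidden = 64,
                          dropout_rate = 0.3,
                          norm_mode = c("inverse_sqrt", "inverse", "none"),
                          seed = 1L, activation = c("tanh", "identity"),
                          use_layernorm = TRUE) {
  norm_mode <- match.arg(norm_mode)
  activation <- match.arg(activation)
  if (n_genes < 1 || n_fc < 1 || n_hidden < 1 || n_pathways < 0) {
    abort("layer widths must be positive (n_pathways may be 0)")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0,1)")
  structure(list(n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 n_fc = as.integer(n_fc), n_hidden = as.integer(n_hidden),
                 dropout_rate = dropout_rate, norm_mode = norm_mode,
                 seed = as.integer(seed), activation = activation,
                 use_layernorm = use_layernorm),
            class = "pinnet_config")
}

glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_out * n_in, -lim, lim), n_out, n_in)
}

#' Initialize a pathway-informed network
#'
#' All weight matrices are Xavier (Glorot-uniform) initialized from
#' `cfg$seed`; layer-norm gains start at 1 and shifts at 0; the pathway
#' branch has no bias (its pre-activation is exactly `((Wp o M) g) * u`),
#' all other layers carry biases. Initialization is bit-reproducible from
#' the seed.
#'
#' @param cfg A [pinnet_config()].
#' @param mask A `pinnet_mask` matching `cfg` (`NULL` when
#'   `cfg$n_pathways == 0`).
#' @return A `pinnet_model`.
#' @export
init_model <- function(cfg, mask = NULL) {
  stopifnot(inherits(cfg, "pinnet_config"))
  m <- cfg$n_pathways
  if (m > 0) {
    if (is.null(mask)) abort("a mask is required when n_pathways > 0")
    if (!all(dim(mask$M) == c(m, cfg$n_genes))) {
      abort(sprintf("mask is %d x %d but config expects %d x %d",
                    nrow(mask$M), ncol(mask$M), m, cfg$n_genes))
    }
  } else {
    mask <- NULL
  }
  n <- cfg$n_genes; nf <- cfg$n_fc; h <- cfg$n_hidden
  u <- if (m > 0) normalization_vector(mask, cfg$norm_mode) else numeric(0)
  params <- with_seed(cfg$seed, {
    p <- list()
    if (m > 0) {
      p$Wp <- glorot(m, n)
      p$ln_g_p <- rep(1, m); p$ln_b_p <- rep(0, m)
    }
    p$Wf <- glorot(nf, n); p$bf <- rep(0, nf)
    p$ln_g_f <- rep(1, nf); p$ln_b_f <- rep(0, nf)
    p$Wh <- glorot(h, m + nf); p$bh <- rep(0, h)
    p$Wo <- glorot(2, h); p$bo <- rep(0, 2)
    p
  })
  structure(list(cfg = cfg, mask = mask, u = u, params = params),
            class = "pinnet_model")
}

#' Build the unmasked DNN baseline
#'
#' Identical pipeline with the masked pathway branch replaced by a single
#' fully connected first layer of width `n_hidden1` (grid candidates 128,
#' 512, 1024, 4096), followed by the same layer normalization, dropout,
#' 64-node hidden layer and softmax head.
#'
#' @param n_genes Input width.
#' @param n_hidden1 First-layer width.
#' @param n_hidden2 Second hidden layer width, default 64.
#' @param seed Initialization seed.
#' @param ... Passed to [pinnet_config()].
#' @return A `pinnet_model` with no pathway branch.
#' @export
build_baseline_dnn <- function(n_genes, n_hidden1 = 128, n_hidden2 = 64,
                               seed = 1L, ...) {
  init_model(pinnet_config(n_genes = n_genes, n_pathways = 0L,
                           n_fc = n_hidden1, n_hidden = n_hidden2,
                           seed = seed, ...))
}

#' Build the feature-selection MLP
#'
#' Four-layer perceptron with widths `{n, n/2, n/4, 2}` (ceilings for odd
#' n), realized in the same pipeline as the baseline.
#'
#' @param n_genes Input width n.
#' @param seed Initialization seed.
#' @param ... Passed to [pinnet_config()].
#' @return A `pinnet_model`.
#' @export
build_mlp <- function(n_genes, seed = 1L, ...) {
  init_model(pinnet_config(n_genes = n_genes, n_pathways = 0L,
                           n_fc = max(1L, as.integer(ceiling(n_genes / 2))),
                           n_hidden = max(1L, as.integer(ceiling(n_genes / 4))),
                           seed = seed, ...))
}

act_fun <- function(z, activation) if (activation == "tanh") tanh(z) else z
act_grad <- function(a, activation) if (activation == "tanh") 1 - a^2 else a * 0 + 1

# Layer normalization over the nodes of one branch, per sample.
layernorm_forward <- function(A, gamma, beta) {
  mu <- rowMeans(A)
  C <- A - mu
  v <- rowMeans(C^2)
  inv <- 1 / sqrt(v + LN_EPS)
  Nrm <- C * inv
  list(out = sweep(Nrm, 2, gamma, "*") + rep(beta, each = nrow(A)),
       C = C, v = v, inv = inv, Nrm = Nrm)
}

layernorm_backward <- function(dOut, cache, gamma) {
  dgamma <- colSums(dOut * cache$Nrm)
  dbeta <- colSums(dOut)
  dN <- sweep(dOut, 2, gamma, "*")
  dA <- cache$inv * (dN - rowMeans(dN) - cache$Nrm * rowMeans(dN * cache$Nrm))
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

effective_pathway_weights <- function(model) {
  if (model$cfg$n_pathways == 0) return(NULL)
  model$params$Wp * model$mask$M
}

#' Forward pass
#'
#' Computes class probabilities (and all intermediate activations when
#' `keep_cache = TRUE`). Evaluation mode (`training = FALSE`) is
#' deterministic; training mode applies inverted dropout.
#'
#' @param model A `pinnet_model`.
#' @param X Numeric matrix, samples x genes.
#' @param training Apply dropout?
#' @param keep_cache Return intermediates for backprop/attribution?
#' @return List with `prob` (samples x 2, columns control/case) and, if
#'   requested, the activation cache.
#' @export
nn_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (any(!is.finite(X))) abort("non-finite values in the input")
  cfg <- model$cfg; prm <- model$params
  if (ncol(X) != cfg$n_genes) abort("input width does not match n_genes")
  B <- nrow(X)
  m <- cfg$n_pathways
  cache <- list(X = X)

  if (m > 0) {
    WpM <- prm$Wp * model$mask$M
    Zp_raw <- X %*% t(WpM)
    Zp <- sweep(Zp_raw, 2, model$u, "*")
    P <- act_fun(Zp, cfg$activation)
    if (cfg$use_layernorm) {
      lnp <- layernorm_forward(P, prm$ln_g_p, prm$ln_b_p)
      LNp <- lnp$out
    } else {
      lnp <- NULL; LNp <- P
    }
    cache$WpM <- WpM; cache$Zp <- Zp; cache$P <- P; cache$lnp <- lnp
  } else {
    LNp <- NULL
  }

  Zf <- X %*% t(prm$Wf) + rep(prm$bf, each = B)
  Fc <- act_fun(Zf, cfg$activation)
  if (cfg$use_layernorm) {
    lnf <- layernorm_forward(Fc, prm$ln_g_f, prm$ln_b_f)
    LNf <- lnf$out
  } else {
    lnf <- NULL; LNf <- Fc
  }
  cache$Zf <- Zf; cache$Fc <- Fc; cache$lnf <- lnf

  H0 <- if (m > 0) cbind(LNp, LNf) else LNf
  cache$H0 <- H0
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    D1 <- matrix(rbinom(length(H0), 1, keep) / keep, nrow(H0), ncol(H0))
    H0d <- H0 * D1
  } else {
    D1 <- NULL; H0d <- H0
  }
  cache$D1 <- D1; cache$H0d <- H0d

  Zh <- H0d %*% t(prm$Wh) + rep(prm$bh, each = B)
  Hh <- act_fun(Zh, cfg$activation)
  cache$Zh <- Zh; cache$Hh <- Hh
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    D2 <- matrix(rbinom(length(Hh), 1, keep) / keep, nrow(Hh), ncol(Hh))
    Hd <- Hh * D2
  } else {
    D2 <- NULL; Hd <- Hh
  }
  cache$D2 <- D2; cache$Hd <- Hd

  Zo <- Hd %*% t(prm$Wo) + rep(prm$bo, each = B)
  Zo_shift <- Zo - apply(Zo, 1, max)
  E <- exp(Zo_shift)
  prob <- E / rowSums(E)
  colnames(prob) <- c("control", "case")
  cache$Zo <- Zo
  out <- list(prob = prob)
  if (keep_cache) out$cache <- cache
  out
}

#' Class-probability predictions as a tibble
#'
#' @param object A `pinnet_model`.
#' @param data Dataset tibble or numeric matrix (samples x genes).
#' @param ... Unused.
#' @return Tibble with `sample_id`, `p_control`, `p_case`.
#' @export
predict.pinnet_model <- function(object, data, ...) {
  X <- if (is.matrix(data)) data else feature_matrix(data)
  pr <- nn_forward(object, X)$prob
  tibble::tibble(sample_id = rownames(X) %||% paste0("s", seq_len(nrow(X))),
                 p_control = pr[, 1], p_case = pr[, 2])
}

#' Pathway-branch activations
#'
#' `p = tanh(((Wp o M) g) * u)`: each pathway node only sees its member
#' genes, scaled by the size normalization.
#'
#' @param model A `pinnet_model` with a pathway branch.
#' @param g A gene vector (length n) or matrix (samples x n).
#' @return Matrix samples x m of pathway-node activations.
#' @export
forward_pathway <- function(model, g) {
  if (model$cfg$n_pathways == 0) abort("model has no pathway branch")
  if (!is.matrix(g)) g <- matrix(g, nrow = 1)
  if (any(!is.finite(g))) abort("non-finite values in the input")
  Zp <- sweep(g %*% t(effective_pathway_weights(model)), 2, model$u, "*")
  act_fun(Zp, model$cfg$activation)
}

#' Fully connected branch activations
#'
#' `f = tanh(Wf g + bf)`.
#'
#' @inheritParams forward_pathway
#' @return Matrix samples x n_fc.
#' @export
forward_fc <- function(model, g) {
  if (!is.matrix(g)) g <- matrix(g, nrow = 1)
  if (any(!is.finite(g))) abort("non-finite values in the input")
  Zf <- g %*% t(model$params$Wf) + rep(model$params$bf, each = nrow(g))
  act_fun(Zf, model$cfg$activation)
}

# Gradients of the mean cross-entropy over a batch. `cache` must come from
# nn_forward(..., training = TRUE (or FALSE), keep_cache = TRUE) on the same
# parameters; `y` is the 0/1 label vector.
nn_backward <- function(model, cache, prob, y) {
  cfg <- model$cfg; prm <- model$params
  B <- nrow(cache$X)
  m <- cfg$n_pathways
  Y <- cbind(1 - y, y)
  dZo <- (prob - Y) / B
  grads <- list(Wo = t(dZo) %*% cache$Hd, bo = colSums(dZo))
  dHd <- dZo %*% prm$Wo
  dHh <- if (!is.null(cache$D2)) dHd * cache$D2 else dHd
  dZh <- dHh * act_grad(cache$Hh, cfg$activation)
  grads$Wh <- t(dZh) %*% cache$H0d
  grads$bh <- colSums(dZh)
  dH0d <- dZh %*% prm$Wh
  dH0 <- if (!is.null(cache$D1)) dH0d * cache$D1 else dH0d

  nf <- cfg$n_fc
  if (m > 0) {
    dLNp <- dH0[, seq_len(m), drop = FALSE]
    dLNf <- dH0[, m + seq_len(nf), drop = FALSE]
    if (cfg$use_layernorm) {
      lb <- layernorm_backward(dLNp, cache$lnp, prm$ln_g_p)
      dP <- lb$dA; grads$ln_g_p <- lb$dgamma; grads$ln_b_p <- lb$dbeta
    } else {
      dP <- dLNp
    }
    dZp <- dP * act_grad(cache$P, cfg$activation)
    dZp_raw <- sweep(dZp, 2, model$u, "*")
    grads$Wp <- (t(dZp_raw) %*% cache$X) * model$mask$M
  } else {
    dLNf <- dH0
  }
  if (cfg$use_layernorm) {
    lb <- layernorm_backward(dLNf, cache$lnf, prm$ln_g_f)
    dF <- lb$dA; grads$ln_g_f <- lb$dgamma; grads$ln_b_f <- lb$dbeta
  } else {
    dF <- dLNf
  }
  dZf <- dF * act_grad(cache$Fc, cfg$activation)
  grads$Wf <- t(dZf) %*% cache$X
  grads$bf <- colSums(dZf)
  grads
}

cross_entropy <- function(prob, y) {
  eps <- 1e-12
  -mean(log(pmax(ifelse(y == 1, prob[, 2], prob[, 1]), eps)))
}

#' @export
print.pinnet_model <- function(x, ...) {
  cfg <- x$cfg
  kind <- if (cfg$n_pathways > 0) "pathway-informed network" else "fully connected network"
  cat(sprintf("<pinnet_model> %s: %d genes -> [%s%d fc] -> %d -> 2\n",
              kind, cfg$n_genes,
              if (cfg$n_pathways > 0) paste0(cfg$n_pathways, " pathway + ") else "",
              cfg$n_fc, cfg$n_hidden))
  invisible(x)
}
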