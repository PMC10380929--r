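test_that("initialization is seed-deterministic and honours the mask", {
  mask <- tiny_mask()
  cfg <- pinnet_config(4, 2, n_fc = 3, seed = 7)
  m1 <- init_model(cfg, mask)
  m2 <- init_model(cfg, mask)
  expect_identical(m1$params, m2$params)

  eff <- m1$params$Wp * mask$M
  expect_true(all(eff[mask$M == 0] == 0))
  expect_equal(sum(mask$M[1, ]), 2)  # row P1 has exactly 2 free weights

  expect_error(init_model(pinnet_config(5, 2), mask), "mask is")
})

test_that("forward pass matches an independent scalar-loop oracle", {
  mask <- tiny_mask()
  set.seed(1)
  for (rep in 1:3) {
    mod <- init_model(pinnet_config(4, 2, n_fc = 3, n_hidden = 5,
                                    seed = 100 + rep), mask)
    x <- runif(4)
    got <- nn_forward(mod, matrix(x, 1))$prob
    expect_equal(as.numeric(got), oracle_forward(mod, x), tolerance = 1e-6)
  }
})

test_that("pathway branch follows p = tanh(((Wp o M) g) * u)", {
  mask <- tiny_mask()
  mod <- init_model(pinnet_config(4, 2, seed = 3), mask)
  # zero input -> zero activations on both branches (pathway branch is bias-free)
  expect_equal(as.numeric(forward_pathway(mod, rep(0, 4))), c(0, 0))

  # hand-built single pathway {g1, g2}, unit weights, u = 1/sqrt(2)
  mod$params$Wp <- rbind(c(1, 1, 99, 99), c(0, 0, 0, 0))
  g <- c(1, 1, 5, 0)
  p <- forward_pathway(mod, g)
  expect_equal(unname(p[1, 1]), tanh(2 / sqrt(2)))
  # g3 is masked out of pathway 1: perturbing it leaves the node unchanged
  g2 <- c(1, 1, -40, 0)
  expect_identical(forward_pathway(mod, g2)[1, 1], p[1, 1])

  # normalization mode ratio: pre-activation with mode none vs inverse on a
  # 4-gene pathway differs by exactly the pathway size
  col4 <- tibble::tibble(pathway = "Q", description = "d",
                         genes = list(paste0("g", 1:4)))
  m_none <- init_model(pinnet_config(4, 1, seed = 5, norm_mode = "none"),
                       build_mask(col4, paste0("g", 1:4), "none"))
  m_inv <- m_none
  m_inv$u <- normalization_vector(m_none$mask, "inverse")
  x <- runif(4)
  pre_none <- atanh(forward_pathway(m_none, x))
  pre_inv <- atanh(forward_pathway(m_inv, x))
  expect_equal(as.numeric(pre_none / pre_inv), 4, tolerance = 1e-9)
})

test_that("fully connected branch equals tanh(Wf g + bf) and stays in (-1,1)", {
  mod <- init_model(pinnet_config(4, 2, n_fc = 3, seed = 9), tiny_mask())
  x <- runif(4)
  expect_equal(as.numeric(forward_fc(mod, x)),
               as.numeric(tanh(mod$params$Wf %*% x + mod$params$bf)),
               tolerance = 1e-6)
  expect_true(all(abs(forward_fc(mod, x)) < 1))
  expect_equal(as.numeric(forward_fc(mod, rep(0, 4))),
               as.numeric(tanh(mod$params$bf)))
  expect_error(forward_fc(mod, c(1, NA, 2, 3)), "non-finite")
})

test_that("evaluation-mode forward is deterministic with softmax rows summing to 1", {
  fx <- small_sim(seed = 21)
  mod <- init_model(pinnet_config(length(feature_names(fx$data)),
                                  nrow(fx$mask$M), seed = 2), fx$mask)
  X <- feature_matrix(fx$data)[1:7, ]
  p1 <- nn_forward(mod, X)$prob
  p2 <- nn_forward(mod, X)$prob
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1)), rep(1, 7), tolerance = 1e-6)
})

test_that("genes excluded from all pathways cannot reach any pathway node", {
  fx <- small_sim(seed = 8)
  mask <- fx$mask
  free <- which(colSums(mask$M) == 0)
  skip_if(length(free) == 0, "fixture has no pathway-free gene")
  mod <- init_model(pinnet_config(ncol(mask$M), nrow(mask$M), seed = 4), mask)
  x <- runif(ncol(mask$M))
  x2 <- x; x2[free[1]] <- x2[free[1]] + 10
  expect_identical(forward_pathway(mod, x), forward_pathway(mod, x2))
  # but the fully connected branch does see it
  expect_false(isTRUE(all.equal(forward_fc(mod, x), forward_fc(mod, x2))))
})

test_that("backpropagation gradients match central finite differences", {
  mask <- tiny_mask()
  mod <- init_model(pinnet_config(4, 2, n_fc = 3, n_hidden = 5,
                                  dropout_rate = 0, seed = 7), mask)
  set.seed(2)
  X <- matrix(runif(6 * 4), 6, 4)
  y <- c(0, 1, 0, 1, 1, 0)
  fw <- pinnet:::nn_forward(mod, X, training = TRUE, keep_cache = TRUE)
  gr <- pinnet:::nn_backward(mod, fw$cache, fw$prob, y)
  loss_at <- function(m) pinnet:::cross_entropy(pinnet:::nn_forward(m, X)$prob, y)
  eps <- 1e-6
  for (nm in names(gr)) {
    idx <- seq_len(min(length(mod$params[[nm]]), 6))
    for (i in idx) {
      up <- mod; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- mod; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(as.numeric(gr[[nm]][i]), num, tolerance = 1e-5,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("baseline DNN has the documented parameter count and seed determinism", {
  d1 <- build_baseline_dnn(100, n_hidden1 = 128, seed = 3)
  d2 <- build_baseline_dnn(100, n_hidden1 = 128, seed = 3)
  expect_identical(d1$params, d2$params)
  n_par <- sum(vapply(d1$params, length, numeric(1)))
  # closed form: W1 + b1 + 2 LN vectors + Wh + bh + Wo + bo
  expect_equal(n_par,
               128 * 100 + 128 + 2 * 128 + 64 * 128 + 64 + 2 * 64 + 2)
  pr <- nn_forward(d1, matrix(runif(300), 3, 100))$prob
  expect_equal(unname(rowSums(pr)), rep(1, 3), tolerance = 1e-6)
})

test_that("pathway-node variance is size-independent under inverse_sqrt scaling", {
  # pre-activation variance over random Xavier draws for a size-10 vs a
  # size-1000 pathway, same input
  set.seed(99)
  n <- 1200
  sizes <- c(10, 1000)
  x <- runif(n)
  draws <- sapply(sizes, function(k) {
    M <- c(rep(1, k), rep(0, n - k))
    u <- 1 / sqrt(k)
    lim <- sqrt(6 / (n + 1))
    vapply(seq_len(1000), function(i) {
      w <- runif(n, -lim, lim)
      sum(w * M * x) * u
    }, numeric(1))
  })
  ratio <- var(draws[, 1]) / var(draws[, 2])
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.4)
})
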