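test_that("graph-learning layer matches scalar hand evaluation", {
  # identical rows -> uniform over the prior's support
  A <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))
  X <- matrix(1, 3, 2)
  par <- list(P = matrix(c(1, 1), 2, 1), a = 0.7)
  S <- graph_learning_layer(X, A, par)
  expect_equal(S, A / rowSums(A))

  # 3-node chain, scalar features [0], [1], [10], P = 1, a = 1:
  # hand-evaluate every entry of the masked softmax
  Ac <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))
  Xc <- matrix(c(0, 1, 10), 3, 1)
  parc <- list(P = matrix(1, 1, 1), a = 1)
  Sc <- graph_learning_layer(Xc, Ac, parc)
  Shand <- matrix(0, 3, 3)
  g <- c(0, 1, 10)
  for (i in 1:3) {
    e <- numeric(3)
    for (j in 1:3) e[j] <- Ac[i, j] * exp(max(abs(g[i] - g[j]), 0))
    Shand[i, ] <- e / sum(e)
  }
  expect_equal(Sc, Shand, tolerance = 1e-10)

  # structural invariants: rows sum to 1, support within the prior
  set.seed(3)
  for (rep in 1:5) {
    n <- 6
    Ar <- matrix(rbinom(n * n, 1, 0.4), n, n)
    Ar <- 1 * ((Ar + t(Ar)) > 0); diag(Ar) <- 1
    Xr <- matrix(rnorm(n * 4), n, 4)
    parr <- list(P = matrix(rnorm(8), 4, 2), a = rnorm(2))
    Sr <- graph_learning_layer(Xr, Ar, parr)
    expect_equal(rowSums(Sr), rep(1, n), tolerance = 1e-6)
    expect_true(all(Sr >= 0))
    expect_true(all(Sr[Ar == 0] == 0))
  }

  expect_error(graph_learning_layer(matrix(1, 2, 3), diag(2),
                                    list(P = matrix(1, 2, 1), a = 1)),
               "mismatch")
})

test_that("graph-learning loss matches hand evaluation", {
  # identical features, gamma = 0 -> 0
  X <- matrix(1, 3, 2)
  S <- matrix(1 / 3, 3, 3)
  expect_equal(graph_learning_loss(X, S, gamma = 0), 0)

  # S = identity: distance term vanishes, Frobenius term = p
  X2 <- matrix(rnorm(8), 4, 2)
  expect_equal(graph_learning_loss(X2, diag(4), gamma = 1), 4)

  # 2-node hand case: features 0 and 2, S all 1/2, gamma 0:
  # sum_ij ||g_i - g_j||^2 S_ij = 4 * 0.5 + 4 * 0.5 = 4
  expect_equal(
    graph_learning_loss(matrix(c(0, 2), 2, 1),
                        matrix(0.5, 2, 2), gamma = 0), 4)
})

test_that("graph convolution is sigma(S X W) with no extra normalization", {
  X <- matrix(rnorm(6), 3, 2)
  expect_equal(graph_conv(X, diag(3), diag(2), identity), X)

  # constant column preserved by any row-stochastic S (before W)
  S <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE)
  Xc <- cbind(c(3, 3), c(1, 2))
  expect_equal(graph_conv(Xc, S, diag(2), identity)[, 1], c(3, 3))

  # 2x2 hand example with ReLU
  expect_equal(
    graph_conv(matrix(c(1, 3), 2, 1),
               rbind(c(1, 0), c(0.5, 0.5)),
               matrix(2, 1, 1), function(x) pmax(x, 0)),
    matrix(c(2, 4), 2, 1))

  expect_error(graph_conv(matrix(1, 3, 2), diag(2), diag(2)), "mismatch")
})

test_that("cross-entropy and joint loss match closed forms", {
  # perfect one-hot prediction -> 0 (up to clipping)
  Z <- rbind(c(1, 0), c(0, 1))
  Y <- rbind(c(1, 0), c(0, 1))
  expect_lt(cross_entropy_loss(Z, Y), 1e-10)

  # uniform prediction, one sample -> ln 2
  expect_equal(cross_entropy_loss(matrix(0.5, 1, 2), matrix(c(1, 0), 1)),
               log(2))

  # hand case: row (0.8, 0.2), true class 1 -> -ln 0.8
  expect_equal(cross_entropy_loss(matrix(c(0.8, 0.2), 1), matrix(c(1, 0), 1)),
               -log(0.8), tolerance = 1e-12)

  expect_equal(total_loss(4, log(2), lambda = 1), 4 + log(2))
  expect_equal(total_loss(4, log(2), lambda = 0), 4)
  expect_error(total_loss(1, 1, lambda = -1), "nonnegative")
})

test_that("analytic L1 gradients match finite differences", {
  # 4-node instance; differentiate the training objective with lambda = 0
  # (pure graph-learning loss) w.r.t. P and a through the masked softmax
  set.seed(11)
  n <- 4
  A <- rbind(c(1, 1, 0, 1), c(1, 1, 1, 0), c(0, 1, 1, 1), c(1, 0, 1, 1))
  X <- matrix(rnorm(n * 3), n, 3)
  cfg <- pglcn_config(mode = "transductive", embed_dim = 2, hidden = 4L,
                      gamma = 0.05, lambda = 0, seed = 1)
  params <- pglcn:::init_pglcn_params(cfg, f = 3, c = 2)
  se <- pglcn:::support_edges(A)
  d2 <- rowSums((X[se$ii, ] - X[se$jj, ])^2)

  pass <- pglcn:::engine_pass(X, se$ii, se$jj, d2, c(1, 2, 1, 2), 1:4,
                              params, cfg)
  lossP <- function(P) {
    p2 <- params; p2$P <- P
    pglcn:::engine_pass(X, se$ii, se$jj, d2, c(1, 2, 1, 2), 1:4, p2, cfg,
                        want_grads = FALSE)$L1
  }
  lossA <- function(a) {
    p2 <- params; p2$a <- a
    pglcn:::engine_pass(X, se$ii, se$jj, d2, c(1, 2, 1, 2), 1:4, p2, cfg,
                        want_grads = FALSE)$L1
  }
  gP_num <- finite_diff(lossP, params$P)
  ga_num <- finite_diff(lossA, params$a)
  expect_lt(max(abs(pass$grads$P - gP_num)) / max(abs(gP_num)), 1e-4)
  expect_lt(max(abs(pass$grads$a - ga_num)) / max(abs(ga_num)), 1e-4)
})

test_that("full-objective gradients match finite differences", {
  set.seed(12)
  n <- 5
  A <- matrix(rbinom(n * n, 1, 0.5), n, n)
  A <- 1 * ((A + t(A)) > 0); diag(A) <- 1
  X <- matrix(rnorm(n * 3), n, 3)
  y <- c(1, 2, 1, 2, 1)
  cfg <- pglcn_config(mode = "transductive", embed_dim = 2, hidden = 3L,
                      gamma = 0.02, lambda = 1.5, seed = 4)
  params <- pglcn:::init_pglcn_params(cfg, f = 3, c = 2)
  se <- pglcn:::support_edges(A)
  d2 <- rowSums((X[se$ii, ] - X[se$jj, ])^2)
  pass <- pglcn:::engine_pass(X, se$ii, se$jj, d2, y, 1:4, params, cfg)
  for (nm in c("Wc1", "bc2", "P")) {
    fnum <- finite_diff(function(v) {
      p2 <- params; p2[[nm]] <- v
      pglcn:::engine_pass(X, se$ii, se$jj, d2, y, 1:4, p2, cfg,
                          want_grads = FALSE)$loss
    }, params[[nm]])
    denom <- max(abs(fnum), 1e-8)
    expect_lt(max(abs(pass$grads[[nm]] - fnum)) / denom, 1e-4)
  }
})

test_that("dense forward agrees with the sparse training engine", {
  set.seed(13)
  tb <- tiny_bench_model(seed = 13)
  A <- pglcn:::benchmark_adjacency(tb$bench)
  X <- tb$bench$node_features
  dense <- pglcn_forward(X, A, tb$model$params, tb$model$config)
  y <- match(tb$bench$node_labels, tb$model$classes)
  se <- pglcn:::support_edges(A)
  d2 <- rowSums((X[se$ii, ] - X[se$jj, ])^2)
  eng <- pglcn:::engine_pass(X, se$ii, se$jj, d2, y, tb$split$train,
                             tb$model$params, tb$model$config,
                             want_grads = FALSE)
  expect_equal(dense$probs, eng$probs, tolerance = 1e-8)
  expect_equal(as.matrix(eng$S), unname(dense$S), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("forward pass is deterministic and batch-consistent in cohort mode", {
  st <- tiny_cohort_setup(n = 20, p = 6)
  cfg <- pglcn_config(mode = "cohort", hidden = c(8L, 8L), fc_dim = 16L,
                      epochs = 5L, seed = 2)
  params <- pglcn:::init_pglcn_params(cfg, f = 6, c = 2, p = 6)
  arr <- st$feats$values[, , , drop = FALSE]
  out <- pglcn_forward(arr, st$feats$adjacency, params, cfg)

  # two patients with identical features get identical logits
  arr2 <- arr
  arr2[2, , ] <- arr2[1, , ]
  out2 <- pglcn_forward(arr2, st$feats$adjacency, params, cfg)
  expect_equal(out2$logits[1, ], out2$logits[2, ])

  # permuting the batch permutes the logits identically
  perm <- c(5, 3, 1, 2, 4, 6:20)
  out3 <- pglcn_forward(arr[perm, , , drop = FALSE], st$feats$adjacency,
                        params, cfg)
  expect_equal(out3$logits, out$logits[perm, ], tolerance = 1e-10)

  # zero-weight head -> all logits zero -> probabilities (0.5, 0.5)
  p0 <- params
  p0$Wf2[] <- 0; p0$bf2[] <- 0
  out0 <- pglcn_forward(arr[1:3, , , drop = FALSE], st$feats$adjacency,
                        p0, cfg)
  expect_equal(out0$probs, matrix(0.5, 3, 2))
})

test_that("training is seeded, deterministic, and supervised only via lambda", {
  st <- tiny_cohort_setup(n = 40, p = 6)
  data <- list(features = st$feats$values, labels = st$cohort$tmb_label,
               train_idx = 1:28, val_idx = 29:40)
  cfg <- pglcn_config(mode = "cohort", hidden = c(8L, 8L), fc_dim = 16L,
                      epochs = 30L, patience = 30L, seed = 21)
  m1 <- train_pglcn(data, st$feats$adjacency, cfg)
  m2 <- train_pglcn(data, st$feats$adjacency, cfg)
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$params, m2$params)

  # lambda = 0: the objective ignores labels, the head keeps its
  # initialization and stays at chance
  cfg0 <- pglcn_config(mode = "cohort", hidden = c(8L, 8L), fc_dim = 16L,
                       epochs = 15L, patience = 15L, lambda = 0, seed = 21)
  m0 <- train_pglcn(data, st$feats$adjacency, cfg0)
  init <- pglcn:::init_pglcn_params(cfg0, f = 6, c = 2, p = 6)
  expect_identical(m0$params$Wf2, init$Wf2)
  expect_identical(m0$params$Wc1, init$Wc1)
})

test_that("training recovers a planted pathway signal", {
  st <- tiny_cohort_setup(n = 150, p = 10, effect_k = 4, effect_size = 2,
                          seed = 31)
  y <- st$cohort$tmb_label
  set.seed(32)
  te <- sample(150, 30)
  rest <- setdiff(1:150, te)
  va <- sample(rest, 24)
  tr <- setdiff(rest, va)
  cfg <- pglcn_config(mode = "cohort", hidden = c(16L, 16L), fc_dim = 32L,
                      epochs = 120L, patience = 30L, seed = 33)
  m <- train_pglcn(list(features = st$feats$values, labels = y,
                        train_idx = tr, val_idx = va),
                   st$feats$adjacency, cfg)
  probs <- predict(m, st$feats$values[te, , , drop = FALSE])
  auc <- pglcn:::rank_auc(probs[, match(1, m$classes)], y[te])
  expect_gt(auc, 0.9)
})

test_that("sparsity weight gamma is monotone on the closed 3-node problem", {
  # minimize sum_ij d_ij S_ij + gamma ||S||_F^2 over row-stochastic S on
  # a 3-node chain support; the optimal ||S||_F^2 never increases in
  # gamma
  A <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))
  set.seed(40)
  X <- matrix(rnorm(3), 3, 1)
  d2 <- as.matrix(dist(X))^2
  frob_at_opt <- function(gamma) {
    obj <- function(theta) {
      # softmax parameterization per row over the support
      S <- matrix(0, 3, 3)
      k <- 1
      for (i in 1:3) {
        sup <- which(A[i, ] == 1)
        e <- exp(theta[k:(k + length(sup) - 1)])
        S[i, sup] <- e / sum(e)
        k <- k + length(sup)
      }
      sum(d2 * S) + gamma * sum(S^2)
    }
    n_par <- sum(A)
    fit <- optim(rep(0, n_par), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    S <- matrix(0, 3, 3)
    k <- 1
    for (i in 1:3) {
      sup <- which(A[i, ] == 1)
      e <- exp(fit$par[k:(k + length(sup) - 1)])
      S[i, sup] <- e / sum(e)
      k <- k + length(sup)
    }
    sum(S^2)
  }
  frobs <- vapply(c(0.01, 0.1, 1, 10), frob_at_opt, numeric(1))
  expect_true(all(diff(frobs) <= 1e-6))
})

test_that("constant features reduce convolution to neighborhood averaging", {
  # with identical feature rows the learned S is uniform over neighbors,
  # so one linear conv layer equals the hand-rolled neighborhood mean
  A <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 1), c(1, 0, 1, 1), c(0, 1, 1, 1))
  X <- matrix(1, 4, 3)
  par <- list(P = matrix(rnorm(6), 3, 2), a = rnorm(2))
  S <- graph_learning_layer(X, A, par)
  H <- matrix(rnorm(12), 4, 3)   # arbitrary signal propagated by S
  got <- graph_conv(H, S, diag(3), identity)
  want <- t(vapply(1:4, function(i) colMeans(H[A[i, ] == 1, , drop = FALSE]),
                   numeric(3)))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("non-finite losses abort with a diagnostic", {
  st <- tiny_cohort_setup(n = 20, p = 6)
  bad <- st$feats$values
  bad[1, 1, 1] <- NaN
  cfg <- pglcn_config(mode = "cohort", hidden = c(4L, 4L), fc_dim = 8L,
                      epochs = 3L, seed = 1)
  expect_error(
    train_pglcn(list(features = bad, labels = st$cohort$tmb_label,
                     train_idx = 1:15, val_idx = 16:20),
                st$feats$adjacency, cfg),
    "non-finite")
})
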