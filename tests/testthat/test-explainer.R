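test_that("masked forward matches identity and limit cases", {
  tb <- tiny_bench_model(seed = 5)
  A <- pglcn:::benchmark_adjacency(tb$bench)
  sub <- 1:12
  Esub <- A[sub, sub]
  X <- tb$bench$node_features[sub, ]
  nv <- length(sub); f <- ncol(X)

  # +inf logits: sigmoid -> 1, prediction equals the unmasked model
  open <- list(edge_logits = matrix(40, nv, nv),
               feature_logits = rep(40, f))
  fw <- masked_forward(tb$model, X, Esub, open)
  ref <- pglcn_forward(X, Esub, tb$model$params, tb$model$config)
  expect_equal(fw$probs, ref$probs, tolerance = 1e-8)
  # ... in both masking conventions
  fw_rn <- masked_forward(tb$model, X, Esub, open, renormalize = TRUE)
  expect_equal(fw_rn$probs, ref$probs, tolerance = 1e-8)

  # -inf off-diagonal under renormalization: graph reduces to self-loops
  selfonly <- list(edge_logits = matrix(-40, nv, nv) + diag(80, nv),
                   feature_logits = rep(40, f))
  fw_self <- masked_forward(tb$model, X, Esub, selfonly, renormalize = TRUE)
  expect_equal(unname(fw_self$S), diag(nv), tolerance = 1e-10)

  expect_error(
    masked_forward(tb$model, X, Esub,
                   list(edge_logits = matrix(0, 2, 2),
                        feature_logits = rep(0, f))),
    "mismatch")
})

test_that("masked forward composes mask arithmetic with the plain forward", {
  # 3-node toy: applying the mask by hand and running the unmasked
  # forward must reproduce masked_forward (renormalizing convention)
  tb <- tiny_bench_model(seed = 6)
  A3 <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))
  X3 <- tb$bench$node_features[1:3, ]
  set.seed(1)
  ml <- matrix(rnorm(9), 3, 3); ml <- (ml + t(ml)) / 2
  fl <- rnorm(ncol(X3))
  masks <- list(edge_logits = ml, feature_logits = fl)
  fw <- masked_forward(tb$model, X3, A3, masks, renormalize = TRUE)
  Es <- A3 * pglcn:::sigmoid(ml)
  Xs <- sweep(X3, 2, pglcn:::sigmoid(fl), "*")
  ref <- pglcn_forward(Xs, Es, tb$model$params, tb$model$config)
  expect_equal(fw$probs, ref$probs, tolerance = 1e-10)
})

test_that("explainer loss components match closed forms", {
  tb <- tiny_bench_model(seed = 5)
  A <- pglcn:::benchmark_adjacency(tb$bench)[1:6, 1:6]
  X <- tb$bench$node_features[1:6, ]
  cfg <- explainer_config(theta_edge_entropy = 2, theta_feat_entropy = 2,
                          theta_edge_size = 2, theta_feat_size = 2)
  # all mask probabilities 0.5: entropy component = theta ln 2, size
  # component = theta / 2
  half <- list(edge_logits = matrix(0, 6, 6), feature_logits = rep(0, ncol(X)))
  comp <- explainer_loss(tb$model, X, A, half, target_label = 1L, cfg,
                         instance_node = 1L)
  expect_equal(comp$edge_entropy, 2 * log(2), tolerance = 1e-12)
  expect_equal(comp$feat_entropy, 2 * log(2), tolerance = 1e-12)
  expect_equal(comp$edge_size, 2 * 0.5, tolerance = 1e-12)
  expect_equal(comp$feat_size, 2 * 0.5, tolerance = 1e-12)

  # near-binary masks: entropy components vanish
  bin <- list(edge_logits = matrix(80, 6, 6) - diag(40, 6),
              feature_logits = rep(-80, ncol(X)))
  comp2 <- explainer_loss(tb$model, X, A, bin, target_label = 1L, cfg,
                          instance_node = 1L)
  expect_lt(comp2$edge_entropy, 1e-8)
  expect_lt(comp2$feat_entropy, 1e-8)

  # hand evaluation of the binary entropy mean for a 2x2 mask
  h <- function(x) -x * log(x) - (1 - x) * log(1 - x)
  probs <- c(0.9, 0.1, 0.5, 0.5)
  expect_equal(mean(h(probs)), 0.5091, tolerance = 1e-4)
})

test_that("the C++ objective equals the R reference at arbitrary masks", {
  tb <- tiny_bench_model(seed = 9)
  A <- pglcn:::benchmark_adjacency(tb$bench)
  sub <- sort(unlist(tb$bench$motif_nodes[1]))
  sub <- sort(unique(c(sub, 1:4)))
  Esub <- A[sub, sub]
  X <- tb$bench$node_features[sub, ]
  nv <- length(sub)
  cfg <- explainer_config()
  set.seed(2)
  for (renorm in c(TRUE, FALSE)) {
    ml <- matrix(rnorm(nv * nv), nv, nv); ml <- (ml + t(ml)) / 2
    fl <- rnorm(ncol(X))
    rcmp <- explainer_loss(tb$model, X, Esub,
                           list(edge_logits = ml, feature_logits = fl),
                           target_label = 2L,
                           {cfg$renormalize <- renorm; cfg},
                           instance_node = 3L)
    ccmp <- pglcn:::explainer_eval_cpp(X, Esub, tb$model$params, ml, fl,
                                       2L, 1L, cfg$theta, FALSE,
                                       tb$model$config$abs_diff, renorm)
    expect_equal(ccmp$total, rcmp$total, tolerance = 1e-8)
    expect_equal(ccmp$pred_nll, rcmp$pred_nll, tolerance = 1e-8)
  }
})

test_that("the implemented objective is the mutual-information surrogate", {
  # MI(Y; Gs, Xs) = H(Y) - H(Y | Gs, Xs): since the model is frozen,
  # H(Y) is mask-independent, so loss + MI must be constant across masks
  tb <- tiny_bench_model(seed = 10)
  A <- pglcn:::benchmark_adjacency(tb$bench)[1:8, 1:8]
  X <- tb$bench$node_features[1:8, ]
  cfg <- explainer_config(theta_edge_entropy = 0, theta_feat_entropy = 0,
                          theta_edge_size = 0, theta_feat_size = 0)
  ref <- pglcn_forward(X, A, tb$model$params, tb$model$config)
  yhat <- which.max(ref$probs[2, ])
  HY <- -sum(ref$probs[2, ] * log(ref$probs[2, ]))
  set.seed(3)
  consts <- replicate(4, {
    ml <- matrix(rnorm(64), 8, 8); ml <- (ml + t(ml)) / 2
    masks <- list(edge_logits = ml, feature_logits = rnorm(ncol(X)))
    loss <- explainer_loss(tb$model, X, A, masks, target_label = yhat,
                           cfg, instance_node = 2L)$total
    mi <- HY - loss      # MI with the conditional entropy surrogate
    loss + mi
  })
  expect_equal(max(consts) - min(consts), 0, tolerance = 1e-10)
  expect_equal(consts[1], HY, tolerance = 1e-10)
})

test_that("explanation AUC equals the exhaustive pairwise oracle", {
  expect_equal(explanation_auc(c(0.9, 0.8), c(TRUE, FALSE)), 1)
  expect_equal(explanation_auc(rep(0.5, 6), c(1, 1, 0, 0, 0, 1)), 0.5)
  expect_equal(explanation_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_true(is.na(explanation_auc(c(1, 2), c(TRUE, TRUE))))

  # exhaustive comparison on all score patterns over <= 8 edges
  set.seed(8)
  for (rep in 1:200) {
    m <- sample(2:8, 1)
    scores <- sample(seq(0, 1, by = 0.25), m, replace = TRUE)
    flags <- rbinom(m, 1, 0.5)
    expect_equal(explanation_auc(scores, flags), brute_auc(scores, flags))
  }
})

test_that("mask fitting is seeded, finite, and loss-decreasing", {
  tb <- tiny_bench_model(seed = 12)
  A <- pglcn:::benchmark_adjacency(tb$bench)
  v <- tb$bench$motif_nodes[[1]][3]
  sub <- pglcn:::neighborhood_list(tb$bench$edges,
                                   nrow(tb$bench$node_features), 3)[[v]]
  Esub <- A[sub, sub]
  X <- tb$bench$node_features[sub, ]
  cfg <- explainer_config(epochs = 60L, seed = 4)
  e1 <- fit_explanation(tb$model, X, Esub, cfg,
                        instance_node = match(v, sub))
  e2 <- fit_explanation(tb$model, X, Esub, cfg,
                        instance_node = match(v, sub))
  expect_identical(e1$edge_mask, e2$edge_mask)
  expect_true(all(is.finite(e1$loss_trace)))
  expect_lt(e1$loss_trace[length(e1$loss_trace)], e1$loss_trace[1])
  # symmetric mask, supported on E
  expect_equal(e1$edge_mask, t(e1$edge_mask), tolerance = 1e-12)
})

test_that("a provably edge-dependent toy model ranks that edge first", {
  # hand-built 3-node transductive model whose prediction for node 1
  # depends (through propagation) only on information arriving over edge
  # (1,2): feature of node 2 is the sole class signal
  A <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 1))
  X <- rbind(c(0, 0), c(5, 0), c(0, 0))
  params <- list(P = matrix(0, 2, 1), a = 0,
                 Wc1 = diag(2), bc1 = c(0, 0),
                 Wc2 = rbind(c(1, -1), c(0, 0)), bc2 = c(0, 0))
  model <- structure(list(
    params = params,
    config = pglcn_config(mode = "transductive", embed_dim = 1,
                          hidden = 2L, seed = 1),
    classes = c(0L, 1L)), class = "pglcn_model")
  expl <- fit_explanation(model, X, A,
                          explainer_config(epochs = 120L, seed = 1),
                          instance_node = 1L, target_class = 1L)
  off <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  scores <- expl$edge_mask[off]
  labels <- paste(off[, 1], off[, 2])
  expect_equal(labels[which.max(scores)], "1 2")
})

test_that("subgraph extraction ranks and thresholds the support edges", {
  E <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1))
  W <- matrix(0.1, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.9
  W[2, 4] <- W[4, 2] <- 0.7
  expl <- structure(list(edge_mask = W, support = E,
                         feature_mask = c(0.3, 0.8)),
                    class = "pglcn_explanation")
  top2 <- extract_subgraph(expl, top_k = 2)
  expect_equal(top2$edges$weight, c(0.9, 0.7))
  expect_equal(top2$edges$i, c(1, 2))
  expect_equal(top2$edges$j, c(2, 4))
  expect_equal(top2$nodes, c(1, 2, 4))
  expect_equal(top2$feature_importance, c(0.3, 0.8))

  # top_k beyond the edge count returns the full support
  all_e <- extract_subgraph(expl, top_k = 100)
  expect_equal(nrow(all_e$edges), sum(E[upper.tri(E)] > 0))

  # strict threshold at 1.0 -> empty (sigmoid < 1 strictly)
  none <- extract_subgraph(expl, threshold = 1.0)
  expect_equal(nrow(none$edges), 0L)
})

test_that("top-k explanation subgraphs preserve predictions better than random", {
  # planted-signal cohort: keeping the explainer's top-k edges must
  # preserve the predicted class for nearly all correctly classified
  # patients, and beat random subgraphs of the same size
  st <- tiny_cohort_setup(n = 120, p = 30, effect_k = 8, effect_size = 2.5,
                          seed = 61)
  y <- st$cohort$tmb_label
  tr <- 1:80; va <- 81:100; te <- 101:120
  cfg <- pglcn_config(mode = "cohort", hidden = c(16L, 16L), fc_dim = 32L,
                      epochs = 100L, patience = 25L, seed = 62)
  m <- train_pglcn(list(features = st$feats$values, labels = y,
                        train_idx = tr, val_idx = va),
                   st$feats$adjacency, cfg)
  A <- st$feats$adjacency
  p <- nrow(A)
  probs <- predict(m, st$feats$values)
  pred <- max.col(probs)
  correct <- which((pred - 1) == y)
  correct <- head(intersect(correct, c(te, va)), 20)
  expect_gte(length(correct), 20)

  k <- 10
  offdiag <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  keep_class <- function(b, keep_idx) {
    # evaluate the frozen model on the induced k-edge subgraph: nodes
    # outside it lose their edges and their features
    Ak <- diag(p)
    nodes <- sort(unique(as.vector(offdiag[keep_idx, ])))
    for (r in keep_idx) {
      Ak[offdiag[r, 1], offdiag[r, 2]] <- 1
      Ak[offdiag[r, 2], offdiag[r, 1]] <- 1
    }
    Xb <- matrix(st$feats$values[b, , ], p, dim(st$feats$values)[3])
    Xb[setdiff(seq_len(p), nodes), ] <- 0
    max.col(pglcn_forward(array(Xb, c(1, dim(Xb))), Ak, m$params,
                          m$config)$probs)[1] == pred[b]
  }
  kept_top <- kept_rand <- logical(0)
  set.seed(63)
  for (b in correct) {
    Xb <- matrix(st$feats$values[b, , ], p, dim(st$feats$values)[3])
    ex <- fit_explanation(m, Xb, A, explainer_config(epochs = 80L, seed = b))
    ranks <- order(-ex$edge_mask[offdiag])
    kept_top <- c(kept_top, keep_class(b, ranks[1:k]))
    kept_rand <- c(kept_rand, keep_class(b, sample(nrow(offdiag), k)))
  }
  expect_gte(mean(kept_top), 0.9)
  expect_gt(mean(kept_top), mean(kept_rand))
})
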