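#' Edge/feature-mask explanations
#'
#' Given a trained network with frozen parameters, an explanation is a
#' pair of continuous masks: a symmetric edge mask over the support of
#' the instance adjacency (self-loops included) and a per-column feature
#' mask.  Masks are logit-parameterized; the network is evaluated on
#' `E * sigmoid(M)` and `X * sigmoid(F)` and the mask logits are trained
#' to preserve the model's original prediction (a conditional-entropy /
#' mutual-information surrogate) while staying small (size terms) and
#' near-binary (entropy terms).
#'
#' @name explainer
NULL

#' Explainer optimization settings
#'
#' @param lr Adam learning rate for the mask logits.
#' @param epochs optimization epochs.
#' @param theta_edge_entropy,theta_feat_entropy weights of the binary
#'   entropy regularizers on the edge / feature mask.
#' @param theta_edge_size,theta_feat_size weights of the mean-mask size
#'   regularizers.
#' @param init_sd sd of the Gaussian mask-logit initialization.
#' @param init_mean mean of the mask-logit initialization (0 starts all
#'   masks at sigmoid 0.5; positive values start from an intact graph and
#'   let the size penalty erode unsupported edges).
#' @param renormalize how the edge mask enters the frozen network.
#'   `TRUE`: the masked adjacency `E * sigmoid(M)` feeds the
#'   graph-learning softmax, whose rows re-normalize around the mask.
#'   `FALSE` (default): the affinity S is computed from the unmasked
#'   graph and the mask attenuates the propagation weights directly
#'   (`S * sigmoid(M)`), so every edge's message is scaled absolutely —
#'   the convention of mask-based GNN explainers, and the one that makes
#'   redundant-but-real edges retain weight instead of being silently
#'   re-absorbed by row renormalization.
#' @param optimize_features also optimize the feature mask (default TRUE).
#' @param seed RNG seed for mask initialization.
#' @return list of class `pglcn_explainer_config`.
#' @export
explainer_config <- function(lr = 0.1, epochs = 100L,
                             theta_edge_entropy = 0.3,
                             theta_feat_entropy = 0.1,
                             theta_edge_size = 0.05,
                             theta_feat_size = 1.0,
                             init_sd = 0.1, init_mean = 0,
                             optimize_features = TRUE, renormalize = FALSE,
                             seed = 0L) {
  structure(list(lr = lr, epochs = as.integer(epochs),
                 theta = c(theta_edge_entropy, theta_feat_entropy,
                           theta_edge_size, theta_feat_size),
                 init_sd = init_sd, init_mean = init_mean,
                 optimize_features = isTRUE(optimize_features),
                 renormalize = isTRUE(renormalize),
                 seed = as.integer(seed)),
            class = "pglcn_explainer_config")
}

# Apply masks to an instance: symmetric sigmoid edge mask on the support,
# per-column sigmoid feature mask.
apply_masks <- function(X, E, masks) {
  M <- masks$edge_logits
  Msym <- (M + t(M)) / 2
  Es <- E * sigmoid(Msym)
  sf <- sigmoid(masks$feature_logits)
  Xs <- sweep(as.matrix(X), 2L, sf, "*")
  list(Xs = Xs, Es = Es, sigM = sigmoid(Msym), sigF = sf)
}

#' Evaluate a frozen model on masked inputs (dense reference)
#'
#' @param model a trained `pglcn_model` (parameters are not updated).
#' @param X instance features: node x f (transductive subgraph) or the
#'   p x 3q matrix of one patient.
#' @param E 0/1 instance adjacency with unit diagonal.
#' @param masks list with `edge_logits` (matching E; symmetrized as
#'   `(M + t(M))/2`) and `feature_logits` (length `ncol(X)`).
#' @param renormalize see [explainer_config()]; `TRUE` masks the
#'   adjacency before the affinity softmax, `FALSE` attenuates the
#'   learned propagation weights directly.
#' @return list with `probs` (per node, or one row in cohort mode), `Es`,
#'   `Xs`.
#' @export
masked_forward <- function(model, X, E, masks, renormalize = FALSE) {
  if (!all(dim(masks$edge_logits) == dim(E))) {
    stop("edge mask / adjacency shape mismatch", call. = FALSE)
  }
  mk <- apply_masks(X, E, masks)
  par <- model$params
  cfg <- model$config
  S <- if (renormalize) {
    graph_learning_layer(mk$Xs, mk$Es, par, cfg$abs_diff)
  } else {
    graph_learning_layer(mk$Xs, E, par, cfg$abs_diff) * mk$sigM
  }
  K <- n_conv_layers(par)
  H <- mk$Xs
  for (k in seq_len(K)) {
    Uk <- sweep(as.matrix(S %*% H %*% par[[paste0("Wc", k)]]), 2L,
                par[[paste0("bc", k)]], "+")
    H <- if (cfg$mode == "transductive" && k == K) Uk else relu(Uk)
  }
  if (cfg$mode == "transductive") {
    return(list(probs = softmax_rows(H), Es = mk$Es, Xs = mk$Xs, S = S))
  }
  v <- as.vector(t(H))
  f1 <- relu(as.vector(v %*% par$Wf1) + par$bf1)
  z <- as.vector(f1 %*% par$Wf2) + par$bf2
  list(probs = matrix(exp(z - max(z)) / sum(exp(z - max(z))), 1L),
       Es = mk$Es, Xs = mk$Xs, S = S)
}

#' Explainer loss and its components (dense reference)
#'
#' `L = -log P(target | masked inputs) + theta_ee * mean h(sigma(M)) +
#' theta_fe * mean h(sigma(F)) + theta_es * mean sigma(M) + theta_fs *
#' mean sigma(F)` with `h` the binary entropy; mask means are taken over
#' the support of E (edge mask) and the feature columns (feature mask).
#'
#' @inheritParams masked_forward
#' @param target_label the model's original predicted class for the
#'   instance (1-based column of the probability matrix).
#' @param config an [explainer_config()].
#' @param instance_node explained node index (transductive mode).
#' @return list with `total` and the individual components.
#' @export
explainer_loss <- function(model, X, E, masks, target_label, config,
                           instance_node = NULL) {
  fw <- masked_forward(model, X, E, masks, renormalize = config$renormalize)
  prob <- if (model$config$mode == "transductive") {
    fw$probs[instance_node, target_label]
  } else {
    fw$probs[1L, target_label]
  }
  eps <- 1e-12
  mk <- apply_masks(X, E, masks)
  sm <- pmin(pmax(mk$sigM[E > 0], eps), 1 - eps)
  sf <- pmin(pmax(mk$sigF, eps), 1 - eps)
  h <- function(x) -x * log(x) - (1 - x) * log(1 - x)
  th <- config$theta
  comps <- list(pred_nll = -log(pmin(pmax(prob, eps), 1 - eps)),
                edge_entropy = th[1] * mean(h(sm)),
                feat_entropy = th[2] * mean(h(sf)),
                edge_size = th[3] * mean(sm),
                feat_size = th[4] * mean(sf))
  comps$total <- sum(unlist(comps))
  comps
}

#' Fit an explanation for one instance
#'
#' Runs Adam on the mask logits only (model parameters frozen).  The
#' optimization target is the class the model itself predicts for the
#' unmasked instance.
#'
#' @param model a trained `pglcn_model`.
#' @param X instance features (node x f subgraph matrix, or one patient's
#'   p x 3q matrix in cohort mode).
#' @param E 0/1 instance adjacency with unit diagonal.
#' @param config an [explainer_config()].
#' @param instance_node node to explain (transductive mode; index into X
#'   rows).
#' @param target_class optional 1-based class to preserve; defaults to
#'   the model's prediction on the unmasked instance.
#' @return object of class `pglcn_explanation`: `edge_mask` (symmetric
#'   sigmoid probabilities), `feature_mask`, `support` (copy of E),
#'   `loss_trace`, `target_class`, `final_prob`.
#' @export
fit_explanation <- function(model, X, E, config = explainer_config(),
                            instance_node = NULL, target_class = NULL) {
  X <- as.matrix(X)
  nv <- nrow(X); f <- ncol(X)
  cfg <- model$config
  has_fc <- cfg$mode == "cohort"
  if (!has_fc && is.null(instance_node)) {
    stop("`instance_node` is required in transductive mode", call. = FALSE)
  }
  if (is.null(target_class)) {
    id0 <- matrix(0, nv, nv)
    masks0 <- list(edge_logits = id0 + 20, feature_logits = rep(20, f))
    fw <- masked_forward(model, X, E, masks0)
    target_class <- if (has_fc) which.max(fw$probs[1L, ]) else
      which.max(fw$probs[instance_node, ])
  }
  init <- with_seed(config$seed, {
    m <- matrix(rnorm(nv * nv, config$init_mean, config$init_sd), nv, nv)
    list(M = (m + t(m)) / 2, F = rnorm(f, sd = config$init_sd))
  })
  res <- explain_instance_cpp(
    X, E, model$params, init$M, init$F,
    if (has_fc) 0L else instance_node - 1L, target_class - 1L,
    config$theta, config$lr, config$epochs, has_fc, cfg$abs_diff,
    config$optimize_features, config$renormalize)
  if (!all(is.finite(res$loss_trace))) {
    stop("non-finite explainer loss during mask optimization", call. = FALSE)
  }
  out <- list(edge_mask = res$edge_mask,
              edge_mask_avg = res$edge_mask_avg,
              edge_logits = res$edge_logits,
              feature_mask = as.vector(res$feat_mask), support = E,
              loss_trace = res$loss_trace, target_class = target_class,
              final_prob = res$final_prob)
  class(out) <- "pglcn_explanation"
  out
}

#' @export
print.pglcn_explanation <- function(x, ...) {
  cat(sprintf("<pglcn_explanation> %d nodes, target class %d, final loss %.4f\n",
              nrow(x$edge_mask), x$target_class,
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Explanation ROC AUC
#'
#' AUC of mask scores against ground-truth edge indicators: the
#' normalized count of concordant (positive, negative) pairs with ties
#' counted one half.
#'
#' @param edge_mask_probs numeric scores for a set of evaluation edges.
#' @param ground_truth_edge_flags logical/0-1 vector; TRUE = ground-truth
#'   (motif) edge.
#' @return AUC in `[0, 1]`; `NA` when the evaluation set lacks positives
#'   or negatives.
#' @export
explanation_auc <- function(edge_mask_probs, ground_truth_edge_flags) {
  stopifnot(length(edge_mask_probs) == length(ground_truth_edge_flags))
  rank_auc(edge_mask_probs, ground_truth_edge_flags)
}

#' Extract the explanation subgraph
#'
#' Ranks the (undirected, non-self-loop) support edges by mask weight and
#' keeps the top `top_k`, or all edges above `threshold`.
#'
#' @param explanation a `pglcn_explanation`.
#' @param top_k number of edges to keep (clipped to the edge count).
#' @param threshold alternative: keep edges with `sigma(mask) >
#'   threshold` (strict).
#' @return list with `edges` (data frame: i, j, weight), `nodes` (induced
#'   node set) and `feature_importance` (the sigmoid feature mask).
#' @export
extract_subgraph <- function(explanation, top_k = NULL, threshold = NULL) {
  E <- explanation$support
  W <- explanation$edge_mask
  idx <- which(upper.tri(E) & E > 0, arr.ind = TRUE)
  w <- W[idx]
  ord <- order(w, decreasing = TRUE)
  keep <- if (!is.null(top_k)) {
    ord[seq_len(min(top_k, length(ord)))]
  } else if (!is.null(threshold)) {
    which(w > threshold)
  } else {
    ord
  }
  edges <- data.frame(i = idx[keep, 1L], j = idx[keep, 2L],
                      weight = w[keep])
  edges <- edges[order(-edges$weight), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, nodes = sort(unique(c(edges$i, edges$j))),
       feature_importance = explanation$feature_mask)
}

# K-hop neighborhoods for every node, via the (undirected) edge list.
# Neighborhoods larger than `max_size` are truncated to the nearest
# nodes in breadth-first (distance) order, ties broken by node id, the
# center always kept: hub-adjacent balls in scale-free graphs otherwise
# swallow half the graph without adding information about the center.
neighborhood_list <- function(edges, n_nodes, hops, max_size = Inf) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
  lapply(seq_len(n_nodes), function(v) {
    ball <- as.integer(igraph::ego(g, order = hops, nodes = v)[[1]])
    if (length(ball) > max_size) {
      d <- as.vector(igraph::distances(g, v = v, to = ball))
      ball <- ball[order(d, ball)][seq_len(max_size)]
    }
    sort(ball)
  })
}

#' Explain the motif nodes of a synthetic benchmark
#'
#' For each requested node: extracts the node's K-hop computation
#' subgraph (K = number of convolution layers, default 2), fits an edge
#' mask against the model's own predicted class, and scores the mask
#' weights of the subgraph's undirected non-self-loop edges against the
#' within-motif ground truth.
#'
#' @param bench a `pglcn_benchmark`.
#' @param model a transductive `pglcn_model` trained on `bench`.
#' @param config an [explainer_config()].
#' @param nodes nodes to explain (default: all motif nodes).
#' @param hops neighborhood radius.  Default: number of convolution
#'   layers + 1 — the network's true receptive field, since the learned
#'   affinity row of a node already depends on its neighbors' features.
#' @param max_neighborhood truncate each evaluation neighborhood to this
#   many nearest nodes (default 100; see `neighborhood_list`).
#' @return list with `auc` (mean over nodes with a defined AUC),
#'   `node_auc` (per node, NA when undefined) and `n_explained`.
#' @export
explain_benchmark <- function(bench, model, config = explainer_config(),
                              nodes = NULL, hops = NULL,
                              max_neighborhood = 100L) {
  if (is.null(hops)) hops <- n_conv_layers(model$params) + 1L
  if (is.null(nodes)) nodes <- sort(unlist(bench$motif_nodes))
  n <- nrow(bench$node_features)
  A <- benchmark_adjacency(bench)
  X <- bench$node_features
  nbrs <- neighborhood_list(bench$edges, n, hops, max_neighborhood)
  flag_key <- paste(bench$edges[, 1L], bench$edges[, 2L])
  flags <- stats::setNames(bench$motif_edge_flags, flag_key)

  # model predictions once, on the full graph
  full <- pglcn_forward(X, A, model$params, model$config)
  pred <- max.col(full$probs)

  aucs <- rep(NA_real_, length(nodes))
  for (t in seq_along(nodes)) {
    v <- nodes[t]
    sub <- nbrs[[v]]
    Esub <- A[sub, sub, drop = FALSE]
    expl <- fit_explanation(model, X[sub, , drop = FALSE], Esub,
                            config = config,
                            instance_node = match(v, sub),
                            target_class = pred[v])
    idx <- which(upper.tri(Esub) & Esub > 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    gi <- sub[idx[, 1L]]; gj <- sub[idx[, 2L]]
    key <- paste(pmin(gi, gj), pmax(gi, gj))
    truth <- flags[key]
    truth[is.na(truth)] <- FALSE
    aucs[t] <- explanation_auc(expl$edge_mask[idx], truth)
  }
  ok <- !is.na(aucs)
  list(auc = mean(aucs[ok]), node_auc = aucs, n_explained = sum(ok))
}
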