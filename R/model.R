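#' The pathway graph-learning convolutional network
#'
#' The network stacks (i) a graph-learning layer that turns node features
#' into a row-stochastic affinity matrix S supported on a fixed 0/1 prior
#' adjacency A, (ii) simplified graph convolutions `X^(k+1) = sigma(S X^(k)
#' W^(k))` (no Laplacian normalization: S rows already sum to 1), and, in
#' cohort mode, (iii) fully connected layers mapping the flattened
#' pathway-by-channel representation to class logits.  Training minimizes
#' `L = L1 + lambda * L2` where `L1 = sum_ij ||g_i - g_j||^2 S_ij +
#' gamma ||S||_F^2` is the graph-learning loss and L2 the cross-entropy
#' over labeled samples.
#'
#' Two modes are supported: `"transductive"` (one graph, labels on nodes;
#' the last convolution is hidden-to-output with `c` classes) and
#' `"cohort"` (one p-node pathway graph per patient with shared prior and
#' shared parameters, one label per patient).
#'
#' @name pglcn-model
NULL

relu <- function(x) pmax(x, 0)

#' Graph-learning layer (dense reference)
#'
#' Computes the learned affinity `S_ij = A_ij exp(ReLU(a' |g~_i - g~_j|)) /
#' sum_j A_ij exp(ReLU(a' |g~_i - g~_j|))` with `g~ = g P`.  Rows are
#' normalized over the support of the prior only; because `A_ii = 1`, no
#' row has empty support.
#'
#' @param features node x f matrix.
#' @param prior_A 0/1 matrix with unit diagonal, rows aligned to features.
#' @param params list with projection `P` (f x d) and attention vector `a`
#'   (length d).
#' @param abs_diff use the elementwise absolute difference `|g~_i - g~_j|`
#'   (default TRUE); `FALSE` uses the signed difference.
#' @return row-stochastic matrix S with `S_ij = 0` wherever `A_ij = 0`.
#' @export
graph_learning_layer <- function(features, prior_A, params, abs_diff = TRUE) {
  X <- as.matrix(features)
  if (nrow(X) != nrow(prior_A) || ncol(X) != nrow(params$P)) {
    stop("dimension mismatch between features, prior adjacency and parameters",
         call. = FALSE)
  }
  Gt <- X %*% params$P
  U <- matrix(0, nrow(X), nrow(X))
  for (k in seq_along(params$a)) {
    D <- outer(Gt[, k], Gt[, k], "-")
    if (abs_diff) D <- abs(D)
    U <- U + params$a[k] * D
  }
  E <- prior_A * exp(relu(U))
  E / rowSums(E)
}

#' Graph-learning loss (Eq. L1)
#'
#' `L1 = sum_ij ||g_i - g_j||^2 S_ij + gamma ||S||_F^2`.  A large feature
#' distance is penalized when paired with a large affinity; the Frobenius
#' term controls the sparsity/uniformity of S.
#'
#' @param features node x f matrix g.
#' @param S affinity matrix (typically row-stochastic).
#' @param gamma nonnegative sparsity weight.
#' @return scalar loss.
#' @export
graph_learning_loss <- function(features, S, gamma = 0.01) {
  X <- as.matrix(features)
  S <- as.matrix(S)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  sum(D2 * S) + gamma * sum(S^2)
}

#' Simplified graph convolution
#'
#' `sigma(S X W)`; no extra degree normalization because S is
#' row-stochastic.
#'
#' @param X node x f input.
#' @param S affinity matrix.
#' @param W f x g weight matrix.
#' @param activation function applied elementwise (default ReLU; use
#'   `identity` for a linear output layer).
#' @return node x g matrix.
#' @export
graph_conv <- function(X, S, W, activation = relu) {
  X <- as.matrix(X)
  if (ncol(S) != nrow(X) || ncol(X) != nrow(W)) {
    stop("shape mismatch in graph convolution", call. = FALSE)
  }
  activation(as.matrix(S %*% X %*% W))
}

#' Cross-entropy loss over labeled samples (Eq. L2)
#'
#' @param Z samples x c matrix of class probabilities (softmax applied).
#' @param Y samples x c one-hot matrix of true labels.
#' @param labeled_ids indices of labeled samples (default: all).
#' @param eps probabilities are clipped to `[eps, 1 - eps]` before the log.
#' @return scalar negative log-likelihood summed over labeled samples.
#' @export
cross_entropy_loss <- function(Z, Y, labeled_ids = seq_len(nrow(Z)),
                               eps = 1e-12) {
  Z <- pmin(pmax(Z, eps), 1 - eps)
  -sum(Y[labeled_ids, , drop = FALSE] * log(Z[labeled_ids, , drop = FALSE]))
}

#' Joint training objective `L = L1 + lambda * L2`
#' @param L1 graph-learning loss.
#' @param L2 cross-entropy loss.
#' @param lambda nonnegative tradeoff weight.
#' @return scalar.
#' @export
total_loss <- function(L1, L2, lambda = 1) {
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  L1 + lambda * L2
}

#' Model/training configuration
#'
#' @param mode `"transductive"` or `"cohort"`.
#' @param embed_dim d of the graph-learning projection (must stay below
#'   the input feature dimension).
#' @param hidden widths of the hidden convolution layers (any depth).
#'   In transductive mode one extra hidden-to-output convolution of
#'   width `c` is appended; in cohort mode the fully connected head
#'   follows the last hidden convolution.
#' @param fc_dim width of the first fully connected layer (cohort mode).
#' @param gamma sparsity weight of the graph-learning loss.
#' @param lambda tradeoff between graph-learning and cross-entropy terms.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss.
#' @param abs_diff absolute-difference pairwise term (see
#'   [graph_learning_layer()]).
#' @param seed RNG seed for initialization.
#' @return list of class `pglcn_config`.
#' @export
pglcn_config <- function(mode = c("cohort", "transductive"),
                         embed_dim = 4L, hidden = c(64L, 64L), fc_dim = 128L,
                         gamma = 0.01, lambda = 1, lr = NULL, epochs = 200L,
                         patience = 20L, abs_diff = TRUE, seed = 0L) {
  mode <- match.arg(mode)
  if (is.null(lr)) lr <- if (mode == "transductive") 0.01 else 1e-3
  stopifnot(gamma >= 0, lambda >= 0, lr > 0)
  structure(list(mode = mode, embed_dim = as.integer(embed_dim),
                 hidden = as.integer(hidden), fc_dim = as.integer(fc_dim),
                 gamma = gamma, lambda = lambda, lr = lr,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 abs_diff = isTRUE(abs_diff), seed = as.integer(seed)),
            class = "pglcn_config")
}

glorot <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)
}

# Initialize all trainable arrays.  f: input feature dim; p: nodes per
# graph (cohort mode); c: class count.  Convolution weights are stored
# flat as Wc1/bc1 ... WcK/bcK; in transductive mode the last convolution
# is the hidden-to-output layer (width c), in cohort mode all
# convolutions are hidden and a two-layer fully connected head follows.
init_pglcn_params <- function(config, f, c, p = NULL) {
  d <- min(config$embed_dim, f - 1L)
  widths <- if (config$mode == "transductive") {
    c(config$hidden, c)
  } else {
    config$hidden
  }
  with_seed(config$seed, {
    par <- list(P = glorot(f, d), a = rnorm(d, sd = 0.1))
    d_in <- f
    for (k in seq_along(widths)) {
      par[[paste0("Wc", k)]] <- glorot(d_in, widths[k])
      par[[paste0("bc", k)]] <- rep(0, widths[k])
      d_in <- widths[k]
    }
    if (config$mode == "cohort") {
      par$Wf1 <- glorot(p * d_in, config$fc_dim)
      par$bf1 <- rep(0, config$fc_dim)
      par$Wf2 <- glorot(config$fc_dim, c)
      par$bf2 <- rep(0, c)
    }
    par
  })
}

n_conv_layers <- function(params) {
  sum(grepl("^Wc", names(params)))
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- Shared sparse engine ---------------------------------------------
#
# One forward/backward pass over a (possibly block-diagonal) graph.
# `ii`/`jj` are directed support index pairs including the diagonal;
# `graph_of` maps each global node row to its graph (patient) for cohort
# mode.  Returns loss pieces, per-sample probabilities, and gradients.

engine_pass <- function(X, ii, jj, dist2, y, labeled, params, config,
                        graph_of = NULL, p = NULL, want_grads = TRUE) {
  N <- nrow(X)
  c <- if (config$mode == "transductive") {
    ncol(params[[paste0("Wc", n_conv_layers(params))]])
  } else {
    ncol(params$Wf2)
  }
  lambda <- config$lambda; gamma <- config$gamma

  Gt <- X %*% params$P
  D <- Gt[ii, , drop = FALSE] - Gt[jj, , drop = FALSE]
  Ab <- if (config$abs_diff) abs(D) else D
  u <- as.vector(Ab %*% params$a)
  # cap the exponent: softmax ratios are unaffected for moderate spreads
  # and exp() cannot overflow to Inf during training
  r <- pmin(pmax(u, 0), 60)
  e <- exp(r)
  ss <- rowsum(e, ii)[, 1L]
  Sv <- e / ss[ii]
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = Sv, dims = c(N, N))

  K <- n_conv_layers(params)
  Hin <- Mlist <- Ulist <- vector("list", K)
  Hcur <- X
  for (k in seq_len(K)) {
    Hin[[k]] <- Hcur
    Mlist[[k]] <- Hcur %*% params[[paste0("Wc", k)]]
    Uk <- as.matrix(S %*% Mlist[[k]])
    Ulist[[k]] <- sweep(Uk, 2L, params[[paste0("bc", k)]], "+")
    last_logits <- config$mode == "transductive" && k == K
    Hcur <- if (last_logits) Ulist[[k]] else relu(Ulist[[k]])
  }

  if (config$mode == "transductive") {
    Z <- Hcur
    probs <- softmax_rows(Z)
    n_samples <- N
  } else {
    HK <- Hcur
    hK <- ncol(HK)
    n_samples <- N / p
    # flatten per patient in fixed pathway order (channel fastest)
    V <- t(matrix(aperm(array(HK, c(p, n_samples, hK)), c(3L, 1L, 2L)),
                  hK * p, n_samples))
    F1pre <- sweep(V %*% params$Wf1, 2L, params$bf1, "+")
    F1 <- relu(F1pre)
    Z <- sweep(F1 %*% params$Wf2, 2L, params$bf2, "+")
    probs <- softmax_rows(Z)
  }

  Yoh <- matrix(0, n_samples, c)
  Yoh[cbind(labeled, y[labeled])] <- 1
  L2 <- cross_entropy_loss(probs, Yoh, labeled)
  L1 <- sum(dist2 * Sv) + gamma * sum(Sv^2)
  out <- list(L1 = L1, L2 = L2, loss = L1 + lambda * L2, probs = probs,
              S = S, Sv = Sv)
  if (!want_grads) return(out)

  dZ <- probs
  dZ[cbind(labeled, y[labeled])] <- dZ[cbind(labeled, y[labeled])] - 1
  unlab <- setdiff(seq_len(n_samples), labeled)
  if (length(unlab)) dZ[unlab, ] <- 0

  grads <- list()
  if (config$mode == "transductive") {
    dUk <- dZ
  } else {
    grads$Wf2 <- lambda * crossprod(F1, dZ)
    grads$bf2 <- lambda * colSums(dZ)
    dF1 <- (dZ %*% t(params$Wf2)) * (F1pre > 0)
    grads$Wf1 <- lambda * crossprod(V, dF1)
    grads$bf1 <- lambda * colSums(dF1)
    dV <- dF1 %*% t(params$Wf1)
    hK <- ncol(Ulist[[K]])
    dHK <- matrix(aperm(array(t(dV), c(hK, p, n_samples)), c(2L, 3L, 1L)),
                  N, hK)
    dUk <- dHK * (Ulist[[K]] > 0)
  }

  dSv_conv <- 0
  for (k in rev(seq_len(K))) {
    StdUk <- as.matrix(Matrix::crossprod(S, dUk))
    grads[[paste0("Wc", k)]] <- lambda * crossprod(Hin[[k]], StdUk)
    grads[[paste0("bc", k)]] <- lambda * colSums(dUk)
    dSv_conv <- dSv_conv +
      rowSums(dUk[ii, , drop = FALSE] * Mlist[[k]][jj, , drop = FALSE])
    if (k > 1L) {
      dHprev <- StdUk %*% t(params[[paste0("Wc", k)]])
      dUk <- dHprev * (Ulist[[k - 1L]] > 0)
    }
  }

  dSv <- (dist2 + 2 * gamma * Sv) + lambda * dSv_conv
  rho <- rowsum(dSv * Sv, ii)[, 1L]
  dr <- Sv * (dSv - rho[ii])
  du <- dr * (u > 0)
  ga <- as.vector(crossprod(Ab, du))
  sgn <- if (config$abs_diff) sign(D) else (D * 0 + 1)
  Emat <- sweep(sgn * du, 2L, params$a, "*")
  dGt <- rowsum(Emat, ii) - rowsum(Emat, jj)
  gP <- crossprod(X, dGt)

  grads$P <- gP; grads$a <- ga
  # the convolution weights enter only through lambda*L2 (scaled above);
  # P and a receive both loss terms through dSv.
  out$grads <- grads
  out
}

# Directed support index pairs (both directions + diagonal) of a 0/1
# adjacency.
support_edges <- function(A) {
  idx <- which(A != 0, arr.ind = TRUE)
  list(ii = idx[, 1L], jj = idx[, 2L])
}

#' Full forward pass (dense reference)
#'
#' @param features transductive mode: node x f matrix; cohort mode:
#'   n x p x 3q array of per-patient pathway features.
#' @param prior_A 0/1 prior adjacency with unit diagonal.
#' @param params parameter list from a trained model (`model$params`).
#' @param config a [pglcn_config()] matching the parameters.
#' @return list with `probs` (samples x c), `logits`, and `S` (learned
#'   affinity; in cohort mode a list, one per patient).
#' @export
pglcn_forward <- function(features, prior_A, params, config) {
  K <- n_conv_layers(params)
  conv_stack <- function(X, S, mode) {
    H <- X
    for (k in seq_len(K)) {
      Uk <- sweep(as.matrix(S %*% H %*% params[[paste0("Wc", k)]]), 2L,
                  params[[paste0("bc", k)]], "+")
      H <- if (mode == "transductive" && k == K) Uk else relu(Uk)
    }
    H
  }
  if (config$mode == "transductive") {
    S <- graph_learning_layer(features, prior_A, params, config$abs_diff)
    Z <- conv_stack(as.matrix(features), S, "transductive")
    return(list(probs = softmax_rows(Z), logits = Z, S = S))
  }
  if (length(dim(features)) != 3L) {
    stop("cohort mode expects an n x p x 3q feature array", call. = FALSE)
  }
  n <- dim(features)[1L]
  Slist <- vector("list", n)
  Z <- matrix(0, n, ncol(params$Wf2))
  for (b in seq_len(n)) {
    Xb <- matrix(features[b, , ], dim(features)[2L], dim(features)[3L])
    S <- graph_learning_layer(Xb, prior_A, params, config$abs_diff)
    HK <- conv_stack(Xb, S, "cohort")
    v <- as.vector(t(HK))
    f1 <- relu(as.vector(v %*% params$Wf1) + params$bf1)
    Z[b, ] <- as.vector(f1 %*% params$Wf2) + params$bf2
    Slist[[b]] <- S
  }
  list(probs = softmax_rows(Z), logits = Z, S = Slist)
}

#' Train a PGLCN model
#'
#' Gradient-based (Adam) minimization of `L = L1 + lambda * L2` with early
#' stopping on validation cross-entropy; the best-validation parameters
#' are returned.  Fully seeded and single-threaded deterministic.
#'
#' @param data transductive mode: list with `features` (node x f),
#'   `labels` (integer classes, 0-based or 1-based), `train_idx`,
#'   `val_idx`.  Cohort mode: the same but `features` is an n x p x 3q
#'   array and indices refer to patients.  Samples in neither index set
#'   are treated as unlabeled: they contribute to the graph-learning loss
#'   but not to the cross-entropy.
#' @param prior_A 0/1 prior adjacency with unit diagonal (node graph, or
#'   the shared p x p pathway graph in cohort mode).
#' @param config a [pglcn_config()].
#' @return object of class `pglcn_model`: `params`, `config`, `prior_A`,
#'   `log` (per-epoch losses), `best_epoch`, `classes`.
#' @export
train_pglcn <- function(data, prior_A, config) {
  mode <- config$mode
  y_raw <- data$labels
  classes <- sort(unique(y_raw))
  y <- match(y_raw, classes)
  c <- length(classes)
  train_idx <- data$train_idx
  val_idx <- data$val_idx

  if (mode == "transductive") {
    X <- as.matrix(data$features)
    N <- nrow(X); p <- NULL
    se <- support_edges(prior_A)
    ii <- se$ii; jj <- se$jj
  } else {
    arr <- data$features
    n <- dim(arr)[1L]; p <- dim(arr)[2L]; f <- dim(arr)[3L]
    # stack patients: global node row (b-1)*p + i
    X <- matrix(aperm(arr, c(2L, 1L, 3L)), n * p, f)
    N <- n * p
    se <- support_edges(prior_A)
    mp <- length(se$ii)
    off <- rep((seq_len(n) - 1L) * p, each = mp)
    ii <- rep(se$ii, n) + off
    jj <- rep(se$jj, n) + off
  }
  dist2 <- rowSums((X[ii, , drop = FALSE] - X[jj, , drop = FALSE])^2)

  params <- init_pglcn_params(config, f = ncol(X), c = c, p = p)
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- vector("list", config$epochs)
  wait <- 0L
  for (ep in seq_len(config$epochs)) {
    pass <- engine_pass(X, ii, jj, dist2, y, train_idx, params, config,
                        p = p)
    if (!is.finite(pass$loss)) {
      stop(sprintf("non-finite training loss at epoch %d (L1 = %g, L2 = %g)",
                   ep, pass$L1, pass$L2), call. = FALSE)
    }
    val_loss <- if (length(val_idx)) {
      Yv <- matrix(0, nrow(pass$probs), c)
      Yv[cbind(val_idx, y[val_idx])] <- 1
      cross_entropy_loss(pass$probs, Yv, val_idx) / length(val_idx)
    } else pass$loss
    val_acc <- if (length(val_idx)) {
      mean(max.col(pass$probs[val_idx, , drop = FALSE]) == y[val_idx])
    } else NA_real_
    log[[ep]] <- data.frame(epoch = ep, loss = pass$loss, L1 = pass$L1,
                            L2 = pass$L2, val_loss = val_loss,
                            val_acc = val_acc)
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
    upd <- adam_step(params, pass$grads, state, config$lr)
    params <- upd$params; state <- upd$state
  }
  out <- list(params = best$params, config = config, prior_A = prior_A,
              log = do.call(rbind, log[!vapply(log, is.null, logical(1))]),
              best_epoch = best$epoch, classes = classes)
  class(out) <- "pglcn_model"
  out
}

#' @export
print.pglcn_model <- function(x, ...) {
  cat(sprintf("<pglcn_model> mode = %s, %d classes, best epoch %d (val loss %.4f)\n",
              x$config$mode, length(x$classes), x$best_epoch,
              min(x$log$val_loss)))
  invisible(x)
}

#' Predict class probabilities from a trained model
#' @param object a `pglcn_model`.
#' @param features new features (same layout as training).
#' @param ... unused.
#' @return samples x c probability matrix (columns ordered as
#'   `object$classes`).
#' @export
predict.pglcn_model <- function(object, features, ...) {
  pglcn_forward(features, object$prior_A, object$params, object$config)$probs
}
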