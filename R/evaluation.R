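#' Class balancing, cross-validation, and baseline comparison
#'
#' Evaluation follows a repeated stratified scheme: 5-fold
#' cross-validation with 5 repeats (20% test), the non-test portion
#' split 80/20 into training and validation, SMOTE applied to the
#' training partition only, and accuracy, recall, F1, AUC and precision
#' reported as mean and standard deviation over the 25 runs.
#'
#' @name evaluation
NULL

#' SMOTE minority oversampling
#'
#' Synthetic minority samples `x + u (x_nn - x)` with `u ~ Uniform(0,1)`
#' and `x_nn` one of the `k` nearest minority neighbors of `x`, generated
#' until the classes are equal.  Originals are retained and synthetic
#' rows are flagged.
#'
#' @param features sample x f numeric matrix.
#' @param labels binary vector (0/1).
#' @param k_neighbors neighborhood size (default 5; reduced with a
#'   warning when the minority class is too small).
#' @param seed RNG seed.
#' @return list with `features`, `labels` and logical `synthetic`.
#' @export
smote_oversample <- function(features, labels, k_neighbors = 5L, seed = 0L) {
  X <- as.matrix(features)
  labels <- as.integer(labels)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  minority <- if (tab[["1"]] <= tab[["0"]]) 1L else 0L
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min < 2L) stop("minority class needs at least 2 samples for SMOTE",
                       call. = FALSE)
  if (n_min == n_maj) {
    return(list(features = X, labels = labels,
                synthetic = rep(FALSE, nrow(X))))
  }
  if (k_neighbors >= n_min) {
    k_neighbors <- n_min - 1L
    warning(sprintf("k_neighbors reduced to %d (minority size)", k_neighbors),
            call. = FALSE)
  }
  min_idx <- which(labels == minority)
  Xm <- X[min_idx, , drop = FALSE]
  Dm <- as.matrix(dist(Xm))
  diag(Dm) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min), function(i)
    order(Dm[i, ])[seq_len(k_neighbors)]))
  n_new <- n_maj - n_min
  with_seed(seed, {
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
    u <- runif(n_new)
    Xnew <- Xm[base, , drop = FALSE] +
      u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
    list(features = rbind(X, Xnew),
         labels = c(labels, rep(minority, n_new)),
         synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)))
  })
}

# Stratified assignment of indices to `folds` groups.
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified cross-validation plan
#'
#' For each repeat, a stratified k-fold assignment; each fold in turn is
#' the test set (20% for 5 folds) and the remaining samples are split,
#' again stratified, into training (80%) and validation (20%).
#'
#' @param labels class labels.
#' @param seed RNG seed.
#' @param folds folds per repeat (default 5).
#' @param repeats repeats (default 5).
#' @param val_fraction fraction of the non-test samples used for
#'   validation (default 0.2).
#' @return object of class `pglcn_cv_plan`: list `splits` of
#'   `repeats * folds` entries with `train`, `val`, `test` index vectors,
#'   plus the settings.
#' @export
make_cv_plan <- function(labels, seed = 0L, folds = 5L, repeats = 5L,
                         val_fraction = 0.2) {
  labels <- as.vector(labels)
  if (any(table(labels) < folds)) {
    stop("every class needs at least `folds` samples", call. = FALSE)
  }
  splits <- with_seed(seed, {
    out <- list()
    for (r in seq_len(repeats)) {
      fold_of <- stratified_folds(labels, folds)
      for (fd in seq_len(folds)) {
        test <- which(fold_of == fd)
        rest <- which(fold_of != fd)
        val_assign <- stratified_folds(labels[rest], round(1 / val_fraction))
        val <- rest[val_assign == 1L]
        train <- setdiff(rest, val)
        out[[length(out) + 1L]] <-
          list(repeat_id = r, fold = fd, train = sort(train),
               val = sort(val), test = sort(test))
      }
    }
    out
  })
  structure(list(splits = splits, folds = folds, repeats = repeats,
                 val_fraction = val_fraction, seed = seed,
                 n = length(labels)),
            class = "pglcn_cv_plan")
}

#' Binary classification metrics
#'
#' Accuracy, recall, precision and F1 from the confusion matrix at the
#' given probability threshold (positive class = 1); AUC from the score
#' ranking (threshold-free).
#'
#' @param true_labels 0/1 truth.
#' @param scores predicted positive-class probabilities in `[0, 1]`.
#' @param threshold classification cutoff (default 0.5).
#' @return named list: `accuracy`, `recall`, `f1`, `auc`, `precision`.
#'   AUC is `NA` if the truth has one class; precision/recall/F1 are `NA`
#'   when their denominators are empty.
#' @export
compute_metrics <- function(true_labels, scores, threshold = 0.5) {
  y <- as.integer(true_labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  prec <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(prec) || is.na(rec)) {
    NA_real_
  } else if (prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else 0
  list(accuracy = (tp + tn) / length(y), recall = rec, f1 = f1,
       auc = rank_auc(scores, y), precision = prec)
}

# ---- reference classifier baselines -----------------------------------

# AdaBoost.M1 with depth-1 rpart stumps.
adaboost_fit <- function(X, y, rounds = 50L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(y = factor(y), X)
  stumps <- list(); alphas <- numeric(0)
  for (r in seq_len(rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = 0, minsplit = 2,
                                                       xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5 || err <= 1e-10) {
      if (err <= 1e-10) { stumps[[r]] <- fit; alphas[r] <- 10 }
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[r]] <- fit; alphas[r] <- alpha
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas)
}

adaboost_predict <- function(model, X) {
  df <- data.frame(X)
  score <- rep(0, nrow(df))
  for (r in seq_along(model$stumps)) {
    pred <- as.integer(as.character(predict(model$stumps[[r]], df,
                                            type = "class")))
    score <- score + model$alphas[r] * ifelse(pred == 1L, 1, -1)
  }
  plogis(2 * score)
}

# Fit one named baseline and return positive-class probabilities on Xte.
fit_predict_baseline <- function(name, Xtr, ytr, Xte, seed) {
  with_seed(seed, switch(
    name,
    logreg = {
      fit <- glmnet::glmnet(Xtr, factor(ytr), family = "binomial",
                            alpha = 0, lambda = 1e-3)
      as.vector(predict(fit, Xte, type = "response"))
    },
    svm_rbf = {
      fit <- e1071::svm(Xtr, factor(ytr), kernel = "radial",
                        probability = TRUE)
      attr(predict(fit, Xte, probability = TRUE), "probabilities")[, "1"]
    },
    svm_linear = {
      fit <- e1071::svm(Xtr, factor(ytr), kernel = "linear",
                        probability = TRUE)
      attr(predict(fit, Xte, probability = TRUE), "probabilities")[, "1"]
    },
    rf = {
      fit <- randomForest::randomForest(Xtr, factor(ytr))
      predict(fit, Xte, type = "prob")[, "1"]
    },
    adaboost = {
      fit <- adaboost_fit(Xtr, ytr)
      adaboost_predict(fit, Xte)
    },
    dtree = {
      df <- data.frame(y = factor(ytr), Xtr)
      fit <- rpart::rpart(y ~ ., data = df)
      predict(fit, data.frame(Xte), type = "prob")[, "1"]
    },
    dummy = rep(mean(ytr), nrow(Xte)),
    stop(sprintf("unknown model '%s'", name), call. = FALSE)
  ))
}

BASELINE_NAMES <- c("logreg", "svm_rbf", "svm_linear", "rf", "adaboost",
                    "dtree", "dummy", "pglcn")

#' Compare classifiers under a shared cross-validation plan
#'
#' Every model is trained and evaluated on identical splits.  SMOTE is
#' applied to the training partition of each split only (never to
#' validation or test), on the flattened feature representation.
#'
#' @param features n x p x 3q pathway feature array (see
#'   [pathway_pca_features()]) or an n x f matrix.  Baselines use the
#'   flattened matrix; `"pglcn"` uses the array with `prior_A`.
#' @param labels 0/1 TMB labels.
#' @param model_specs character vector of model names among `"pglcn"`,
#'   `"logreg"`, `"svm_rbf"`, `"svm_linear"`, `"rf"`, `"adaboost"`,
#'   `"dtree"`, `"dummy"`, or a named list where each element is a list
#'   with optional extra settings (`config` for pglcn).
#' @param cv_plan a [make_cv_plan()] object.
#' @param prior_A pathway adjacency (required when `"pglcn"` is among the
#'   models).
#' @param smote apply SMOTE to training partitions (default TRUE).
#' @param k_neighbors SMOTE neighborhood size.
#' @param seed base seed for per-split model seeds.
#' @return data frame with one row per model: mean and sd of accuracy,
#'   recall, F1, AUC, precision over the splits, and mean wall time per
#'   run (seconds).
#' @export
run_model_comparison <- function(features, labels, model_specs, cv_plan,
                                 prior_A = NULL, smote = TRUE,
                                 k_neighbors = 5L, seed = 0L) {
  if (is.character(model_specs)) {
    model_specs <- stats::setNames(
      lapply(model_specs, function(nm) list()), model_specs)
  }
  bad <- setdiff(names(model_specs), BASELINE_NAMES)
  if (length(bad)) stop(sprintf("unknown model name '%s'", bad[1]), call. = FALSE)
  is_array <- length(dim(features)) == 3L
  flat <- if (is_array) {
    matrix(features, dim(features)[1L], prod(dim(features)[-1L]))
  } else as.matrix(features)
  y <- as.integer(labels)

  rows <- list()
  for (mi in seq_along(model_specs)) {
    nm <- names(model_specs)[mi]
    spec <- model_specs[[mi]]
    mets <- list(); times <- numeric(0)
    for (si in seq_along(cv_plan$splits)) {
      sp <- cv_plan$splits[[si]]
      split_seed <- derive_seed(seed, si)
      t0 <- proc.time()[["elapsed"]]
      if (nm == "pglcn") {
        if (is.null(prior_A)) stop("pglcn requires `prior_A`", call. = FALSE)
        scores <- pglcn_cv_scores(features, y, sp, prior_A, spec,
                                  smote, k_neighbors, split_seed)
      } else {
        tr <- c(sp$train, sp$val)   # baselines have no validation stage
        Xtr <- flat[tr, , drop = FALSE]; ytr <- y[tr]
        if (smote) {
          bal <- smote_oversample(Xtr, ytr, k_neighbors, seed = split_seed)
          Xtr <- bal$features; ytr <- bal$labels
        }
        scores <- fit_predict_baseline(nm, Xtr, ytr,
                                       flat[sp$test, , drop = FALSE],
                                       split_seed)
      }
      times <- c(times, proc.time()[["elapsed"]] - t0)
      mets[[si]] <- compute_metrics(y[sp$test], scores)
    }
    mm <- do.call(rbind, lapply(mets, as.data.frame))
    rows[[mi]] <- data.frame(
      model = nm,
      accuracy = mean(mm$accuracy), accuracy_sd = sd(mm$accuracy),
      recall = mean(mm$recall, na.rm = TRUE), recall_sd = sd(mm$recall, na.rm = TRUE),
      f1 = mean(mm$f1, na.rm = TRUE), f1_sd = sd(mm$f1, na.rm = TRUE),
      auc = mean(mm$auc, na.rm = TRUE), auc_sd = sd(mm$auc, na.rm = TRUE),
      precision = mean(mm$precision, na.rm = TRUE),
      precision_sd = sd(mm$precision, na.rm = TRUE),
      time = mean(times))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# PGLCN inside one CV split: SMOTE on the flattened training features,
# reshaped back to the pathway tensor; validation drives early stopping.
pglcn_cv_scores <- function(features, y, sp, prior_A, spec, smote,
                            k_neighbors, seed) {
  p <- dim(features)[2L]; q3 <- dim(features)[3L]
  Xtr_flat <- matrix(features[sp$train, , , drop = FALSE],
                     length(sp$train), p * q3)
  ytr <- y[sp$train]
  if (smote) {
    bal <- smote_oversample(Xtr_flat, ytr, k_neighbors, seed = seed)
    Xtr_flat <- bal$features; ytr <- bal$labels
  }
  n_tr <- nrow(Xtr_flat)
  n_val <- length(sp$val); n_te <- length(sp$test)
  arr <- array(0, dim = c(n_tr + n_val + n_te, p, q3))
  arr[seq_len(n_tr), , ] <- array(Xtr_flat, dim = c(n_tr, p, q3))
  arr[n_tr + seq_len(n_val), , ] <- features[sp$val, , , drop = FALSE]
  arr[n_tr + n_val + seq_len(n_te), , ] <- features[sp$test, , , drop = FALSE]
  labels_all <- c(ytr, y[sp$val], rep(0L, n_te))
  cfg <- spec$config
  if (is.null(cfg)) cfg <- pglcn_config(mode = "cohort", seed = seed)
  cfg$seed <- as.integer(seed)
  model <- train_pglcn(
    list(features = arr, labels = labels_all,
         train_idx = seq_len(n_tr), val_idx = n_tr + seq_len(n_val)),
    prior_A, cfg)
  probs <- predict(model, arr[n_tr + n_val + seq_len(n_te), , , drop = FALSE])
  probs[, match(1L, model$classes)]
}
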