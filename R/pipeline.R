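#' End-to-end drivers
#'
#' High-level entry points wiring generation, training, explanation and
#' reporting, with per-stage seeds fanned out deterministically from one
#' global seed and a JSON manifest written next to every artifact
#' directory.
#'
#' @name pipeline
NULL

write_manifest <- function(dir, config, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config = config, seed = seed,
         r_version = as.character(getRversion()),
         pglcn_version = as.character(utils::packageVersion("pglcn"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Stratified train/validation split of node indices.
split_nodes <- function(labels, train_fraction = 0.8, seed = 0L) {
  with_seed(seed, {
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      train <- c(train, idx[seq_len(ceiling(train_fraction * length(idx)))])
    }
    list(train = sort(train),
         val = sort(setdiff(seq_along(labels), train)))
  })
}

#' Train a node classifier on one benchmark and score its explanations
#'
#' @param bench a `pglcn_benchmark`.
#' @param seed seed for the split, initialization and masks.
#' @param config transductive [pglcn_config()] (default settings tuned
#'   for the benchmark sizes).
#' @param expl_config an [explainer_config()].
#' @param nodes motif nodes to explain (default: all).
#' @return list with `model`, `val_accuracy`, `explanation` (see
#'   [explain_benchmark()]).
#' @export
run_benchmark_once <- function(bench, seed = 0L, config = NULL,
                               expl_config = NULL, nodes = NULL) {
  if (is.null(config)) {
    config <- pglcn_config(mode = "transductive", embed_dim = 4L,
                           hidden = c(16L, 16L), epochs = 600L,
                           patience = 60L, lr = 0.01,
                           seed = derive_seed(seed, 11L))
  }
  if (is.null(expl_config)) {
    expl_config <- explainer_config(seed = derive_seed(seed, 12L))
  }
  sp <- split_nodes(bench$node_labels, seed = derive_seed(seed, 10L))
  A <- benchmark_adjacency(bench)
  model <- train_pglcn(
    list(features = bench$node_features, labels = bench$node_labels,
         train_idx = sp$train, val_idx = sp$val),
    A, config)
  probs <- pglcn_forward(bench$node_features, A, model$params,
                         model$config)$probs
  val_acc <- mean(max.col(probs[sp$val, , drop = FALSE]) ==
                    match(bench$node_labels[sp$val], model$classes))
  expl <- explain_benchmark(bench, model, config = expl_config,
                            nodes = nodes)
  list(model = model, val_accuracy = val_acc, explanation = expl)
}

#' Run the five-benchmark explanation-fidelity suite
#'
#' For each dataset and seed: generate the benchmark, train the node
#' classifier, fit edge masks for the motif nodes, and average the
#' per-node explanation AUC.  Training failures are recorded as NA and
#' the run continues.
#'
#' @param names benchmark names (subset of the five).
#' @param seeds nonempty integer vector of seeds.
#' @param out optional artifact directory (manifest + table written).
#' @param nodes_per_dataset optional cap on motif nodes explained per
#'   dataset (default: all motif nodes).
#' @param config,expl_config see [run_benchmark_once()].
#' @return list with `table` (per-dataset mean and sd of the AUC over
#'   seeds) and `runs` (per-run details).
#' @export
run_benchmark_suite <- function(names = BENCHMARK_NAMES, seeds = 0:2,
                                out = NULL, nodes_per_dataset = NULL,
                                config = NULL, expl_config = NULL) {
  if (length(seeds) == 0L) stop("`seeds` must be nonempty", call. = FALSE)
  names <- match.arg(names, BENCHMARK_NAMES, several.ok = TRUE)
  runs <- list()
  for (nm in names) {
    for (sd_i in seeds) {
      res <- tryCatch({
        bench <- make_benchmark(nm, seed = sd_i)
        nodes <- sort(unlist(bench$motif_nodes))
        if (!is.null(nodes_per_dataset) &&
            length(nodes) > nodes_per_dataset) {
          nodes <- with_seed(derive_seed(sd_i, 13L),
                             sort(sample(nodes, nodes_per_dataset)))
        }
        r <- run_benchmark_once(bench, seed = sd_i, config = config,
                                expl_config = expl_config, nodes = nodes)
        list(name = nm, seed = sd_i, auc = r$explanation$auc,
             val_accuracy = r$val_accuracy,
             n_explained = r$explanation$n_explained, error = NA_character_)
      }, error = function(e) {
        list(name = nm, seed = sd_i, auc = NA_real_,
             val_accuracy = NA_real_, n_explained = 0L,
             error = conditionMessage(e))
      })
      runs[[length(runs) + 1L]] <- res
    }
  }
  df <- do.call(rbind, lapply(runs, as.data.frame))
  tab <- do.call(rbind, lapply(split(df, df$name), function(g) {
    data.frame(name = g$name[1L], auc = mean(g$auc, na.rm = TRUE),
               auc_sd = sd(g$auc, na.rm = TRUE), n_seeds = nrow(g))
  }))
  tab <- tab[match(names, tab$name), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(out)) {
    write_manifest(out, list(names = names, seeds = seeds), seeds[1L])
    write.table(tab, file.path(out, "fidelity.tsv"), sep = "\t",
                row.names = FALSE)
    write.table(df, file.path(out, "runs.tsv"), sep = "\t",
                row.names = FALSE)
  }
  list(table = tab, runs = df)
}

#' Simulate, featurize, train, evaluate and explain a synthetic cohort
#'
#' Smoke-testable twin of the full clinical pipeline on simulated data:
#' simulate a pathway graph and a multi-omics cohort with planted
#' pathway-level TMB effects, build per-pathway PCA features, run the
#' cross-validated model comparison, train one final model and explain
#' patients.
#'
#' @param seed global seed.
#' @param n_patients,p,effect_pathways,effect_size,noise_sd,high_fraction
#'   cohort settings (see [simulate_multiomics_cohort()];
#'   `effect_pathways` is a count here, taking the first k pathway ids,
#'   which always form a connected subtree).
#' @param q principal components per omic.
#' @param models model names for [run_model_comparison()].
#' @param folds,repeats cross-validation settings.
#' @param config cohort [pglcn_config()] for the final model.
#' @param n_explain patients to explain (default 5).
#' @param out optional artifact directory.
#' @return list with `comparison` (metric table), `model`, `cohort`,
#'   `features`, `explanations`, `test_auc`.
#' @export
end_to_end_synthetic <- function(seed = 0L, n_patients = 200L, p = 20L,
                                 effect_pathways = 8L, effect_size = 2,
                                 noise_sd = 1, high_fraction = 0.3,
                                 q = 2L, models = c("logreg", "rf", "dummy"),
                                 folds = 5L, repeats = 1L, config = NULL,
                                 n_explain = 5L, out = NULL) {
  graph <- simulate_pathway_graph(p = p, seed = derive_seed(seed, 1L))
  eff <- graph$pathway_ids[seq_len(effect_pathways)]
  cohort <- simulate_multiomics_cohort(
    n_patients, graph, effect_pathways = eff, effect_size = effect_size,
    noise_sd = noise_sd, high_fraction = high_fraction,
    seed = derive_seed(seed, 2L))
  feats <- pathway_pca_features(cohort, graph, q = q)
  y <- cohort$tmb_label

  plan <- make_cv_plan(y, seed = derive_seed(seed, 3L), folds = folds,
                       repeats = repeats)
  comparison <- run_model_comparison(feats$values, y, models, plan,
                                     prior_A = feats$adjacency,
                                     seed = derive_seed(seed, 4L))

  if (is.null(config)) {
    config <- pglcn_config(mode = "cohort", seed = derive_seed(seed, 5L))
  }
  sp <- plan$splits[[1L]]
  # leakage-free featurization for the held-out evaluation of the final
  # model: PCA axes fitted on the training patients only
  feats_fold <- pathway_pca_features(cohort, graph, q = q,
                                     fit_patients = sp$train)
  model <- train_pglcn(
    list(features = feats_fold$values, labels = y,
         train_idx = sp$train, val_idx = sp$val),
    feats_fold$adjacency, config)
  probs <- predict(model, feats_fold$values[sp$test, , , drop = FALSE])
  test_auc <- rank_auc(probs[, match(1L, model$classes)], y[sp$test])

  expl_cfg <- explainer_config(seed = derive_seed(seed, 6L))
  pick <- head(sp$test[order(-probs[, match(1L, model$classes)])], n_explain)
  explanations <- lapply(pick, function(b) {
    fit_explanation(model,
                    matrix(feats_fold$values[b, , ], p,
                           dim(feats_fold$values)[3L]),
                    feats_fold$adjacency, config = expl_cfg)
  })
  names(explanations) <- cohort$patient_ids[pick]

  if (!is.null(out)) {
    write_manifest(out, list(n_patients = n_patients, p = p,
                             effect_pathways = effect_pathways,
                             effect_size = effect_size, q = q,
                             models = models, folds = folds,
                             repeats = repeats), seed)
    write.table(comparison, file.path(out, "comparison.tsv"), sep = "\t",
                row.names = FALSE)
  }
  list(comparison = comparison, model = model, cohort = cohort,
       features = feats, explanations = explanations,
       test_auc = test_auc, test_idx = sp$test)
}
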