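# Shared fixtures and independent oracles.

# Exhaustive pairwise AUC oracle: concordant pairs / all (pos, neg)
# pairs, ties counted one half.  Independent of the rank-based
# implementation under test.
brute_auc <- function(scores, flags) {
  flags <- as.logical(flags)
  pos <- scores[flags]; neg <- scores[!flags]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Central finite differences of f at x (vector or matrix, elementwise).
finite_diff <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Small pathway graph + cohort + features for cohort-mode tests.
tiny_cohort_setup <- function(n = 60, p = 8, effect_k = 3, effect_size = 3,
                              seed = 42) {
  graph <- simulate_pathway_graph(p = p, genes_per_pathway = 6,
                                  seed = seed)
  eff <- graph$pathway_ids[seq_len(effect_k)]
  cohort <- simulate_multiomics_cohort(
    n, graph, effect_pathways = eff, effect_size = effect_size,
    high_fraction = 0.4, seed = seed + 1)
  feats <- pathway_pca_features(cohort, graph, q = 2)
  list(graph = graph, cohort = cohort, feats = feats, eff = eff)
}

# A small trained transductive model on a reduced BA-House benchmark.
tiny_bench_model <- function(seed = 7) {
  bench <- make_benchmark("BA-House", seed = seed, n_base = 60L,
                          n_motifs = 12L)
  sp <- pglcn:::split_nodes(bench$node_labels, seed = seed)
  cfg <- pglcn_config(mode = "transductive", embed_dim = 3L,
                      hidden = c(8L, 8L), epochs = 150L, patience = 30L,
                      seed = seed)
  model <- train_pglcn(
    list(features = bench$node_features, labels = bench$node_labels,
         train_idx = sp$train, val_idx = sp$val),
    pglcn:::benchmark_adjacency(bench), cfg)
  list(bench = bench, model = model, split = sp)
}
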