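#' Synthetic motif-graph benchmarks
#'
#' Five node-classification datasets with ground-truth motif structure,
#' used to quantify how faithfully an explainer recovers the subgraph that
#' determines a node's label: `BA-House`, `BA-Community`, `BA-Grid`,
#' `Tree-Cycles`, `Tree-Grids`.  Each dataset is a base graph (a 300-node
#' Barabasi-Albert preferential-attachment graph or a depth-8 balanced
#' binary tree with 255 nodes) to which 80 copies of a small motif (5-node
#' house, 3x3 grid, or 6-cycle) are attached at uniformly chosen base
#' nodes, one attachment edge per motif.  Within-motif edges are the
#' ground-truth explanation; attachment edges are not.
#'
#' @name synthetic-benchmarks
NULL

BENCHMARK_NAMES <- c("BA-House", "BA-Community", "BA-Grid",
                     "Tree-Cycles", "Tree-Grids")

#' Generate a Barabasi-Albert preferential-attachment graph
#'
#' Each newly added node attaches to `m_attach` existing nodes chosen with
#' probability proportional to degree.  The result is connected and has
#' neither self-loops nor duplicate undirected edges.
#'
#' @param n_nodes number of nodes (must exceed `m_attach`).
#' @param m_attach edges added per new node (default 1, a sparse tree base).
#' @param seed integer RNG seed.
#' @return integer matrix with two columns (undirected edge list, 1-based).
#' @export
make_ba_graph <- function(n_nodes, m_attach = 1L, seed = 0L) {
  stop_if_not_scalar_count(n_nodes, "n_nodes")
  stop_if_not_scalar_count(m_attach, "m_attach")
  if (n_nodes <= m_attach) {
    stop("`n_nodes` must be greater than `m_attach`", call. = FALSE)
  }
  g <- with_seed(seed, igraph::sample_pa(n_nodes, power = 1, m = m_attach,
                                         directed = FALSE))
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  canonical_edges(el)
}

# Balanced binary tree with `depth` levels (2^depth - 1 nodes).
make_tree_graph <- function(depth = 8L) {
  stop_if_not_scalar_count(depth, "depth")
  n <- 2L^depth - 1L
  g <- igraph::make_tree(n, children = 2, mode = "undirected")
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  canonical_edges(el)
}

# Sort each edge (min, max) and order rows; drops nothing (inputs are simple).
canonical_edges <- function(el) {
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  storage.mode(el) <- "integer"
  dimnames(el) <- NULL
  el
}

#' Construct a canonical motif
#'
#' * `house`: 5 nodes, 6 edges — a 4-cycle (two bottom and two middle/top
#'   wall nodes) plus a roof apex joined to the two top wall nodes.  Roles
#'   distinguish bottom (1), middle (2) and top/roof (3) positions.
#' * `grid3x3`: a 3x3 lattice, 9 nodes, 12 edges, single role (the
#'   grid-vs-base distinction is the classification task).
#' * `cycle6`: a 6-cycle, 6 nodes, 6 edges, single role.
#'
#' @param kind one of `"house"`, `"grid3x3"`, `"cycle6"`.
#' @return list with `edges` (1-based, local ids), `roles` (integer per
#'   node; role ids start at 1) and `n_nodes`.
#' @export
make_motif <- function(kind) {
  kind <- match.arg(kind, c("house", "grid3x3", "cycle6"))
  if (kind == "house") {
    # 1,2 bottom; 3,4 middle; 5 roof apex
    edges <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L),
                   c(3L, 4L), c(3L, 5L), c(4L, 5L))
    roles <- c(1L, 1L, 2L, 2L, 3L)
  } else if (kind == "grid3x3") {
    idx <- function(r, c) (r - 1L) * 3L + c
    edges <- NULL
    for (r in 1:3) for (c in 1:3) {
      if (c < 3L) edges <- rbind(edges, c(idx(r, c), idx(r, c + 1L)))
      if (r < 3L) edges <- rbind(edges, c(idx(r, c), idx(r + 1L, c)))
    }
    roles <- rep(1L, 9L)
  } else {
    edges <- cbind(1:6, c(2:6, 1L))
    roles <- rep(1L, 6L)
  }
  list(edges = canonical_edges(edges), roles = roles,
       n_nodes = length(roles), kind = kind)
}

#' Attach motif copies to a base graph
#'
#' Adds `count` disjoint copies of a motif, each joined to one uniformly
#' chosen base node (with replacement) by a single attachment edge from the
#' motif's first node.  Attachment edges are never flagged as motif edges.
#'
#' @param base integer edge matrix (1-based) of the base graph.
#' @param kind motif kind, see [make_motif()].
#' @param count number of motif copies (>= 1).
#' @param seed integer RNG seed for attachment-point choice.
#' @return list with `edges`, `motif_edge_flags` (logical per edge row),
#'   `motif_nodes` (list of integer vectors, one per motif copy),
#'   `node_roles` (integer per node: 0 for base nodes, motif role otherwise)
#'   and `n_base`.
#' @export
attach_motifs <- function(base, kind, count, seed = 0L) {
  if (is.null(base) || nrow(base) == 0L) stop("base graph is empty", call. = FALSE)
  stop_if_not_scalar_count(count, "count")
  motif <- make_motif(kind)
  n_base <- max(base)
  anchors <- with_seed(seed, sample.int(n_base, count, replace = TRUE))

  edges <- base
  flags <- rep(FALSE, nrow(base))
  motif_nodes <- vector("list", count)
  roles <- rep(0L, n_base)
  offset <- n_base
  for (i in seq_len(count)) {
    ids <- offset + seq_len(motif$n_nodes)
    medges <- matrix(ids[motif$edges], ncol = 2L)
    edges <- rbind(edges, medges, c(anchors[i], ids[1L]))
    flags <- c(flags, rep(TRUE, nrow(medges)), FALSE)
    motif_nodes[[i]] <- ids
    roles <- c(roles, motif$roles)
    offset <- offset + motif$n_nodes
  }
  storage.mode(edges) <- "integer"
  list(edges = edges, motif_edge_flags = flags, motif_nodes = motif_nodes,
       node_roles = roles, n_base = n_base, motif_kind = kind)
}

# Degree-derived node features: constant column, degree transforms,
# small-degree indicators, neighbour-degree summaries, local clustering.
structural_features <- function(edges, n_nodes) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
  deg <- igraph::degree(g)
  mx <- max(deg, 1)
  adj <- igraph::as_adj_list(g)
  nbd <- function(f, default) {
    vapply(adj, function(v) if (length(v)) f(deg[as.integer(v)]) else default,
           numeric(1))
  }
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  X <- cbind(1, deg / mx, log1p(deg) / log1p(mx),
             as.numeric(deg == 1L), as.numeric(deg == 2L),
             as.numeric(deg == 3L),
             nbd(mean, 0) / mx, nbd(max, 0) / mx, nbd(min, 0) / mx,
             cc)
  colnames(X) <- c("ones", "deg", "logdeg", "deg1", "deg2", "deg3",
                   "nb_mean", "nb_max", "nb_min", "clust")
  X
}

#' Generate a synthetic motif benchmark
#'
#' @param name one of `"BA-House"`, `"BA-Community"`, `"BA-Grid"`,
#'   `"Tree-Cycles"`, `"Tree-Grids"`.
#' @param seed integer RNG seed; regenerating with the same seed is
#'   bit-for-bit identical.
#' @param feature_policy `"structural"` (default; degree-derived columns,
#'   dimension 10) or `"ones"` (constant ones, dimension 10).
#'   `BA-Community` additionally appends two community-indexed Gaussian
#'   columns (mean +1 / -1 by community, sd 0.5) so the two communities
#'   are distinguishable.
#' @param n_base base-graph size (default 300 for BA bases; tree bases are
#'   fixed at depth 8, 255 nodes).
#' @param n_motifs number of attached motif copies (default 80).
#' @param m_attach Barabasi-Albert attachment parameter (default 5, the
#'   convention of this benchmark family: a dense base keeps explanation
#'   neighborhoods populated with negative edges).
#' @param perturb_frac fraction of the edge count added as random noise
#'   edges (never flagged as motif edges).  Default 0.01 for the BA-based
#'   datasets and 0.1 for the tree-based ones, whose sparse bases
#'   otherwise let node degree alone reveal motif membership.
#' @return an object of class `pglcn_benchmark`: list with `name`, `edges`
#'   (1-based undirected edge matrix), `node_features`, `node_labels`
#'   (integer classes, base class 0), `motif_edge_flags`, `motif_nodes`,
#'   `seed`.
#' @export
make_benchmark <- function(name, seed = 0L,
                           feature_policy = c("structural", "ones"),
                           n_base = 300L, n_motifs = 80L, m_attach = 5L,
                           perturb_frac = NULL) {
  name <- match.arg(name, BENCHMARK_NAMES)
  feature_policy <- match.arg(feature_policy)
  if (is.null(perturb_frac)) {
    perturb_frac <- if (name %in% c("Tree-Cycles", "Tree-Grids")) 0.1 else 0.01
  }

  if (name == "BA-Community") {
    b1 <- make_benchmark("BA-House", seed = derive_seed(seed, 1L),
                         feature_policy = feature_policy,
                         n_base = n_base, n_motifs = n_motifs,
                         m_attach = m_attach, perturb_frac = perturb_frac)
    b2 <- make_benchmark("BA-House", seed = derive_seed(seed, 2L),
                         feature_policy = feature_policy,
                         n_base = n_base, n_motifs = n_motifs,
                         m_attach = m_attach, perturb_frac = perturb_frac)
    n1 <- nrow(b1$node_features)
    n2 <- nrow(b2$node_features)
    n <- n1 + n2
    edges <- rbind(b1$edges, b2$edges + n1)
    flags <- c(b1$motif_edge_flags, b2$motif_edge_flags)
    motif_nodes <- c(b1$motif_nodes, lapply(b2$motif_nodes, `+`, n1))
    labels <- c(b1$node_labels, b2$node_labels + 4L)
    n_cross <- max(1L, round(0.01 * n))
    cross <- with_seed(derive_seed(seed, 3L), cbind(
      sample.int(n1, n_cross, replace = TRUE),
      n1 + sample.int(n2, n_cross, replace = TRUE)))
    storage.mode(cross) <- "integer"
    edges <- rbind(edges, cross)
    flags <- c(flags, rep(FALSE, n_cross))
    comm <- rep(c(1, -1), c(n1, n2))
    gauss <- with_seed(derive_seed(seed, 4L),
                       matrix(rnorm(2L * n, mean = comm, sd = 0.5), n, 2L))
    colnames(gauss) <- c("comm1", "comm2")
    feats <- cbind(rbind(b1$node_features, b2$node_features), gauss)
    out <- list(name = name, edges = edges, node_features = feats,
                node_labels = labels, motif_edge_flags = flags,
                motif_nodes = motif_nodes, seed = seed)
    class(out) <- "pglcn_benchmark"
    return(out)
  }

  base <- switch(name,
    "BA-House" = , "BA-Grid" =
      make_ba_graph(n_base, m_attach, seed = derive_seed(seed, 1L)),
    "Tree-Cycles" = , "Tree-Grids" = make_tree_graph(8L))
  kind <- switch(name, "BA-House" = "house",
                 "BA-Grid" = "grid3x3", "Tree-Cycles" = "cycle6",
                 "Tree-Grids" = "grid3x3")
  at <- attach_motifs(base, kind, n_motifs, seed = derive_seed(seed, 2L))
  n <- length(at$node_roles)
  pt <- perturb_edges(at$edges, n, round(perturb_frac * nrow(at$edges)),
                      seed = derive_seed(seed, 5L))
  at$edges <- pt$edges
  at$motif_edge_flags <- c(at$motif_edge_flags, rep(FALSE, pt$n_added))
  feats <- if (feature_policy == "ones") {
    matrix(1, n, 10L)
  } else {
    structural_features(at$edges, n)
  }
  out <- list(name = name, edges = at$edges, node_features = feats,
              node_labels = at$node_roles, motif_edge_flags = at$motif_edge_flags,
              motif_nodes = at$motif_nodes, seed = seed)
  class(out) <- "pglcn_benchmark"
  out
}

#' @export
print.pglcn_benchmark <- function(x, ...) {
  cat(sprintf(
    "<pglcn_benchmark> %s: %d nodes, %d edges (%d motif edges), %d motifs, %d classes\n",
    x$name, nrow(x$node_features), nrow(x$edges), sum(x$motif_edge_flags),
    length(x$motif_nodes), length(unique(x$node_labels))))
  invisible(x)
}

#' Write a benchmark bundle to a directory
#'
#' Plain-text layout: `edges.txt` (one `u v` pair per line, 0-based ids,
#' with a third column flagging within-motif edges), `labels.tsv`,
#' `features.tsv`, `motifs.tsv` (motif id, node id) and `meta.json`.
#'
#' @param bench a `pglcn_benchmark`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(cbind(bench$edges - 1L, as.integer(bench$motif_edge_flags)),
              file.path(dir, "edges.txt"), row.names = FALSE,
              col.names = FALSE)
  write.table(data.frame(node = seq_len(nrow(bench$node_features)) - 1L,
                         label = bench$node_labels),
              file.path(dir, "labels.tsv"), sep = "\t", row.names = FALSE)
  write.table(bench$node_features, file.path(dir, "features.tsv"),
              sep = "\t", row.names = FALSE)
  motif_tab <- data.frame(
    motif = rep(seq_along(bench$motif_nodes),
                lengths(bench$motif_nodes)) - 1L,
    node = unlist(bench$motif_nodes) - 1L)
  write.table(motif_tab, file.path(dir, "motifs.tsv"), sep = "\t",
              row.names = FALSE)
  jsonlite::write_json(list(name = bench$name, seed = bench$seed),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a benchmark bundle written by [write_benchmark()]
#' @param dir bundle directory.
#' @return a `pglcn_benchmark`.
#' @export
read_benchmark <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  ed <- as.matrix(read.table(file.path(dir, "edges.txt")))
  lab <- read.table(file.path(dir, "labels.tsv"), header = TRUE, sep = "\t")
  feats <- as.matrix(read.table(file.path(dir, "features.tsv"),
                                header = TRUE, sep = "\t"))
  mt <- read.table(file.path(dir, "motifs.tsv"), header = TRUE, sep = "\t")
  edges <- matrix(as.integer(ed[, 1:2]) + 1L, ncol = 2L)
  out <- list(name = meta$name, edges = edges, node_features = feats,
              node_labels = as.integer(lab$label[order(lab$node)]),
              motif_edge_flags = as.logical(ed[, 3L]),
              motif_nodes = unname(split(as.integer(mt$node) + 1L, mt$motif)),
              seed = meta$seed)
  class(out) <- "pglcn_benchmark"
  out
}

# Add `count` random perturbation edges (no self-loops, no duplicates)
# between uniformly chosen node pairs.  Standard in this benchmark family:
# noise edges keep node degree alone from revealing motif membership and
# populate explanation neighborhoods with negative edges.
perturb_edges <- function(edges, n_nodes, count, seed) {
  if (count <= 0L) return(list(edges = edges, n_added = 0L))
  existing <- paste(edges[, 1L], edges[, 2L])
  new <- matrix(integer(0), 0L, 2L)
  with_seed(seed, {
    tries <- 0L
    while (nrow(new) < count && tries < 50L * count) {
      tries <- tries + 1L
      u <- sample.int(n_nodes, 1L); v <- sample.int(n_nodes, 1L)
      if (u == v) next
      key <- paste(min(u, v), max(u, v))
      if (key %in% existing) next
      existing <- c(existing, key)
      new <- rbind(new, c(min(u, v), max(u, v)))
    }
  })
  storage.mode(new) <- "integer"
  list(edges = rbind(edges, new), n_added = nrow(new))
}

# Dense 0/1 prior adjacency (with unit diagonal) from a benchmark edge list.
benchmark_adjacency <- function(bench) {
  n <- nrow(bench$node_features)
  A <- matrix(0, n, n)
  A[bench$edges] <- 1
  A[bench$edges[, 2:1]] <- 1
  diag(A) <- 1
  A
}
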