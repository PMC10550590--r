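#' Pathway prior graphs and multi-omics featurization
#'
#' The biological prior behind the classifier is a graph over Reactome
#' pathways: nodes are pathways, edges are parent-child hierarchy
#' relations, and the diagonal is set to 1 (self-linking).  Per-patient
#' node features are the leading principal components of each pathway's
#' gene-level expression, copy-number and methylation sub-matrices,
#' laid out as a p x 3q matrix per patient (expression PCs first, then
#' copy number, then methylation).
#'
#' @name pathway-graph
NULL

#' Parse a Reactome-style hierarchy relation table into a pathway adjacency
#'
#' @param relations two-column data frame / matrix of parent-child pathway
#'   identifiers, or a path to a tab-separated file in the
#'   `ReactomePathwaysRelation.txt` dialect (no header).
#' @param keep_ids optional character vector defining the pathway universe;
#'   relations mentioning identifiers outside it are dropped (a message
#'   reports the count).  Defaults to all identifiers seen.
#' @return symmetric 0/1 matrix with unit diagonal, dimnames = pathway ids.
#' @export
parse_reactome_hierarchy <- function(relations, keep_ids = NULL) {
  if (is.character(relations) && length(relations) == 1L) {
    relations <- read.table(relations, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  }
  rel <- as.matrix(relations)
  if (nrow(rel) == 0L || ncol(rel) < 2L) {
    stop("empty relation record set", call. = FALSE)
  }
  rel <- rel[, 1:2, drop = FALSE]
  mode(rel) <- "character"
  ids <- if (is.null(keep_ids)) sort(unique(as.vector(rel))) else unique(keep_ids)
  keep <- rel[, 1L] %in% ids & rel[, 2L] %in% ids
  if (any(!keep)) {
    message(sum(!keep), " relation(s) dropped: identifier(s) outside the pathway universe")
  }
  rel <- rel[keep, , drop = FALSE]
  p <- length(ids)
  A <- matrix(0, p, p, dimnames = list(ids, ids))
  if (nrow(rel) > 0L) {
    A[rel] <- 1
    A[rel[, 2:1, drop = FALSE]] <- 1
  }
  diag(A) <- 1
  A
}

#' Parse GMT gene-set records
#'
#' Each record is `pathway_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param gmt path to a GMT file, or a character vector of GMT lines.
#' @return named list mapping pathway id to a character vector of unique
#'   gene symbols.  Pathways with empty gene lists are retained (with a
#'   message).
#' @export
parse_genesets <- function(gmt) {
  lines <- if (length(gmt) == 1L && file.exists(gmt)) readLines(gmt) else gmt
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(parts[[1]])) {
      stop(sprintf("malformed GMT record at line %d", i), call. = FALSE)
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      message(sprintf("pathway '%s' has an empty gene list", parts[[1]]))
    }
    out[[parts[[1]]]] <- genes
  }
  out
}

#' Assemble a pathway graph object
#'
#' The pathway universe is the set of identifiers present in both the
#' hierarchy and the gene-set map.
#'
#' @param adjacency symmetric 0/1 matrix from [parse_reactome_hierarchy()].
#' @param gene_sets named list from [parse_genesets()].
#' @return object of class `pglcn_pathway_graph`: `pathway_ids`,
#'   `adjacency`, `gene_sets`.
#' @export
pathway_graph <- function(adjacency, gene_sets) {
  ids <- intersect(rownames(adjacency), names(gene_sets))
  if (length(ids) == 0L) stop("no pathways shared by hierarchy and gene sets", call. = FALSE)
  out <- list(pathway_ids = ids,
              adjacency = adjacency[ids, ids, drop = FALSE],
              gene_sets = gene_sets[ids])
  class(out) <- "pglcn_pathway_graph"
  out
}

#' @export
print.pglcn_pathway_graph <- function(x, ...) {
  cat(sprintf("<pglcn_pathway_graph> %d pathways, %d hierarchy edges, %d genes\n",
              length(x$pathway_ids),
              (sum(x$adjacency) - length(x$pathway_ids)) / 2,
              length(unique(unlist(x$gene_sets)))))
  invisible(x)
}

#' TMB labels from mutation counts
#'
#' Tumor mutation burden is the per-patient nonsynonymous mutation count
#' divided by the covered megabases; "high" is strictly greater than
#' 10 mutations per megabase.
#'
#' @param mutation_counts nonnegative per-patient counts.
#' @param covered_megabases positive scalar or per-patient vector
#'   (default 38, a common exome footprint).
#' @param threshold rate cutoff (default 10 mutations/Mb, strict `>`).
#' @return list with `rate` and integer `label` (1 = high TMB).
#' @export
compute_tmb_labels <- function(mutation_counts, covered_megabases = 38,
                               threshold = 10) {
  if (any(mutation_counts < 0)) stop("mutation counts must be nonnegative", call. = FALSE)
  if (any(covered_megabases <= 0)) stop("covered megabases must be positive", call. = FALSE)
  rate <- mutation_counts / covered_megabases
  list(rate = rate, label = as.integer(rate > threshold))
}

#' Per-pathway multi-omics PCA features
#'
#' For each pathway and each omic layer, the pathway's gene columns are
#' centered using the fit-set means and projected onto the top-`q`
#' principal axes estimated on the fit set only; every patient (fit or
#' held out) is then scored on those axes.  Column layout per pathway row:
#' expression PCs 1..q, copy-number PCs q+1..2q, methylation PCs 2q+1..3q.
#' Axis signs are fixed by forcing each axis's largest-magnitude loading
#' positive.  Pathways with fewer usable dimensions than `q` get zero
#' padding; pathways with no genes in the cohort are dropped (with a
#' warning) and the adjacency re-indexed.
#'
#' @param cohort a `pglcn_cohort` (see [simulate_multiomics_cohort()]) or a
#'   list with `expression`, `copy_number`, `methylation` patient x gene
#'   matrices sharing dimnames.
#' @param graph a `pglcn_pathway_graph`.
#' @param q principal components per omic (default 2, so 6 columns per
#'   pathway row).
#' @param fit_patients integer indices of patients used to estimate
#'   centers and axes (default: all patients).  Held-out rows never
#'   influence the fit.
#' @return object of class `pglcn_features`: `values` (n x p x 3q array),
#'   `pathway_ids`, `adjacency` (possibly re-indexed), `q`.
#' @export
pathway_pca_features <- function(cohort, graph, q = 2L, fit_patients = NULL) {
  stop_if_not_scalar_count(q, "q")
  G <- cohort$expression; C <- cohort$copy_number; M <- cohort$methylation
  stopifnot(identical(dim(G), dim(C)), identical(dim(G), dim(M)))
  n <- nrow(G)
  genes <- colnames(G)
  if (is.null(fit_patients)) fit_patients <- seq_len(n)

  keep <- vapply(graph$gene_sets, function(gs) any(gs %in% genes), logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " pathway(s) with no genes in the cohort dropped",
            call. = FALSE)
  }
  ids <- graph$pathway_ids[keep]
  p <- length(ids)
  if (p == 0L) stop("no pathway overlaps the cohort genes", call. = FALSE)
  vals <- array(0, dim = c(n, p, 3L * q),
                dimnames = list(rownames(G), ids, NULL))
  omics <- list(G, C, M)
  for (i in seq_len(p)) {
    gs <- intersect(graph$gene_sets[[ids[i]]], genes)
    for (o in 1:3) {
      X <- omics[[o]][, gs, drop = FALSE]
      sc <- pca_project(X, fit_patients, q)
      vals[, i, ((o - 1L) * q + 1L):(o * q)] <- sc
    }
  }
  out <- list(values = vals, pathway_ids = ids,
              adjacency = graph$adjacency[ids, ids, drop = FALSE], q = q)
  class(out) <- "pglcn_features"
  out
}

# Center on fit rows, estimate top-q axes on fit rows, score all rows.
# Axes with (near-)zero variance and missing axes (r_i < q) give zeros.
pca_project <- function(X, fit, q) {
  mu <- colMeans(X[fit, , drop = FALSE])
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc[fit, , drop = FALSE], nu = 0)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > max(tol, 1e-12))
  k <- min(q, rank, ncol(X))
  scores <- matrix(0, nrow(X), q)
  if (k > 0L) {
    V <- sv$v[, seq_len(k), drop = FALSE]
    # sign convention: largest-magnitude loading of each axis positive
    for (j in seq_len(k)) {
      if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
    }
    scores[, seq_len(k)] <- Xc %*% V
  }
  scores
}

#' @export
print.pglcn_features <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pglcn_features> %d patients x %d pathways x %d columns (q = %d)\n",
              d[1], d[2], d[3], x$q))
  invisible(x)
}

#' Simulate a random pathway hierarchy with disjoint gene sets
#'
#' A random tree over `p` pathways (node i's parent drawn uniformly from
#' 1..i-1, so pathways `1..k` always form a connected subtree) with
#' `genes_per_pathway` distinct genes per pathway.
#'
#' @param p number of pathways.
#' @param genes_per_pathway genes per pathway (disjoint blocks).
#' @param seed RNG seed.
#' @return a `pglcn_pathway_graph`; pathway ids are `"P1"..."Pp"`, genes
#'   `"G1"...`.
#' @export
simulate_pathway_graph <- function(p = 30L, genes_per_pathway = 10L, seed = 0L) {
  stop_if_not_scalar_count(p, "p")
  with_seed(seed, {
    parents <- c(NA_integer_, vapply(2:p, function(i)
      if (i == 2L) 1L else sample.int(i - 1L, 1L), integer(1)))
    ids <- paste0("P", seq_len(p))
    rel <- data.frame(parent = ids[parents[-1L]], child = ids[-1L])
    A <- parse_reactome_hierarchy(rel, keep_ids = ids)
    genes <- paste0("G", seq_len(p * genes_per_pathway))
    gs <- split(genes, rep(seq_len(p), each = genes_per_pathway))
    names(gs) <- ids
    pathway_graph(A, gs)
  })
}

#' Simulate a multi-omics cohort with planted pathway-level TMB effects
#'
#' High-TMB patients receive a mean shift of `effect_size` on the
#' expression of every gene in `effect_pathways` (and half-size shifts on
#' copy number and on the methylation latent scale); all other values are
#' independent Gaussian noise.  Methylation is squashed to `[0, 1]`
#' (beta-value convention) through a logistic link.  Mutation rates are
#' drawn consistently with the labels: high group strictly above
#' 10 mutations/Mb.
#'
#' @param n_patients cohort size.
#' @param graph a `pglcn_pathway_graph`.
#' @param effect_pathways character vector of affected pathway ids
#'   (subset of `graph$pathway_ids`).
#' @param effect_size nonnegative mean shift on expression (default 2).
#' @param noise_sd Gaussian noise sd (default 1).
#' @param high_fraction prevalence of the high-TMB class in (0, 1)
#'   (default 0.3).
#' @param seed RNG seed.
#' @return object of class `pglcn_cohort`: `patient_ids`, `gene_ids`,
#'   `expression`, `copy_number`, `methylation`, `mutation_rate`,
#'   `tmb_label`.
#' @export
simulate_multiomics_cohort <- function(n_patients, graph, effect_pathways,
                                       effect_size = 2, noise_sd = 1,
                                       high_fraction = 0.3, seed = 0L) {
  stop_if_not_scalar_count(n_patients, "n_patients")
  if (effect_size < 0) stop("`effect_size` must be nonnegative", call. = FALSE)
  if (high_fraction <= 0 || high_fraction >= 1) {
    stop("`high_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (!all(effect_pathways %in% graph$pathway_ids)) {
    stop("`effect_pathways` must be a subset of the graph's pathways", call. = FALSE)
  }
  genes <- sort(unique(unlist(graph$gene_sets)))
  r <- length(genes)
  eff_genes <- genes %in% unlist(graph$gene_sets[effect_pathways])
  with_seed(seed, {
    y <- rbinom(n_patients, 1L, high_fraction)
    shift <- function(size) outer(y, as.numeric(eff_genes) * size)
    G <- matrix(rnorm(n_patients * r, sd = noise_sd), n_patients, r) + shift(effect_size)
    C <- matrix(rnorm(n_patients * r, sd = noise_sd), n_patients, r) + shift(effect_size / 2)
    Mlat <- matrix(rnorm(n_patients * r, sd = noise_sd), n_patients, r) + shift(effect_size / 2)
    Mval <- plogis(Mlat)
    rate <- ifelse(y == 1L, 10 + rexp(n_patients, rate = 1 / 8),
                   runif(n_patients, 0, 10))
    pid <- sprintf("PT%04d", seq_len(n_patients))
    dn <- list(pid, genes)
    dimnames(G) <- dimnames(C) <- dimnames(Mval) <- dn
    out <- list(patient_ids = pid, gene_ids = genes, expression = G,
                copy_number = C, methylation = Mval, mutation_rate = rate,
                tmb_label = as.integer(rate > 10),
                effect_pathways = effect_pathways, seed = seed)
    class(out) <- "pglcn_cohort"
    out
  })
}

#' @export
print.pglcn_cohort <- function(x, ...) {
  cat(sprintf("<pglcn_cohort> %d patients x %d genes; %d high-TMB (%.1f%%)\n",
              length(x$patient_ids), length(x$gene_ids), sum(x$tmb_label),
              100 * mean(x$tmb_label)))
  invisible(x)
}

#' Write a pathway adjacency back to a relation file
#'
#' Inverse of [parse_reactome_hierarchy()]: emits one parent-child pair
#' per upper-triangular off-diagonal 1.
#'
#' @param adjacency symmetric 0/1 matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(adjacency, path) {
  ut <- which(upper.tri(adjacency) & adjacency == 1, arr.ind = TRUE)
  df <- data.frame(parent = rownames(adjacency)[ut[, 1L]],
                   child = colnames(adjacency)[ut[, 2L]])
  write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
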