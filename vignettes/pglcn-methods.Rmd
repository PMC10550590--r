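---
title: "Pathway graph-learning convolutional networks: models, benchmarks, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway graph-learning convolutional networks: models, benchmarks, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pglcn)
```

# Overview

`pglcn` implements a biologically informed graph neural network for
classifying tumor mutation burden (TMB) status from multi-omics data,
together with the mask-based explanation machinery and the synthetic
motif-graph benchmarks used to quantify how faithfully an explanation
recovers the structure that actually determines a prediction.

The package has three layers:

1. **Biological prior and features** — a pathway graph (nodes = Reactome
   pathways, edges = parent-child hierarchy relations, unit diagonal)
   and, per patient, a $p \times 3q$ feature matrix $K_p$ of per-pathway
   principal components from expression, copy number and methylation.
2. **Model** — a graph-learning layer that produces a row-stochastic
   affinity matrix $S$ supported on the prior, simplified graph
   convolutions $X^{(k+1)} = \sigma(S X^{(k)} W^{(k)})$, and (in cohort
   mode) fully connected layers mapping the flattened pathway
   representation to class logits.
3. **Explanation** — per-instance edge and feature masks trained to
   preserve the frozen model's prediction while staying small and
   near-binary, scored against ground truth (synthetic benchmarks) by
   ROC AUC.

# The model

## Graph-learning layer

Node features $g_i$ are projected to a low dimension, $\tilde g_i = g_i
P$ with $P \in \mathbb{R}^{f \times d}$, $d < f$, and pairwise scores

$$S_{ij} = \frac{A_{ij}\,\exp\!\big(\mathrm{ReLU}(a^\top |\tilde g_i -
\tilde g_j|)\big)}{\sum_j A_{ij}\,\exp\!\big(\mathrm{ReLU}(a^\top
|\tilde g_i - \tilde g_j|)\big)}$$

are normalized row-wise over the support of the prior $A$ only.  Because
$A_{ii} = 1$, no row has empty support; rows of $S$ sum to one by
construction, which is what lets the convolution skip Laplacian
normalization.  The pairwise term uses the elementwise *absolute*
difference: the signed form is antisymmetric, so
$\exp(\mathrm{ReLU}(\cdot))$ would silently ignore one direction of
every pair.  The signed variant remains available (`abs_diff = FALSE`).

The graph-learning loss

$$L_1 = \sum_{i,j} \lVert g_i - g_j \rVert_2^2\, S_{ij} + \gamma
\lVert S \rVert_F^2$$

pulls affinity away from distant node pairs; the Frobenius term (weight
`gamma`, default 0.01) pushes rows toward uniformity over their support
(its minimizer alone is the uniform row), controlling how concentrated
the learned graph may become.  A small closed-form property is worth
keeping in mind (and is tested): on a fixed support, the optimal
$\lVert S\rVert_F^2$ is non-increasing in $\gamma$.

## Convolution stack and heads

Transductive mode (one graph, labels on nodes) uses a stack whose last
convolution is the hidden-to-output layer with $c$ classes.  Cohort mode
(one $p$-node pathway graph per patient, shared parameters, per-patient
$S$) uses ReLU convolutions followed by a two-layer fully connected head
on the flattened $p \times g$ representation; flattening preserves
pathway identity, which is what makes per-pathway attribution by the
explainer possible.  The joint objective is $L = L_1 + \lambda L_2$
with $L_2$ the cross-entropy over labeled samples ($\lambda$ default 1);
unlabeled samples contribute to $L_1$ only.  Both losses are implemented
as the plain sums; Adam's per-parameter scaling makes the sum-vs-mean
convention immaterial.

Defaults: cohort mode — two convolutions of width 64, head 128, Adam at
$10^{-3}$, 200 epochs with early stopping (patience 20) on validation
cross-entropy; transductive mode — three convolutions (16, 16, $c$),
Adam at $10^{-2}$, 600 epochs, patience 60.  The transductive stack is
deeper because on the motif benchmarks prediction quality is not the
bottleneck — *edge reliance* is: each extra layer multiplies the number
of motif paths that reach the classified node, which measurably
improves how completely the explainer recovers motifs.

Two printed shapes are deliberately corrected: the projection is
per-node ($f \times d$, not $np \times d$) and the first convolution
weight is $3q \times g^{(0)}$ (not $1 \times g^{(0)}$); both are the
only shapes conformable with the equations they appear in.

# Pathway featurization

For every pathway and omic layer, the pathway's gene columns are
centered with fit-set means and projected on the top-$q$ axes estimated
**on the fit set only** (default: all patients; inside cross-validation,
the training patients).  This matters: axes estimated on the full cohort
leak test information into training features.  Axis signs are fixed by
making each axis's largest-magnitude loading positive, so features are
reproducible across platforms.  Pathways with fewer usable dimensions
than $q$ are zero-padded; pathways with no genes in the cohort are
dropped and the adjacency re-indexed.  Column order per pathway row is
expression PCs, copy-number PCs, methylation PCs — with $q = 2$, six
columns.

TMB labels are strict: high means more than 10 mutations per megabase;
exactly 10 is low.  The covered-megabase denominator is a parameter
(default 38, a common exome footprint).

# The synthetic cohort generator

`simulate_pathway_graph()` draws a random hierarchy tree over $p$
pathways (node $i$'s parent is uniform over $1..i{-}1$, so the first $k$
pathways always form a connected subtree) with disjoint gene blocks.
`simulate_multiomics_cohort()` draws binary TMB labels at prevalence
`high_fraction` (default 0.3, a realistic high-TMB fraction), shifts the
expression of every effect-pathway gene by `effect_size` in high-TMB
patients (half-size shifts on copy number and on the methylation latent
scale, which is squashed through a logistic link to the beta-value range
$[0,1]$), and draws mutation rates consistently with the labels.

What this emulates: a coordinated, pathway-level mean shift against
independent Gaussian noise.  What it does not emulate: gene-gene
correlation within pathways, batch structure, heavy-tailed expression,
missingness, or any coupling between omics beyond the shared labels.
Passing the recovery tests therefore demonstrates that the machinery
finds coordinated pathway-level signal; it does not certify performance
on real TCGA-like data.

# The five motif benchmarks

`make_benchmark()` builds the standard explanation-fidelity datasets:
a base graph — Barabasi-Albert with 300 nodes, or a depth-8 balanced
binary tree with $2^8{-}1 = 255$ nodes — plus 80 attached motifs
(5-node house, 9-node 3x3 grid, 6-node cycle), one uniformly chosen
anchor and one attachment edge per motif.  `BA-Community` joins two
independently generated BA-House graphs with $0.01n$ random
cross-community edges and doubles the label space.  Within-motif edges
are the ground-truth explanation; attachment and noise edges are not.
Node labels are structural roles: base class plus house positions
(bottom / middle / top); cycle and grid motifs collapse to a single
motif class.

Three generator choices deserve explanation because the underlying
publication family leaves them open:

* **BA attachment parameter `m_attach = 5`.**  With $m = 1$ the base is
  a tree and a motif node's evaluation neighborhood often contains *no*
  negative edge except the attachment edge, making the per-node AUC
  undefined or degenerate.  A dense base is the convention of this
  benchmark family and keeps the negative set populated.
* **Perturbation edges** (1% of edges for BA bases, 10% for tree
  bases).  A perfect binary tree has no degree-2 node except the root,
  so cycle membership would be readable off a node's degree alone and a
  trained classifier would never need edges — leaving nothing for an
  explainer to find.  Noise edges create degree-ambiguous nodes and
  populate neighborhoods with background edges.
* **Node features.**  Row-stochastic propagation of constant features
  is provably degenerate: every row of $SX W$ is identical, so with
  all-ones features the classifier cannot learn at all.  The default
  `"structural"` policy therefore uses degree-derived columns (degree
  transforms, small-degree indicators, neighbor-degree summaries, local
  clustering; dimension 10).  `BA-Community` appends two
  community-indexed Gaussian columns (mean $\pm 1$, sd 0.5).  The
  `"ones"` policy is retained in the configuration for completeness.

# The explainer

For an instance (a patient, or a node with its computation
neighborhood), a symmetric edge-mask logit matrix $M$ (support of the
adjacency, self-loops included; effective logit $(M_{ij} + M_{ji})/2$)
and a per-column feature-mask vector $F$ are optimized by Adam while
the model is frozen:

$$\min_{M,F}\; -\log P_\Phi(\hat y \mid \text{masked inputs})
+ \theta_{ee}\,\overline{H(\sigma(M))}
+ \theta_{fe}\,\overline{H(\sigma(F))}
+ \theta_{es}\,\overline{\sigma(M)}
+ \theta_{fs}\,\overline{\sigma(F)}$$

where $\hat y$ is the model's own prediction, $H$ is the binary entropy
and the bars are means over the support (edge terms) or feature columns.
Maximizing the mutual information between the prediction and the masked
subgraph is equivalent to minimizing this conditional-entropy surrogate
because $H(Y)$ is constant for a frozen model — a property the test
suite checks numerically.  Both regularizers act on $\sigma(\cdot)$ of
the logits; binary entropy requires arguments in $(0,1)$, so applying it
to raw logits (as one printed form suggests) is not meaningful.

Two implementation choices matter greatly in practice and are worth
making explicit:

* **How the mask enters the network** (`renormalize`).  Feeding
  $E \odot \sigma(M)$ through the affinity softmax re-normalizes every
  row around the mask, so any row-proportional attenuation is invisible
  and a redundant-but-real edge can be deleted at zero cost to the
  prediction.  The default (`renormalize = FALSE`) instead computes $S$
  from the unmasked graph and attenuates the propagation weights
  directly, $S \odot \sigma(M)$ — the convention of mask-based GNN
  explainers — so every edge's message is scaled absolutely and each
  contributing edge retains gradient signal.  The literal masked-
  adjacency composition remains available and is what the printed-form
  identities in the test suite exercise.
* **Regularizer balance.**  The entropy term is a *repeller* from 0.5:
  if it dominates, edges with weak prediction gradient polarize to 0 or
  1 according to the sign of their random initialization, which
  randomizes the ranking that the AUC measures.  The defaults
  ($\theta_{ee} = 0.3$, $\theta_{es} = 0.05$, $\theta_{fe} = 0.1$,
  $\theta_{fs} = 1$, learning rate 0.1, 100 epochs) keep the size term
  strong enough that unsupported edges drift down deterministically
  while supported edges are held up by the prediction loss.

Benchmark scoring: for each motif node, the evaluation set is the
undirected non-self-loop edges of the node's $(K{+}1)$-hop neighborhood
($K$ = convolution layers; the extra hop is the feature dependence of
the learned affinity row), truncated to the 100 nearest nodes —
hub-adjacent balls in a scale-free graph otherwise swallow half the
graph without informing the explained node.  Mask weights are scored
against within-motif flags by rank AUC (ties count one half); nodes
whose neighborhood lacks positives or negatives are reported as missing
and excluded from averages.

In cohort mode the feature mask is shared across pathway rows (one
weight per column of $K_p$), and per-patient edge masks can be averaged
over patients to obtain a cohort-level pathway-interaction map.  For
planted-signal recovery the natural ground truth is *edges incident to
an effect pathway* (self-loops included): the flattening head reads
every pathway row, so effect signal provably flows over each such edge
in both directions, whereas edges between unaffected pathways carry
noise only.

# Evaluation machinery

`make_cv_plan()` produces stratified 5-fold plans with 5 repeats (both
configurable): per split, 20% test, and the remainder split 80/20 into
training and validation.  SMOTE (`smote_oversample()`) balances classes
by interpolating a minority sample toward one of its $k$ nearest
minority neighbors ($x + u(x_{nn} - x)$, $u \sim U(0,1)$, originals
retained, synthetic rows flagged); it is applied to the *training
partition only* — balancing the whole cohort before splitting would put
interpolants of test points into training, which is leakage.  A flag-
free id check in the tests verifies synthetic rows never reach
validation or test.

Metrics are computed for the positive (high-TMB) class at a 0.5 cutoff;
AUC is the rank statistic (concordant pairs, ties half) and is checked
against an exhaustive pairwise oracle and against `pROC`.  The baseline
harness runs L2 logistic regression (`glmnet`, ridge), RBF and linear
SVMs (`e1071`), random forest (`randomForest`), AdaBoost.M1 over
decision stumps (implemented in-package), a decision tree (`rpart`) and
a constant-probability dummy on identical splits, reporting mean and
sample standard deviation over the splits plus wall time.

# Numerical choices and degenerate inputs

* Softmax rows are stabilized by subtracting the row maximum; the
  graph-learning exponent is capped at 60 during training so `exp()`
  cannot overflow (softmax ratios are unaffected for moderate spreads).
* Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ before logs.
* ReLU subgradient at exactly 0 is taken as 0 everywhere.
* Zero-variance pathway blocks produce zero features; single-gene
  pathways are zero-padded to $q$ columns.
* Mask denominators carry an additive $10^{-12}$ so a fully masked row
  cannot divide by zero.
* Per-instance mask optimization runs in compiled code
  (RcppArmadillo); `masked_forward()` / `explainer_loss()` are the R
  reference implementations and the test suite asserts agreement
  between the two paths at arbitrary masks.

# Problem sizes used by the shipped experiments

The packaged experiments run at the generator's native scales: the five
benchmarks at their published sizes (700-1400 nodes, 80 motifs, all
motif nodes explained, three seeds), and the planted-signal cohort at
400 patients x 30 pathways x 10 genes per pathway with `effect_size = 2`
on 10 effect pathways.  Unit and property tests use smaller instances
of the same generators (60-150 samples, 5-12 pathways, 12-20 motifs) so
the full suite stays fast.

# Known limitations

* With row-stochastic propagation, structural information must enter
  through node features; the classifier can therefore satisfy part of
  its objective from a node's own features, and motif edges that are
  genuinely redundant *for the trained model* cannot be ranked above
  background by any prediction-preserving mask.  On the motif
  benchmarks this caps explanation fidelity below the ideal on some
  datasets (lowest for Tree-Grids); the acceptance suite reports the
  honest numbers.
* The cohort generator's independence assumptions (see above) make the
  planted-signal task easier than real multi-omics cohorts.
* Checkpointing is plain R serialization of the parameter list; no
  cross-version guarantees are made.
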