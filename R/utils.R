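#' @useDynLib pglcn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rexp plogis predict sd var dist
#' @importFrom utils write.table read.table head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

# Row-wise softmax of a dense matrix, numerically stabilised.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Rank-based ROC AUC
#'
#' AUC computed as the normalized count of concordant (positive, negative)
#' score pairs, with tied pairs counted one half.  Equivalent to the
#' Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param scores numeric score vector (higher = more positive).
#' @param labels binary vector (0/1 or logical), positives = 1/TRUE.
#' @return AUC in `[0, 1]`, or `NA_real_` if either class is absent.
#' @keywords internal
rank_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
}

# Deterministic per-stage seed fan-out from one global seed.  Arithmetic
# in doubles (exact below 2^53); results stay below 2^31 so they remain
# valid R integers even after repeated derivation.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stage) * 9176) %%
               2147483629)
}
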