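# Weighted-adjusted p-values for intersection hypotheses.
#
# Given marginal p-values p_j and weights w_{j,J}, the local test of the
# intersection hypothesis H_J is based on min_j p_j / w_j.  How this
# statistic is converted into an adjusted p-value depends on what is
# known about the joint distribution of the z statistics:
#   nonparametric - no correlations known: weighted Bonferroni,
#   parametric    - all correlations known: exact union probability,
#   mixed         - correlations known within blocks only: block union
#                   probabilities divided by block weight sums, summed
#                   conservatively through the minimum.
# Components with zero weight are dropped on both sides of the
# inequality before any computation.

#' Weighted Bonferroni adjusted p-value
#'
#' @param p Named (or positional) vector of marginal p-values in `[0, 1]`.
#' @param weights Nonnegative weights, `sum(weights) <= 1`, matching `p`.
#' @return `min(1, min(p_j / w_j))` over the positive-weight components.
#' @examples
#' bonferroni_adjusted(c(0.0952, 0.0225, 0.1104), c(0.75, 0.25, 0))  # 0.09
#' @export
bonferroni_adjusted <- function(p, weights) {
  .check_pw(p, weights)
  pos <- weights > 0
  if (!any(pos)) stop("all weights are zero: adjusted p-value undefined")
  min(1, min(p[pos] / weights[pos]))
}

#' Weighted parametric adjusted p-value
#'
#' Exact adjusted p-value when the correlations among the z statistics of
#' all positive-weight components are known:
#' \eqn{P_{H_J}(\min_j P_j/w_j \le \min_j p_j/w_j)}, evaluated as a
#' multivariate normal union probability on the z scale.
#'
#' @inheritParams bonferroni_adjusted
#' @param corr Correlation matrix for the z statistics of all components
#'   of `p` (rows/columns in the same order), or a single number giving a
#'   common correlation.
#' @return Adjusted p-value in `[0, 1]`.
#' @examples
#' parametric_adjusted(c(0.00045, 0.0952), c(0.5, 0.5), 0.5)  # 0.00088
#' @export
parametric_adjusted <- function(p, weights, corr) {
  .check_pw(p, weights)
  pos <- which(weights > 0)
  if (!length(pos)) stop("all weights are zero: adjusted p-value undefined")
  if (length(pos) == 1L) return(min(1, p[pos] / weights[pos]))
  if (is.matrix(corr)) corr <- corr[pos, pos, drop = FALSE]
  else {
    r <- matrix(corr, length(pos), length(pos)); diag(r) <- 1; corr <- r
  }
  m <- min(p[pos] / weights[pos])
  q <- pmin(1, weights[pos] * m)
  1 - .mvn_lower_any(qnorm(1 - q), corr)
}

# P(∩ Z_j <= z_j): exploit a one-factor structure when the matrix has one
# (every off-diagonal r_ij = b_i b_j), otherwise use the generic routine.
.mvn_lower_any <- function(z, corr) {
  b <- .onefactor_loadings(corr)
  if (!is.null(b)) return(onefactor_lower(z, b))
  # P(∩ Z_j <= z_j) = P(∩ -Z_j > -z_j) by symmetry of the MVN
  mvn_upper_orthant(-z, corr)
}

.onefactor_loadings <- function(corr) {
  d <- nrow(corr)
  if (d == 1L) return(0)
  off <- corr[1, 2]
  if (d == 2L) {
    if (off < 0) return(NULL)
    return(c(sqrt(off), sqrt(off)))
  }
  if (any(corr[upper.tri(corr)] <= 0)) return(NULL)
  # b_i = sqrt(r_1i * r_1j / r_ij) for any j != 1, i
  b <- numeric(d)
  b[1] <- sqrt(corr[1, 2] * corr[1, 3] / corr[2, 3])
  if (!is.finite(b[1]) || b[1] >= 1) return(NULL)
  b[2:d] <- corr[1, 2:d] / b[1]
  if (any(b[2:d] >= 1 | b[2:d] <= 0)) return(NULL)
  fit <- tcrossprod(b); diag(fit) <- 1
  if (max(abs(fit - corr)) > 1e-10) return(NULL)
  b
}

#' Weighted mixed adjusted p-value
#'
#' When correlations are known only within blocks of a partition of the
#' index set, each block contributes its parametric union probability
#' divided by its weight sum, and the adjusted p-value is the minimum of
#' these ratios, capped at 1.  Singleton blocks reduce to `p_j / w_j`,
#' so an all-singleton partition reproduces the weighted Bonferroni
#' value, and a single block covering everything reproduces the
#' parametric value (when its weights sum to one).
#'
#' @inheritParams bonferroni_adjusted
#' @param blocks List of index vectors partitioning `seq_along(p)`.
#' @param block_corr List (parallel to `blocks`) of correlation matrices
#'   or scalar common correlations; entries for singleton blocks are
#'   ignored and may be `NULL`.
#' @return Adjusted p-value in `[0, 1]`.
#' @examples
#' mixed_adjusted(c(0.1121, 0.0112, 0.1153), c(0.5, 0.25, 0.25),
#'                blocks = list(1, 2:3), block_corr = list(NULL, 0.5))
#' @export
mixed_adjusted <- function(p, weights, blocks, block_corr = NULL) {
  .check_pw(p, weights)
  cov <- sort(unlist(blocks))
  if (!identical(as.integer(cov), seq_along(p)))
    stop("'blocks' must partition the index set of 'p'")
  terms <- Inf
  for (h in seq_along(blocks)) {
    idx <- blocks[[h]]
    pos <- idx[weights[idx] > 0]
    if (!length(pos)) next
    wsum <- sum(weights[pos])
    if (length(pos) == 1L) {
      # singleton block: union probability is P(P_j <= p_j) = p_j
      terms <- min(terms, p[pos] / wsum)
    } else {
      rc <- block_corr[[h]]
      sub <- match(pos, idx)
      if (is.matrix(rc)) rc <- rc[sub, sub, drop = FALSE]
      else {
        r <- matrix(rc %||% stop("correlation needed for block ", h),
                    length(pos), length(pos))
        diag(r) <- 1; rc <- r
      }
      m <- min(p[pos] / weights[pos])
      q <- pmin(1, weights[pos] * m)
      u <- 1 - .mvn_lower_any(qnorm(1 - q), rc)
      terms <- min(terms, u / wsum)
    }
  }
  if (!is.finite(terms)) stop("all weights are zero: adjusted p-value undefined")
  min(1, terms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_pw <- function(p, weights) {
  stopifnot(length(p) == length(weights))
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) > 1 + 1e-9) stop("weights must sum to at most 1")
  invisible(TRUE)
}

# Regime classification for a subset, given the block partition of the
# full index set: based on the positive-weight members only.
#   "single"        one positive-weight component,
#   "nonparametric" all blocks intersect it in singletons,
#   "parametric"    one block covers all of it,
#   "mixed"         otherwise.
.regime <- function(active, blocks) {
  if (length(active) <= 1L) return("single")
  sizes <- vapply(blocks, function(b) length(intersect(b, active)), 1L)
  sizes <- sizes[sizes > 0L]
  if (all(sizes == 1L)) return("nonparametric")
  if (length(sizes) == 1L) return("parametric")
  "mixed"
}
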