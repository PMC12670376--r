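# Two-stage adaptive design specification.
#
# A design bundles the graphical weighting strategy, the correlation
# knowledge structure, the error-spending plan and the inverse-normal
# combination weights.  Correlation knowledge is expressed as a partition
# of the hypotheses into blocks within which z-statistic correlations are
# known; in the multiarm setting each block collects the treatment-vs-
# control comparisons of one endpoint and the correlations follow the
# Dunnett one-factor structure corr(Z_i, Z_j) = b_i b_j with loadings
# b_i = sqrt(n_i / (n_i + n_0)).

#' Correlation-knowledge structure
#'
#' @param blocks List of hypothesis index (or label) vectors partitioning
#'   the hypotheses; correlations are known within a block and unknown
#'   across blocks.
#' @param loadings1 Per-hypothesis factor loadings of the stage-one z
#'   statistics (within each block, `corr(Z_i, Z_j) = b_i b_j`).  Under
#'   balanced allocation to a shared control this is `sqrt(0.5)` for
#'   every comparison.
#' @param loadings2 Loadings of the incremental stage-two z statistics;
#'   defaults to `loadings1`.
#' @return Object of class `"corr_structure"`.
#' @seealso [dunnett_loadings()]
#' @export
corr_structure <- function(blocks, loadings1, loadings2 = loadings1) {
  k <- length(loadings1)
  stopifnot(length(loadings2) == k)
  if (any(loadings1 < 0 | loadings1 >= 1) || any(loadings2 < 0 | loadings2 >= 1))
    stop("factor loadings must lie in [0, 1)")
  idx <- sort(unlist(blocks))
  if (!identical(as.integer(idx), seq_len(k)))
    stop("'blocks' must partition the hypothesis index set 1..k")
  structure(list(blocks = lapply(blocks, as.integer),
                 loadings1 = as.numeric(loadings1),
                 loadings2 = as.numeric(loadings2)),
            class = "corr_structure")
}

#' Specify a two-stage adaptive graph-based design
#'
#' @param graph An [mcp_graph()] over the `k` elementary hypotheses.
#' @param corr A [corr_structure()]; defaults to one block per
#'   hypothesis (no correlations known) with balanced loadings.
#' @param alpha One-sided familywise error level.
#' @param t Planned information fraction of stage one, in (0, 1).
#' @param spending Stage-one spending: `"ldof"` (Lan-DeMets
#'   O'Brien-Fleming type) or a fixed numeric level `alpha1`.
#' @param nu Inverse-normal combination weights `c(nu1, nu2)` with
#'   `nu1^2 + nu2^2 = 1`; default `c(sqrt(t), sqrt(1 - t))`.  They are
#'   fixed at the planning stage and are never updated on adaptation.
#' @return Object of class `"two_stage_design"` holding the closure
#'   weight table, the spent level `alpha1` and the stage-two combination
#'   level `alpha2` solving the two-stage level condition.
#' @examples
#' g <- mcp_graph(c(.5, .5, 0, 0),
#'                rbind(c(0, .5, .5, 0), c(.5, 0, 0, .5),
#'                      c(0, 1, 0, 0),   c(1, 0, 0, 0)))
#' d <- two_stage_design(g, corr_structure(list(1:2, 3:4),
#'                                         rep(sqrt(0.5), 4)))
#' round(c(d$alpha1, d$alpha2), 6)
#' @export
two_stage_design <- function(graph, corr = NULL, alpha = 0.025, t = 0.5,
                             spending = "ldof", nu = c(sqrt(t), sqrt(1 - t))) {
  stopifnot(inherits(graph, "mcp_graph"), alpha > 0, alpha < 1,
            t > 0, t < 1, length(nu) == 2L)
  if (abs(sum(nu^2) - 1) > 1e-8)
    stop("combination weights must satisfy nu1^2 + nu2^2 = 1")
  k <- length(graph$labels)
  if (is.null(corr))
    corr <- corr_structure(as.list(seq_len(k)), rep(sqrt(0.5), k))
  stopifnot(inherits(corr, "corr_structure"),
            length(corr$loadings1) == k)
  alpha1 <- if (identical(spending, "ldof")) spending_alpha1(t, alpha)
            else {
              stopifnot(is.numeric(spending), spending >= 0, spending < alpha)
              spending
            }
  structure(list(graph = graph, wt = closure_weights(graph), corr = corr,
                 alpha = alpha, t = t, nu = nu, alpha1 = alpha1,
                 alpha2 = solve_alpha2(alpha1, alpha, nu),
                 labels = graph$labels, k = k),
            class = "two_stage_design")
}

#' @export
print.two_stage_design <- function(x, ...) {
  cat("Two-stage adaptive graph-based design\n")
  cat(sprintf("  hypotheses: %d (%s)\n", x$k, paste(x$labels, collapse = ", ")))
  cat(sprintf("  one-sided alpha = %g, information fraction t = %g\n",
              x$alpha, x$t))
  cat(sprintf("  stage-one spent level alpha1 = %.6f\n", x$alpha1))
  cat(sprintf("  combination stage-two level alpha2 = %.6f\n", x$alpha2))
  cat(sprintf("  combination weights nu = (%.4f, %.4f)\n", x$nu[1], x$nu[2]))
  invisible(x)
}

# --- internal: per-subset adjusted p-value under a design ----------------

# Adjusted p-value for the subset given by `mask`, using the weight row
# `wrow` (full length k, NA outside the subset), marginal p-values `p`
# and per-hypothesis loadings `b` for the relevant stage.
.adjusted_for_mask <- function(design, wrow, mask, p, b) {
  members <- mask_members(mask, design$k)
  w <- wrow[members]
  active <- members[w > 0]
  if (!length(active)) return(NA_real_)
  regime <- .regime(active, design$corr$blocks)
  if (regime == "single") return(min(1, p[active] / w[match(active, members)]))
  wa <- wrow[active]
  pa <- p[active]
  if (regime == "nonparametric") return(min(1, min(pa / wa)))
  if (regime == "parametric") {
    r <- tcrossprod(b[active]); diag(r) <- 1
    return(parametric_adjusted(pa, wa, r))
  }
  # mixed: restrict the block partition to the active set
  blk <- lapply(design$corr$blocks, function(bl) intersect(bl, active))
  blk <- blk[vapply(blk, length, 1L) > 0L]
  loc <- lapply(blk, function(bl) match(bl, active))
  bc <- lapply(blk, function(bl) {
    r <- tcrossprod(b[bl]); diag(r) <- 1; r
  })
  mixed_adjusted(pa, wa, loc, bc)
}

.subset_regimes <- function(design, W = design$wt$W) {
  S <- nrow(W)
  vapply(seq_len(S), function(m) {
    members <- mask_members(m, design$k)
    active <- members[W[m, members] > 0]
    if (!length(active)) "degenerate" else .regime(active, design$corr$blocks)
  }, "")
}
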