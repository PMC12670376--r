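# The p-value combination method.
#
# Each intersection hypothesis H_J is tested by a two-stage inverse-normal
# combination test: reject at the interim if the stage-one adjusted
# p-value falls at or below the spent level alpha1, otherwise reject at
# the final analysis if the combination of the stage-one and incremental
# stage-two adjusted p-values falls at or below alpha2, where
# (alpha1, alpha2) satisfy the two-stage level condition.  Because the
# incremental stage-two p-values are computed from the post-adaptation
# design, arbitrary data-dependent selection, re-weighting and
# sample-size changes at the interim preserve the familywise error rate.

#' Lan-DeMets O'Brien-Fleming type error spending
#'
#' \eqn{g(t, \alpha) = 2 - 2\Phi(z_{\alpha/2} / \sqrt{t})}, the amount of
#' one-sided alpha spent by information fraction `t`.
#'
#' @param t Information fraction in (0, 1].
#' @param alpha Total one-sided level.
#' @return Spent level.
#' @examples
#' spending_alpha1(0.5, 0.025)  # 0.001525
#' @export
spending_alpha1 <- function(t, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  if (any(t <= 0) || any(t > 1)) stop("information fraction must be in (0, 1]")
  2 - 2 * pnorm(qnorm(1 - alpha / 2) / sqrt(t))
}

#' Stage-two level of the two-stage combination test
#'
#' Solves for `alpha2` in the level condition
#' \eqn{P(P_1 \le \alpha_1) + P(P_1 > \alpha_1,\,
#' C(P_1, P_2) \le \alpha_2) = \alpha}
#' with independent uniform stage-wise p-values and the inverse-normal
#' combination function, by bivariate normal integration.
#'
#' @param alpha1 Stage-one spent level, `0 <= alpha1 < alpha`.
#' @param alpha Total one-sided level.
#' @param nu Combination weights `c(nu1, nu2)`, `nu1^2 + nu2^2 = 1`.
#' @return The stage-two level `alpha2`.
#' @examples
#' solve_alpha2(0.001525, 0.025, sqrt(c(0.5, 0.5)))  # 0.0245
#' @export
solve_alpha2 <- function(alpha1, alpha, nu) {
  stopifnot(alpha1 >= 0, alpha1 < alpha, alpha < 1,
            abs(sum(nu^2) - 1) < 1e-8)
  if (alpha1 == 0) return(alpha)
  z1 <- qnorm(1 - alpha1)
  # Z1 and Zc = nu1 Z1 + nu2 Z2 are standard normal with corr nu1;
  # P(P1 > a1, C <= a2) = P(Zc >= z_{a2}) - P(Z1 >= z_{a1}, Zc >= z_{a2})
  f <- function(a2) {
    alpha1 + a2 - bvn_lower(-z1, -qnorm(1 - a2), nu[1])
  }
  solve_monotone(f, 1e-12, 1 - 1e-9, target = alpha, tol = 1e-12)
}

#' Inverse-normal combination of stage-wise p-values
#'
#' \eqn{C(p_1, p_2) = 1 - \Phi\{\nu_1 \Phi^{-1}(1-p_1) +
#' \nu_2 \Phi^{-1}(1-p_2)\}}.  Inputs of exactly 0 or 1 are clamped to
#' `[1e-15, 1 - 1e-15]` before the probit transformation.
#'
#' @param p1,p2 Stage-one and incremental stage-two (adjusted) p-values.
#' @param nu Combination weights `c(nu1, nu2)`.
#' @return Combined p-value.
#' @examples
#' combine_pvalues(0.0410, 0.0209, sqrt(c(0.5, 0.5)))  # 0.0038
#' @export
combine_pvalues <- function(p1, p2, nu) {
  stopifnot(abs(sum(nu^2) - 1) < 1e-8)
  1 - pnorm(nu[1] * qnorm(1 - clamp_p(p1)) + nu[2] * qnorm(1 - clamp_p(p2)))
}

#' Interim closed test for the combination method
#'
#' Computes stage-one weighted-adjusted p-values for every intersection
#' hypothesis, rejects those at or below the spent level `alpha1`, and
#' derives the early-rejected elementary hypotheses (those contained
#' only in rejected intersections) and the open sets for stage two.
#'
#' @param design A [two_stage_design()].
#' @param p1 Named vector of stage-one marginal p-values (names matching
#'   the design labels, or positional).
#' @return Object of class `"combo_interim"` with components
#'   `table` (per-intersection data frame), `rejected1` (logical by
#'   subset mask), `I1r`, `I1star` (elementary index vectors) and `p1`.
#' @export
combo_interim <- function(design, p1) {
  stopifnot(inherits(design, "two_stage_design"))
  p1 <- .match_p(design, p1)
  W <- design$wt$W
  S <- nrow(W)
  pJ1 <- vapply(seq_len(S), function(m)
    .adjusted_for_mask(design, W[m, ], m, p1, design$corr$loadings1), 0)
  rejected1 <- pJ1 <= design$alpha1
  elem <- .closed_elementary(rejected1, design$k)
  structure(list(design = design, p1 = p1, pJ1 = pJ1,
                 rejected1 = rejected1,
                 I1r = which(elem), I1star = which(!elem),
                 table = .subset_table(design, pJ1 = pJ1,
                                       rejected1 = rejected1)),
            class = "combo_interim")
}

#' @export
print.combo_interim <- function(x, ...) {
  cat("Interim closed test (combination method)\n")
  cat(sprintf("  spent level alpha1 = %.6f\n", x$design$alpha1))
  cat(sprintf("  intersections rejected at stage one: %d of %d\n",
              sum(x$rejected1), length(x$rejected1)))
  cat("  early-rejected elementary hypotheses:",
      if (length(x$I1r)) paste(x$design$labels[x$I1r], collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Adaptation plan for stage two
#'
#' Describes the design modifications decided at the unblinded interim
#' analysis: the subset of hypotheses carried into stage two, an optional
#' revised weighting graph over those hypotheses, per-hypothesis adapted
#' information fractions (after sample-size reassessment) and adapted
#' incremental stage-two loadings.
#'
#' @param design The [two_stage_design()] being adapted.
#' @param select Labels or indices of the hypotheses selected for stage
#'   two (must be contained in the continuing set at the interim).
#' @param graph Optional [mcp_graph()] over exactly the selected
#'   hypotheses giving the adapted weighting strategy; `NULL` keeps the
#'   preplanned closure weights.
#' @param t_adapted Per-hypothesis adapted information fractions
#'   (named or full-length); default: the planned `t` for every
#'   hypothesis.
#' @param loadings2 Adapted incremental stage-two loadings (full length
#'   k); default: the preplanned stage-two loadings.
#' @return Object of class `"adaptation_plan"`.
#' @export
adaptation_plan <- function(design, select, graph = NULL, t_adapted = NULL,
                            loadings2 = NULL) {
  stopifnot(inherits(design, "two_stage_design"))
  sel <- if (is.character(select)) match(select, design$labels)
         else as.integer(select)
  if (anyNA(sel) || any(sel < 1) || any(sel > design$k))
    stop("unknown hypothesis in 'select'")
  sel <- sort(unique(sel))
  tt <- rep(design$t, design$k)
  if (!is.null(t_adapted)) {
    if (!is.null(names(t_adapted))) {
      idx <- match(names(t_adapted), design$labels)
      if (anyNA(idx)) stop("unknown label in 't_adapted'")
      tt[idx] <- t_adapted
    } else {
      stopifnot(length(t_adapted) %in% c(1L, design$k))
      tt <- rep_len(t_adapted, design$k)
    }
  }
  if (any(tt <= 0 | tt >= 1)) stop("information fractions must be in (0, 1)")
  b2 <- if (is.null(loadings2)) design$corr$loadings2 else as.numeric(loadings2)
  stopifnot(length(b2) == design$k)
  Wt <- NULL
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "mcp_graph"))
    if (!setequal(graph$labels, design$labels[sel]))
      stop("'graph' must be defined on exactly the selected hypotheses")
    Wt <- closure_weights(graph)
  }
  structure(list(select = sel, graph = graph, wt2 = Wt,
                 t_adapted = tt, loadings2 = b2),
            class = "adaptation_plan")
}

# Adapted weight row (full length k, NA outside) for a subset mask that
# is contained in the selected set.
.plan_weight_row <- function(design, plan, mask) {
  if (is.null(plan$wt2)) return(design$wt$W[mask, ])
  members <- mask_members(mask, design$k)
  lab <- design$labels[members]
  sub <- plan$graph$labels
  m2 <- subset_mask(match(lab, sub), length(sub))
  row <- rep(NA_real_, design$k)
  row[members] <- plan$wt2$W[m2, match(lab, sub)]
  row
}

#' Partition of the open intersection hypotheses
#'
#' Splits the intersections left open at the interim into the sets for
#' which full (`A`), no (`B`) or partial (`C`) stage-two data will be
#' available, given the selection in the adaptation plan.
#'
#' @param interim A `"combo_interim"` or `"cer_interim"` object.
#' @param plan An [adaptation_plan()] (or a vector of selected indices).
#' @return List with subset-mask vectors `A`, `B`, `C`.
#' @export
partition_open <- function(interim, plan) {
  sel <- if (inherits(plan, "adaptation_plan")) plan$select else
    sort(unique(as.integer(plan)))
  if (!all(sel %in% interim$I1star))
    stop("selected hypotheses must be contained in the continuing set")
  k <- interim$design$k
  open <- which(!interim$rejected1)
  i2mask <- subset_mask(sel, k)
  e <- bitwAnd(open, i2mask)
  list(A = open[e == open], B = open[e == 0L], C = open[e != open & e != 0L])
}

#' Final closed test for the combination method
#'
#' Computes incremental stage-two adjusted p-values for the open
#' intersection hypotheses (adapted weights on subsets of the selected
#' set; 1 where no stage-two data exist; inherited from the selected
#' part otherwise), combines them with the stage-one adjusted p-values
#' through the inverse-normal function, and performs the closed test.
#'
#' @param interim A `"combo_interim"`.
#' @param plan An [adaptation_plan()].
#' @param p2 Named vector of incremental stage-two marginal p-values
#'   covering the selected hypotheses.
#' @return Object of class `"combo_decision"` with the per-intersection
#'   table and the elementary decisions `phi` (logical, named).
#' @export
combo_final <- function(interim, plan, p2) {
  stopifnot(inherits(interim, "combo_interim"),
            inherits(plan, "adaptation_plan"))
  design <- interim$design
  k <- design$k
  p2full <- .match_p(design, p2, subset = plan$select)
  part <- partition_open(interim, plan)
  S <- length(interim$rejected1)
  pJ2 <- rep(NA_real_, S)
  i2mask <- subset_mask(plan$select, k)
  # adjusted p-values exist for every subset of the selected set (some may
  # already be rejected; the open C-subsets still inherit from them)
  if (i2mask > 0L) {
    inA <- which(bitwAnd(seq_len(S), i2mask) == seq_len(S))
    for (m in inA) {
      pJ2[m] <- .adjusted_for_mask(design, .plan_weight_row(design, plan, m),
                                   m, p2full, plan$loadings2)
    }
    for (m in part$C) pJ2[m] <- pJ2[bitwAnd(m, i2mask)]
  }
  pJ2[part$B] <- 1
  open <- which(!interim$rejected1)
  comb <- rep(NA_real_, S)
  comb[open] <- combine_pvalues(interim$pJ1[open], pJ2[open], design$nu)
  rejected <- interim$rejected1
  rejected[open] <- comb[open] <= design$alpha2
  phi <- .closed_elementary(rejected, k)
  structure(list(design = design, interim = interim, plan = plan,
                 pJ2 = pJ2, combined = comb, rejected = rejected,
                 phi = stats::setNames(phi, design$labels),
                 table = .subset_table(design, pJ1 = interim$pJ1, pJ2 = pJ2,
                                       combined = comb,
                                       rejected1 = interim$rejected1,
                                       rejected = rejected)),
            class = "combo_decision")
}

#' @export
print.combo_decision <- function(x, ...) {
  cat("Final closed test (combination method)\n")
  rej <- names(x$phi)[x$phi]
  cat("  rejected elementary hypotheses:",
      if (length(rej)) paste(rej, collapse = ", ") else "none", "\n")
  invisible(x)
}

# --- shared helpers ------------------------------------------------------

.match_p <- function(design, p, subset = seq_len(design$k)) {
  out <- rep(NA_real_, design$k)
  if (!is.null(names(p))) {
    idx <- match(names(p), design$labels)
    if (anyNA(idx)) stop("unknown hypothesis label in p-values: ",
                         names(p)[is.na(idx)][1])
    out[idx] <- p
  } else {
    if (length(p) == length(subset)) out[subset] <- p
    else if (length(p) == design$k) out <- as.numeric(p)
    else stop("p-value vector has wrong length")
  }
  miss <- setdiff(subset, which(!is.na(out)))
  if (length(miss))
    stop("missing p-values for: ",
         paste(design$labels[miss], collapse = ", "))
  if (any(out[!is.na(out)] < 0 | out[!is.na(out)] > 1))
    stop("p-values must lie in [0, 1]")
  out
}

# elementary closed-test decisions: H_i rejected iff every subset
# containing i is rejected
.closed_elementary <- function(rejected_by_mask, k) {
  vapply(seq_len(k), function(i) {
    bit <- bitwShiftL(1L, i - 1L)
    masks <- which(bitwAnd(seq_along(rejected_by_mask), bit) != 0L)
    all(rejected_by_mask[masks])
  }, TRUE)
}

.subset_table <- function(design, pJ1 = NULL, pJ2 = NULL, combined = NULL,
                          rejected1 = NULL, rejected = NULL) {
  k <- design$k
  S <- nrow(design$wt$W)
  ord <- order(-vapply(seq_len(S), function(m) length(mask_members(m, k)), 1L))
  df <- data.frame(
    subset = vapply(seq_len(S), function(m)
      paste(design$labels[mask_members(m, k)], collapse = ","), ""),
    weights = vapply(seq_len(S), function(m)
      paste(format(round(design$wt$W[m, mask_members(m, k)], 4),
                   trim = TRUE), collapse = ", "), ""),
    regime = .subset_regimes(design),
    stringsAsFactors = FALSE)
  if (!is.null(pJ1)) df$pJ1 <- pJ1
  if (!is.null(pJ2)) df$pJ2 <- pJ2
  if (!is.null(combined)) df$combined <- combined
  if (!is.null(rejected1)) df$rejected_stage1 <- rejected1
  if (!is.null(rejected)) df$rejected <- rejected
  df[ord, , drop = FALSE]
}
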