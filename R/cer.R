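# The conditional error rate (CER / PCER) method.
#
# For every intersection hypothesis a two-stage group-sequential test is
# prespecified through critical constants (c_{J,1}, c_{J,2}): component j
# crosses at stage one if p_{j,1} <= w_{j,J} c_{J,1} and at stage two if
# its cumulative p-value satisfies p_{j,2} <= w_{j,J} c_{J,2}.  Given the
# stage-one data, the conditional probability B_J that the preplanned
# test would reject at stage two is computed (a sum of per-component or
# per-block conditional probabilities when correlations are unknown -
# the PCER - and an exact conditional union probability when they are
# known - the CER).  Any adaptation of stage two preserves the level as
# long as the adapted test's conditional rejection probability does not
# exceed B_J; the adapted critical constant is found by solving the
# corresponding equality.

#' Cumulative two-stage p-value
#'
#' Inverse-normal merge of a stage-one p-value with the incremental
#' stage-two p-value at information fraction `t`:
#' \eqn{1 - \Phi\{\sqrt{t}\,\Phi^{-1}(1-p_1) +
#' \sqrt{1-t}\,\Phi^{-1}(1-p_{(2)})\}}.
#'
#' @param p1 Stage-one marginal p-value.
#' @param p2 Incremental stage-two marginal p-value.
#' @param t Information fraction of stage one (possibly adapted).
#' @return Cumulative p-value.
#' @examples
#' cumulative_pvalue(0.0952, 0.0299, 0.4)  # 0.0111
#' @export
cumulative_pvalue <- function(p1, p2, t) {
  stopifnot(all(t > 0), all(t < 1))
  1 - pnorm(sqrt(t) * qnorm(1 - clamp_p(p1)) +
              sqrt(1 - t) * qnorm(1 - clamp_p(p2)))
}

#' Preplanned group-sequential boundaries for every intersection
#'
#' Solves the stage-one and two-look group-sequential equations for the
#' critical constants of every intersection hypothesis.  Within blocks
#' of known correlation the equations use exact multivariate normal
#' probabilities for the (stage-one, cumulative) z statistics (stage
#' correlation `sqrt(t)` within a hypothesis, shared-control one-factor
#' correlation across hypotheses); across blocks probabilities are
#' summed.  Components with zero weight are dropped.
#'
#' @param design A [two_stage_design()].
#' @return Object of class `"cer_boundaries"` with per-subset constants
#'   `c1`, `c2`, the regimes, and a boundary `table`.
#' @export
cer_boundaries <- function(design) {
  stopifnot(inherits(design, "two_stage_design"))
  W <- design$wt$W
  S <- nrow(W)
  c1 <- c2 <- rep(NA_real_, S)
  for (m in seq_len(S)) {
    bl <- .mask_blocks(design, m)
    c1[m] <- .solve_c1(bl, design$alpha1)
    c2[m] <- .solve_c2(bl, c1[m], design$alpha, design$t)
  }
  tab <- .subset_table(design)
  tab$c1 <- c1[as.integer(rownames(tab))]
  tab$c2 <- c2[as.integer(rownames(tab))]
  structure(list(design = design, c1 = c1, c2 = c2,
                 regime = .subset_regimes(design), table = tab),
            class = "cer_boundaries")
}

#' @export
print.cer_boundaries <- function(x, ...) {
  cat("Preplanned two-stage boundaries (CER method)\n")
  print(utils::head(x$table, 15L), digits = 5)
  invisible(x)
}

# Decompose a subset into its positive-weight block pieces.  Returns a
# list of pieces: indices `j`, weights `w`, stage-one loadings `b1`,
# incremental loadings `b2`.
.mask_blocks <- function(design, mask, wrow = design$wt$W[mask, ]) {
  members <- mask_members(mask, design$k)
  active <- members[wrow[members] > 0]
  if (!length(active)) return(list())
  pieces <- lapply(design$corr$blocks, function(bl) {
    j <- intersect(bl, active)
    if (!length(j)) return(NULL)
    list(j = j, w = wrow[j],
         b1 = design$corr$loadings1[j], b2 = design$corr$loadings2[j])
  })
  pieces[!vapply(pieces, is.null, TRUE)]
}

.solve_c1 <- function(pieces, alpha1) {
  if (!length(pieces)) return(NA_real_)
  f <- function(c) sum(vapply(pieces, function(p)
    onefactor_union(pmin(1, p$w * c), p$b1), 0))
  # all-singleton case is linear: sum w_j c = alpha1
  if (all(vapply(pieces, function(p) length(p$j), 1L) == 1L)) {
    wsum <- sum(vapply(pieces, function(p) p$w, 0))
    return(min(1, alpha1 / wsum))
  }
  solve_monotone(f, 1e-12, 1, target = alpha1, tol = 1e-12)
}

.solve_c2 <- function(pieces, c1, alpha, t) {
  if (!length(pieces)) return(NA_real_)
  f <- function(c2) {
    tot <- 0
    for (p in pieces) {
      u <- qnorm(1 - pmin(1, p$w * c1))
      v <- qnorm(1 - pmin(1, p$w * c2))
      tot <- tot + 1 - twolook_lower(u, v, p$b1, p$b2, t)
    }
    tot
  }
  solve_monotone(f, 1e-12, 1, target = alpha, tol = 1e-12)
}

#' Interim analysis for the CER method
#'
#' Applies the preplanned stage-one boundaries, identifies the
#' early-rejected intersections and elementary hypotheses, and computes
#' the conditional error rate `B_J` for every open intersection (an
#' exact conditional union probability within blocks of known
#' correlation, summed across blocks).
#'
#' @param boundaries A [cer_boundaries()] object.
#' @param p1 Named vector of stage-one marginal p-values.
#' @return Object of class `"cer_interim"` with `rejected1`, `B`, `I1r`,
#'   `I1star`, and a reporting `table`.
#' @export
cer_interim <- function(boundaries, p1) {
  stopifnot(inherits(boundaries, "cer_boundaries"))
  design <- boundaries$design
  p1 <- .match_p(design, p1)
  W <- design$wt$W
  S <- nrow(W)
  rejected1 <- vapply(seq_len(S), function(m) {
    members <- mask_members(m, design$k)
    w <- W[m, members]
    any(p1[members][w > 0] <= w[w > 0] * boundaries$c1[m])
  }, TRUE)
  B <- rep(NA_real_, S)
  for (m in which(!rejected1)) {
    pieces <- .mask_blocks(design, m)
    B[m] <- sum(vapply(pieces, function(p)
      cond_union(pmin(1, p$w * boundaries$c2[m]), p1[p$j], design$t, p$b2),
      0))
  }
  elem <- .closed_elementary(rejected1, design$k)
  tab <- boundaries$table
  tab$B <- B[as.integer(rownames(tab))]
  tab$rejected_stage1 <- rejected1[as.integer(rownames(tab))]
  structure(list(boundaries = boundaries, design = design, p1 = p1,
                 rejected1 = rejected1, B = B,
                 I1r = which(elem), I1star = which(!elem), table = tab),
            class = "cer_interim")
}

#' @export
print.cer_interim <- function(x, ...) {
  cat("Interim analysis (CER method)\n")
  cat("  early-rejected elementary hypotheses:",
      if (length(x$I1r)) paste(x$design$labels[x$I1r], collapse = ", ")
      else "none", "\n")
  print(utils::head(x$table[!x$table$rejected_stage1,
                            c("subset", "weights", "regime", "B")], 10L),
        digits = 4)
  invisible(x)
}

#' Adapted stage-two boundaries
#'
#' For every open intersection hypothesis, solves the CER/PCER equality
#' for the adapted stage-two critical constant using the adapted
#' weights, information fractions and incremental correlation structure.
#' Intersections without any selected component cannot be rejected at
#' stage two; intersections with only part of their components selected
#' are tested through their selected part (weights renormalised over the
#' selected components) while retaining their own conditional error
#' `B_J`.  Nonparametric or mixed intersections with `B_J >= 1` are
#' rejected outright.
#'
#' @param interim A [cer_interim()] object.
#' @param plan An [adaptation_plan()].
#' @return Object of class `"cer_adapted"` with per-subset adapted
#'   constants `ctilde`, auto-rejection flags, effective index sets and
#'   a `table`.
#' @export
cer_adapt <- function(interim, plan) {
  stopifnot(inherits(interim, "cer_interim"),
            inherits(plan, "adaptation_plan"))
  design <- interim$design
  k <- design$k
  part <- partition_open(interim, plan)
  S <- length(interim$rejected1)
  i2mask <- subset_mask(plan$select, k)
  ctilde <- rep(NA_real_, S)
  auto <- rep(FALSE, S)
  eff <- vector("list", S)
  for (m in c(part$A, part$C)) {
    e <- bitwAnd(m, i2mask)
    wrow <- .plan_weight_row(design, plan, e)
    pieces <- .mask_blocks(design, e, wrow)
    for (i in seq_along(pieces)) {
      pieces[[i]]$b2 <- plan$loadings2[pieces[[i]]$j]
      pieces[[i]]$tt <- plan$t_adapted[pieces[[i]]$j]
    }
    eff[[m]] <- pieces
    BJ <- interim$B[m]
    n_pieces <- length(pieces)
    if (BJ >= 1) {
      # possible only when B_J is a sum (PCER); the condition then holds
      # for any adapted test and H_J is rejected outright
      auto[m] <- TRUE
      next
    }
    if (!n_pieces) next
    f <- function(cc) sum(vapply(pieces, function(p)
      cond_union(pmin(1, p$w * cc), interim$p1[p$j], p$tt, p$b2), 0))
    ctilde[m] <- solve_monotone(f, 1e-12, 1, target = BJ, tol = 1e-12)
  }
  tab <- interim$table
  idx <- as.integer(rownames(tab))
  tab$ctilde <- ctilde[idx]
  tab$auto_reject <- auto[idx]
  structure(list(interim = interim, design = design, plan = plan,
                 part = part, ctilde = ctilde, auto = auto, eff = eff,
                 table = tab),
            class = "cer_adapted")
}

#' @export
print.cer_adapted <- function(x, ...) {
  cat("Adapted stage-two boundaries (CER method)\n")
  open <- x$table[!x$table$rejected_stage1, c("subset", "B", "ctilde",
                                              "auto_reject")]
  print(open, digits = 4)
  invisible(x)
}

#' Final closed test for the CER method
#'
#' Computes cumulative two-stage p-values for the selected hypotheses at
#' their adapted information fractions and applies the adapted
#' boundaries: an open intersection is rejected if any selected
#' component's cumulative p-value falls at or below its adapted
#' per-component boundary (or if it was auto-rejected through
#' `B_J >= 1`).  Elementary decisions follow by closed testing.
#'
#' @param adapted A [cer_adapt()] object.
#' @param p2 Named vector of incremental stage-two marginal p-values for
#'   the selected hypotheses.
#' @return Object of class `"cer_decision"` with elementary decisions
#'   `phi` and the cumulative p-values.
#' @export
cer_final <- function(adapted, p2) {
  stopifnot(inherits(adapted, "cer_adapted"))
  design <- adapted$design
  interim <- adapted$interim
  plan <- adapted$plan
  p2full <- .match_p(design, p2, subset = plan$select)
  pcum <- rep(NA_real_, design$k)
  pcum[plan$select] <- cumulative_pvalue(interim$p1[plan$select],
                                         p2full[plan$select],
                                         plan$t_adapted[plan$select])
  rejected <- interim$rejected1
  for (m in c(adapted$part$A, adapted$part$C)) {
    if (adapted$auto[m]) { rejected[m] <- TRUE; next }
    pieces <- adapted$eff[[m]]
    hit <- FALSE
    for (p in pieces) {
      bound <- pmin(1, p$w * adapted$ctilde[m])
      if (any(pcum[p$j] <= bound)) { hit <- TRUE; break }
    }
    rejected[m] <- hit
  }
  # part$B intersections stay unrejected
  phi <- .closed_elementary(rejected, design$k)
  structure(list(design = design, adapted = adapted,
                 p_cumulative = stats::setNames(pcum, design$labels),
                 rejected = rejected,
                 phi = stats::setNames(phi, design$labels)),
            class = "cer_decision")
}

#' @export
print.cer_decision <- function(x, ...) {
  cat("Final closed test (CER method)\n")
  rej <- names(x$phi)[x$phi]
  cat("  rejected elementary hypotheses:",
      if (length(rej)) paste(rej, collapse = ", ") else "none", "\n")
  invisible(x)
}
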