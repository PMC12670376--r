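# Monte-Carlo trial simulator.
#
# Emulates a two-stage trial with several treatment arms compared with a
# shared control on two normally distributed endpoints (one primary and
# one secondary hypothesis per arm).  Subject-level data are generated
# per stage, marginal p-values come from one-sided pooled-variance
# t-tests, ineffective arms are dropped at the interim by a threshold
# rule on the stage-one primary p-values, and the planned stage-two
# subjects of dropped arms are reassigned to the continuing arms.
# Operating characteristics (disjunctive power, conjunctive power,
# familywise error rate) are estimated for the combination method
# (plain replication) and for the CER method (two-phase scheme: m1
# stage-one draws, each followed by m2 stage-two draws, aggregated).

#' Graphical strategy for a multiarm two-endpoint trial
#'
#' Builds the weighting graph for `n_arms` treatment-versus-control
#' comparisons with one primary and one secondary hypothesis per arm:
#' the initial weight is split equally among the primary hypotheses; on
#' rejection of a primary hypothesis a fraction `to_secondary` of its
#' weight moves to the same arm's secondary hypothesis and the rest is
#' shared equally among the other primaries; a rejected secondary
#' returns its weight equally to the other arms' primaries.
#'
#' @param n_arms Number of treatment arms.
#' @param to_secondary Fraction of a rejected primary's weight handed to
#'   its own secondary hypothesis.
#' @return An [mcp_graph()] with hypotheses `P1..Pk, S1..Sk`.
#' @export
multiarm_graph <- function(n_arms = 4L, to_secondary = 3 / 4) {
  k <- 2L * n_arms
  w <- c(rep(1 / n_arms, n_arms), rep(0, n_arms))
  G <- matrix(0, k, k)
  for (i in seq_len(n_arms)) {
    others <- setdiff(seq_len(n_arms), i)
    G[i, n_arms + i] <- to_secondary
    G[i, others] <- (1 - to_secondary) / (n_arms - 1L)
    G[n_arms + i, others] <- 1 / (n_arms - 1L)
  }
  mcp_graph(w, G, labels = c(paste0("P", seq_len(n_arms)),
                             paste0("S", seq_len(n_arms))))
}

#' Simulation scenario for a multiarm two-endpoint trial
#'
#' @param delta Treatment effects of the primary endpoint, one per arm;
#'   the secondary endpoint of each arm has the same effect.
#' @param sigma Common standard deviation of both endpoints in all arms.
#' @param rho Within-subject correlation between the two endpoints.
#' @param n_arm Planned total subjects per arm over both stages.
#' @param t Planned information fraction of the interim analysis.
#' @param alpha One-sided familywise error level.
#' @param rule Arm-dropping rule applied to the stage-one primary
#'   p-values: `"conservative"` (drop if p >= 0.75), `"normal"`
#'   (p >= 0.5), `"aggressive"` (p >= 0.25) or `"ultra"` (keep only the
#'   arm with the smallest p).
#' @return Object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(delta = c(0.4, 0, 0, 0), sigma = 1, rho = 0.5,
                          n_arm = 100L, t = 0.5, alpha = 0.025,
                          rule = c("conservative", "normal", "aggressive",
                                   "ultra")) {
  rule <- match.arg(rule)
  stopifnot(sigma > 0, abs(rho) < 1, n_arm >= 4L, t > 0, t < 1)
  n_arms <- length(delta)
  structure(list(delta = as.numeric(delta), sigma = sigma, rho = rho,
                 n_arm = as.integer(n_arm), t = t, alpha = alpha,
                 rule = rule, n_arms = n_arms),
            class = "scenario_spec")
}

#' Arm-dropping decision rules
#'
#' @param p_primary Stage-one marginal p-values of the primary
#'   hypotheses, one per arm.
#' @param rule Rule name, see [scenario_spec()].
#' @return Integer indices of the continuing arms (ultra-aggressive ties
#'   broken by the lowest arm index).
#' @export
apply_dropping_rule <- function(p_primary,
                                rule = c("conservative", "normal",
                                         "aggressive", "ultra")) {
  rule <- match.arg(rule)
  thr <- c(conservative = 0.75, normal = 0.5, aggressive = 0.25)
  if (rule == "ultra") return(which.min(p_primary))
  which(p_primary < thr[[rule]])
}

#' Generate one stage of subject-level data
#'
#' Draws bivariate normal (primary, secondary) outcomes for the control
#' arm and each active treatment arm and returns one-sided
#' pooled-variance t-test p-values per comparison and endpoint.
#'
#' @param scenario A [scenario_spec()].
#' @param n_control Control-arm subjects in this stage.
#' @param n_treat Named or positional vector of subjects for the active
#'   treatment arms in this stage.
#' @param arms Indices of the active treatment arms (parallel to
#'   `n_treat`).
#' @return Matrix with rows `primary`, `secondary` and one column per
#'   active arm, containing the p-values.
#' @export
generate_stage_data <- function(scenario, n_control, n_treat,
                                arms = seq_along(n_treat)) {
  stopifnot(inherits(scenario, "scenario_spec"),
            n_control >= 2L, all(n_treat >= 2L),
            length(arms) == length(n_treat))
  rho <- scenario$rho; sg <- scenario$sigma
  draw <- function(n, d1, d2) {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    cbind(d1 + sg * z1, d2 + sg * z2)
  }
  ctl <- draw(n_control, 0, 0)
  out <- matrix(NA_real_, 2L, length(arms),
                dimnames = list(c("primary", "secondary"), NULL))
  for (a in seq_along(arms)) {
    trt <- draw(n_treat[a], scenario$delta[arms[a]], scenario$delta[arms[a]])
    for (e in 1:2) {
      out[e, a] <- .pooled_t_p(trt[, e], ctl[, e])
    }
  }
  out
}

# one-sided pooled-variance two-sample t-test p-value (H1: mean1 > mean2)
.pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1L) * stats::var(x) + (ny - 1L) * stats::var(y)) / df
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  stats::pt(tstat, df, lower.tail = FALSE)
}

#' Disjunctive power of the single-stage Dunnett test
#'
#' Power to reject at least one comparison in a one-look, one-sided
#' many-to-one (Dunnett) test with a shared control, computed by
#' multivariate normal integration on the z scale.
#'
#' @param n_per_arm Subjects per arm (all arms, including control).
#' @param delta True mean improvement in every treatment arm.
#' @param sigma Common standard deviation.
#' @param alpha One-sided level.
#' @param n_treat Number of treatment arms.
#' @return Disjunctive power.
#' @examples
#' dunnett_power(70, 10, 20)  # about 0.89
#' @export
dunnett_power <- function(n_per_arm, delta, sigma, alpha = 0.025,
                          n_treat = 2L) {
  stopifnot(n_per_arm > 0, sigma > 0, n_treat >= 1L)
  b <- rep(sqrt(0.5), n_treat)
  crit <- solve_monotone(function(cc)
    1 - onefactor_lower(rep(cc, n_treat), b), 0, 10, target = alpha,
    tol = 1e-12)
  ncp <- delta / (sigma * sqrt(2 / n_per_arm))
  1 - onefactor_lower(rep(crit - ncp, n_treat), b)
}

#' Simulate operating characteristics
#'
#' Runs the full two-stage adaptive procedure (interim closed test,
#' arm dropping with subject reallocation, stage-two testing) on
#' simulated trials and estimates the disjunctive power, conjunctive
#' power and familywise error rate.
#'
#' @param scenario A [scenario_spec()].
#' @param method `"combo"` or `"cer"`.
#' @param reps Number of simulated trials (combination method).
#' @param m1,m2 Stage-one draws and per-draw stage-two draws for the
#'   CER two-phase scheme.
#' @param seed Integer seed.
#' @return Object of class `"operating_characteristics"`: estimates,
#'   Monte-Carlo standard errors and replicate counts.
#' @export
simulate_oc <- function(scenario, method = c("combo", "cer"),
                        reps = 10000L, m1 = 1000L, m2 = 20L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(scenario, "scenario_spec"))
  set.seed(as.integer(seed))
  ctx <- .sim_context(scenario)
  if (method == "combo") .sim_combo(scenario, ctx, as.integer(reps))
  else .sim_cer(scenario, ctx, as.integer(m1), as.integer(m2))
}

# Preplanned boundary tables depend only on the design, not on the data;
# cache them so repeated simulator runs do not re-solve 2^k - 1 pairs of
# group-sequential equations.
.cer_boundaries_cached <- function(design) {
  v <- c(design$wt$W[!is.na(design$wt$W)],
         design$corr$loadings1, design$corr$loadings2,
         design$alpha, design$alpha1, design$t,
         unlist(lapply(design$corr$blocks, function(b) c(-1, b))))
  key <- sprintf("cerbnd_%d_%.15g_%.15g_%.15g", length(v), sum(v),
                 sum(v * seq_along(v)), sum(v^2))
  hit <- .ada_env[[key]]
  if (!is.null(hit)) return(hit)
  val <- cer_boundaries(design)
  .ada_env[[key]] <- val
  val
}

# Precomputed design quantities shared by all replicates.
.sim_context <- function(scenario) {
  n_arms <- scenario$n_arms
  k <- 2L * n_arms
  graph <- multiarm_graph(n_arms)
  blk <- rep(1:2, each = n_arms)           # block 1: primaries, 2: secondaries
  n1 <- as.integer(round(scenario$n_arm * scenario$t))
  b1 <- rep(sqrt(n1 / (2 * n1)), k)        # balanced stage one
  corr <- corr_structure(split(seq_len(k), blk), b1, b1)
  design <- two_stage_design(graph, corr, alpha = scenario$alpha,
                             t = scenario$t)
  eng <- eng_build(design$wt$W, blk)
  contain <- eng_containment(k)
  truenull <- c(scenario$delta, scenario$delta) == 0
  list(design = design, eng = eng, contain = contain, k = k,
       n_arms = n_arms, n1 = n1, truenull = truenull,
       falsenull = !c(scenario$delta, scenario$delta) == 0)
}

# Stage-two allocation after dropping: the planned subjects of dropped
# arms are split equally over the continuing arms (control included),
# remainder to control.
.sim_stage2_alloc <- function(scenario, ctx, keep) {
  n2 <- scenario$n_arm - ctx$n1
  d <- ctx$n_arms - length(keep)
  if (!length(keep)) return(NULL)
  extra <- d * n2
  share <- extra %/% (length(keep) + 1L)
  n_t <- rep(n2 + share, length(keep))
  n_c <- n2 + extra - length(keep) * share
  list(n_treat = n_t, n_control = n_c,
       lambda = n_t / (n_t + n_c),
       tfrac = vapply(n_t, function(nt)
         information_fraction(ctx$n1, ctx$n1, nt, n_c), 0))
}

.sim_one_stage1 <- function(scenario, ctx) {
  p <- generate_stage_data(scenario, ctx$n1, rep(ctx$n1, ctx$n_arms))
  c(p["primary", ], p["secondary", ])
}

.oc_wrap <- function(disj, conj, fwer, n, any_false, any_true, conj_defined) {
  est <- c(disjunctive = if (any_false) mean(disj) else NA,
           conjunctive = if (any_false && conj_defined) mean(conj) else NA,
           fwer = if (any_true) mean(fwer) else NA)
  se <- sqrt(pmax(est * (1 - est), 0) / n)
  structure(list(estimates = est, se = se, n = n), class =
              "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat("Operating characteristics (", x$n, " replicates)\n", sep = "")
  out <- rbind(estimate = 100 * x$estimates, `MC SE` = 100 * x$se)
  colnames(out) <- paste0(names(x$estimates), " (%)")
  print(round(out, 3))
  invisible(x)
}

.sim_combo <- function(scenario, ctx, reps) {
  design <- ctx$design; eng <- ctx$eng
  k <- ctx$k; n_arms <- ctx$n_arms
  S <- bitwShiftL(1L, k) - 1L
  bits <- bitwShiftL(1L, 0:(k - 1L))
  alpha1 <- design$alpha1; alpha2 <- design$alpha2; nu <- design$nu
  b1 <- design$corr$loadings1
  disj <- conj <- fwer <- logical(reps)
  for (r in seq_len(reps)) {
    p1 <- .sim_one_stage1(scenario, ctx)
    pJ1 <- eng_adjusted(eng, p1, b1)
    rej1 <- pJ1 <= alpha1
    elem1 <- eng_elementary(rej1, ctx$contain)
    keep <- apply_dropping_rule(p1[1:n_arms], scenario$rule)
    sel <- c(keep, n_arms + keep)
    sel <- sel[!elem1[sel]]
    rejected <- rej1
    if (length(sel) && length(keep)) {
      al <- .sim_stage2_alloc(scenario, ctx, keep)
      p2m <- generate_stage_data(scenario, al$n_control, al$n_treat,
                                 arms = keep)
      p2 <- rep(1 - .P_EPS, k)
      p2[keep] <- p2m["primary", ]
      p2[n_arms + keep] <- p2m["secondary", ]
      b2 <- rep(0, k)
      b2[c(keep, n_arms + keep)] <- sqrt(rep(al$lambda, 2))
      pJ2all <- eng_adjusted(eng, p2, b2)
      i2mask <- sum(bits[sel])
      open <- which(!rej1)
      e <- bitwAnd(open, i2mask)
      pJ2 <- rep(1, length(open))           # J_B: no stage-two data
      hasdata <- e != 0L
      pJ2[hasdata] <- pJ2all[e[hasdata]]
      comb <- combine_pvalues(pJ1[open], pJ2, nu)
      rejected[open] <- comb <= alpha2
    }
    phi <- eng_elementary(rejected, ctx$contain)
    disj[r] <- any(phi[ctx$falsenull])
    conj[r] <- all(phi[ctx$falsenull])
    fwer[r] <- any(phi[ctx$truenull])
  }
  .oc_wrap(disj, conj, fwer, reps, any(ctx$falsenull), any(ctx$truenull),
           conj_defined = scenario$rule != "ultra")
}

.sim_cer <- function(scenario, ctx, m1, m2) {
  design <- ctx$design; eng <- ctx$eng
  k <- ctx$k; n_arms <- ctx$n_arms
  S <- bitwShiftL(1L, k) - 1L
  bits <- bitwShiftL(1L, 0:(k - 1L))
  bnd <- .cer_boundaries_cached(design)
  b2pre <- design$corr$loadings2
  disj <- conj <- fwer <- numeric(m1)
  for (r in seq_len(m1)) {
    p1 <- .sim_one_stage1(scenario, ctx)
    rej1 <- eng_stage1_reject(eng, p1, bnd$c1)
    elem1 <- eng_elementary(rej1, ctx$contain)
    keep <- apply_dropping_rule(p1[1:n_arms], scenario$rule)
    sel <- c(keep, n_arms + keep)
    sel <- sel[!elem1[sel]]
    open <- which(!rej1)
    if (!length(sel) || !length(keep) || !length(open)) {
      phi <- elem1
      disj[r] <- any(phi[ctx$falsenull])
      conj[r] <- all(phi[ctx$falsenull])
      fwer[r] <- any(phi[ctx$truenull])
      next
    }
    B <- eng_cer_B(eng, p1, bnd$c2, design$t, b2pre)
    al <- .sim_stage2_alloc(scenario, ctx, keep)
    i2mask <- sum(bits[sel])
    e <- bitwAnd(open, i2mask)
    live <- open[e != 0L]                  # J_A and J_C
    elive <- e[e != 0L]
    auto <- B[live] >= 1
    tvec <- rep(design$t, k)
    b2 <- rep(0, k)
    tvec[c(keep, n_arms + keep)] <- rep(al$tfrac, 2)
    b2[c(keep, n_arms + keep)] <- sqrt(rep(al$lambda, 2))
    ctilde <- rep(NA_real_, length(live))
    if (any(!auto)) {
      sub <- eng_build(eng$W0[elive[!auto], , drop = FALSE], eng$blk)
      ctilde[!auto] <- eng_adapt_solve(sub, B[live[!auto]], p1, tvec, b2)
    } else sub <- NULL
    dr <- cj <- fw <- 0
    for (rr in seq_len(m2)) {
      p2m <- generate_stage_data(scenario, al$n_control, al$n_treat,
                                 arms = keep)
      p2 <- rep(NA_real_, k)
      p2[keep] <- p2m["primary", ]
      p2[n_arms + keep] <- p2m["secondary", ]
      pcum <- rep(Inf, k)
      pcum[sel] <- cumulative_pvalue(p1[sel], p2[sel], tvec[sel])
      rejected <- rej1
      rejected[live[auto]] <- TRUE
      if (any(!auto))
        rejected[live[!auto]] <- eng_stage2_reject(sub, pcum,
                                                   ctilde[!auto])
      phi <- eng_elementary(rejected, ctx$contain)
      dr <- dr + any(phi[ctx$falsenull])
      cj <- cj + all(phi[ctx$falsenull])
      fw <- fw + any(phi[ctx$truenull])
    }
    disj[r] <- dr / m2; conj[r] <- cj / m2; fwer[r] <- fw / m2
  }
  est <- c(disjunctive = if (any(ctx$falsenull)) mean(disj) else NA,
           conjunctive = if (any(ctx$falsenull) && scenario$rule != "ultra")
             mean(conj) else NA,
           fwer = if (any(ctx$truenull)) mean(fwer) else NA)
  se <- sqrt(pmax(est * (1 - est), 0) / m1)
  structure(list(estimates = est, se = se, n = m1, m2 = m2),
            class = "operating_characteristics")
}
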