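# Deterministic multivariate-normal numerics shared by all testing modules.
#
# Every probability used by the testing procedures is either
#   (a) a bivariate normal rectangle probability, evaluated by Gauss-Legendre
#       quadrature of the Drezner-Wesolowsky tetrachoric integral, or
#   (b) a probability for z statistics with a one-factor ("shared control")
#       correlation structure corr(Z_i, Z_j) = b_i * b_j, evaluated by
#       Gauss-Hermite quadrature after conditioning on the common factor, or
#   (c) a general MVN orthant probability delegated to mvtnorm.
# All routines are deterministic: repeated calls give identical results.

.ada_env <- new.env(parent = emptyenv())

# Golub-Welsch nodes/weights.  Hermite rule is returned in "probabilist"
# form: sum(w * f(x)) approximates E f(Z) for Z ~ N(0,1), sum(w) == 1.
gauss_hermite <- function(n) {
  key <- paste0("gh", n)
  if (!is.null(.ada_env[[key]])) return(.ada_env[[key]])
  i <- seq_len(n - 1L)
  a <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- a
  J[cbind(i + 1L, i)] <- a
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  res <- list(x = sqrt(2) * e$values[ord], w = (e$vectors[1L, ]^2)[ord])
  .ada_env[[key]] <- res
  res
}

gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  if (!is.null(.ada_env[[key]])) return(.ada_env[[key]])
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  res <- list(x = e$values[ord], w = (2 * e$vectors[1L, ]^2)[ord])
  .ada_env[[key]] <- res
  res
}

.GH_N <- 48L   # factor-conditioning rule; ~1e-10 for products of normal CDFs
.GL_N <- 24L   # tetrachoric integral rule (~1e-14 for |rho| <= 0.925)

# Vectorised bivariate normal CDF P(X <= h, Y <= k) for standard normal
# (X, Y) with correlation rho.  For |rho| <= 0.925 the Drezner-Wesolowsky
# single integral is used (vectorised); the rare high-correlation cases are
# delegated element-wise to mvtnorm's deterministic TVPACK code.
bvn_lower <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(h, n); k <- rep_len(k, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  deg <- !is.finite(h) | !is.finite(k) | abs(rho) >= 1
  if (any(deg)) {
    hh <- h[deg]; kk <- k[deg]; rr <- rho[deg]
    v <- pnorm(pmin(hh, kk))
    two <- is.finite(hh) & is.finite(kk)
    if (any(two)) {
      # |rho| == 1 boundary cases
      up <- two & rr >= 1
      v[up] <- pnorm(pmin(hh[up], kk[up]))
      dn <- two & rr <= -1
      v[dn] <- pmax(0, pnorm(hh[dn]) + pnorm(kk[dn]) - 1)
    }
    v[h[deg] == -Inf | k[deg] == -Inf] <- 0
    both_inf <- h[deg] == Inf & k[deg] == Inf
    v[both_inf] <- 1
    one_inf <- h[deg] == Inf & is.finite(k[deg])
    v[one_inf] <- pnorm(k[deg][one_inf])
    one_inf2 <- k[deg] == Inf & is.finite(h[deg])
    v[one_inf2] <- pnorm(h[deg][one_inf2])
    out[deg] <- v
  }
  ok <- !deg
  if (any(ok)) {
    lo <- abs(rho[ok]) <= 0.925
    io <- which(ok)[lo]
    if (length(io)) {
      gl <- gauss_legendre(.GL_N)
      hh <- h[io]; kk <- k[io]; rr <- rho[io]
      asr <- asin(rr)
      # map nodes to [0, asr] per element: theta = asr * (x + 1) / 2
      th <- outer(asr / 2, gl$x + 1)                    # n x q
      sn <- sin(th)
      num <- hh^2 + kk^2 - 2 * outer(hh * kk, rep(1, .GL_N)) * sn
      f <- exp(-num / (2 * cos(th)^2))
      int <- as.vector(f %*% gl$w) * asr / 2
      out[io] <- pnorm(hh) * pnorm(kk) + int / (2 * pi)
    }
    ih <- which(ok)[!lo]
    for (i in ih) {
      out[i] <- mvtnorm::pmvnorm(
        upper = c(h[i], k[i]),
        corr = matrix(c(1, rho[i], rho[i], 1), 2L),
        algorithm = mvtnorm::TVPACK(abseps = 1e-12))[1L]
    }
  }
  pmin(1, pmax(0, out))
}

# P(∩ Z_j <= z_j) for one-factor correlation corr_ij = b_i * b_j, |b_j| < 1.
onefactor_lower <- function(z, b) {
  stopifnot(length(z) == length(b))
  if (!length(z)) return(1)
  if (any(z == -Inf)) return(0)
  keep <- is.finite(z)
  if (!any(keep)) return(1)
  z <- z[keep]; b <- b[keep]
  if (length(z) == 1L) return(pnorm(z))
  s <- sqrt(1 - b^2)
  gh <- gauss_hermite(.GH_N)
  # Z_j = a_j xi_j - b_j xi_0 ; condition on xi_0 = x
  acc <- rep(0, length(gh$x))
  for (j in seq_along(z)) {
    acc <- acc + pnorm((z[j] + b[j] * gh$x) / s[j], log.p = TRUE)
  }
  sum(gh$w * exp(acc))
}

# P(∪ P_j <= q_j) on the z scale for one-factor z statistics.
onefactor_union <- function(q, b) {
  q <- pmin(pmax(q, 0), 1)
  1 - onefactor_lower(qnorm(1 - q), b)
}

# Two-look joint lower probability for a block of hypotheses sharing a
# control arm.  Z_{j,1} is the stage-one z statistic with factor loading
# b1_j; the cumulative statistic is Z_{j,2} = sqrt(t) Z_{j,1} +
# sqrt(1-t) Z_{j,(2)} with incremental loading b2_j.  Returns
# P(∩_j [Z_{j,1} <= u_j  and  Z_{j,2} <= v_j]).
twolook_lower <- function(u, v, b1, b2, t) {
  m <- length(u)
  stopifnot(length(v) == m, length(b1) == m, length(b2) == m)
  if (!m) return(1)
  if (any(u == -Inf) || any(v == -Inf)) return(0)
  if (m == 1L) {
    # joint of (Z_1, sqrt(t) Z_1 + sqrt(1-t) Z_(2)) has correlation sqrt(t)
    return(bvn_lower(u, v, sqrt(t)))
  }
  a1 <- sqrt(1 - b1^2); a2 <- sqrt(1 - b2^2)
  c1 <- sqrt(t) * a1; c2 <- sqrt(1 - t) * a2
  nrm <- sqrt(c1^2 + c2^2)
  gh <- gauss_hermite(24L)
  x <- gh$x; w <- gh$w
  nx <- length(x)
  X <- matrix(x, nx, nx)        # stage-one control factor (rows)
  Y <- matrix(x, nx, nx, byrow = TRUE)   # stage-two control factor (cols)
  acc <- matrix(0, nx, nx)      # log of the conditional product
  for (j in seq_len(m)) {
    ut <- (u[j] + b1[j] * X) / a1[j]
    vt <- (v[j] + sqrt(t) * b1[j] * X + sqrt(1 - t) * b2[j] * Y) / nrm[j]
    acc <- acc + log(pmax(bvn_lower(ut, vt, c1[j] / nrm[j]), 1e-320))
  }
  tot <- sum(tcrossprod(w) * exp(acc))
  min(1, max(0, tot))
}

# Conditional stage-two crossing probability for one block given stage-one
# p-values: P(∪_j P~_{j,2} <= q_j | p_{j,1}), where the cumulative p-value
# combines stages at information fraction t_j and the incremental z
# statistics have one-factor loadings b2.  Components with q_j = 0 never
# reject and are dropped.
cond_union <- function(q, p1, t, b2) {
  stopifnot(length(q) == length(p1))
  t <- rep_len(t, length(q))
  b2 <- rep_len(b2, length(q))
  q <- pmin(pmax(q, 0), 1)
  zp <- qnorm(1 - clamp_p(p1))
  bb <- (qnorm(1 - q) - sqrt(t) * zp) / sqrt(1 - t)
  1 - onefactor_lower(bb, b2)
}

#' Multivariate normal upper-orthant probability
#'
#' Computes \eqn{P(Z_1 > t_1, \ldots, Z_d > t_d)} for a standard
#' multivariate normal vector with the given correlation matrix.  For
#' dimensions up to three a deterministic algorithm is used directly; for
#' higher dimensions the computation is delegated to
#' [mvtnorm::pmvnorm()] under a fixed internal random seed so that
#' repeated calls return identical values.
#'
#' @param thresholds Numeric vector of lower thresholds (may be `-Inf`).
#' @param corr Correlation matrix (unit diagonal, positive semidefinite).
#' @return A single probability.
#' @examples
#' mvn_upper_orthant(qnorm(0.975), matrix(1))        # 0.025
#' mvn_upper_orthant(c(0, 0), diag(2))               # 0.25
#' @export
mvn_upper_orthant <- function(thresholds, corr) {
  d <- length(thresholds)
  corr <- as.matrix(corr)
  stopifnot(nrow(corr) == d, ncol(corr) == d)
  if (any(abs(diag(corr) - 1) > 1e-8)) stop("'corr' must have unit diagonal")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("'corr' is not positive semidefinite")
  if (d == 1L) return(pnorm(thresholds, lower.tail = FALSE))
  if (d == 2L) {
    h <- thresholds[1]; k <- thresholds[2]; r <- corr[1, 2]
    # P(X>h, Y>k) = P(X<=-h, Y<=-k) by symmetry
    return(bvn_lower(-h, -k, r))
  }
  if (d == 3L && all(abs(corr[upper.tri(corr)]) < 1) && min(ev) > 1e-10) {
    return(mvtnorm::pmvnorm(lower = thresholds, upper = rep(Inf, d),
                            corr = corr,
                            algorithm = mvtnorm::TVPACK(abseps = 1e-10))[1L])
  }
  # deterministic through a fixed, restored RNG state
  seed_exists <- exists(".Random.seed", envir = globalenv())
  if (seed_exists) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (seed_exists) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(271828L)
  mvtnorm::pmvnorm(lower = thresholds, upper = rep(Inf, d), corr = corr,
                   algorithm = mvtnorm::GenzBretz(abseps = 1e-9,
                                                  maxpts = 250000L))[1L]
}

#' Solve a monotone scalar equation
#'
#' Deterministic bracketing root finder for monotone functions, used for
#' all critical-constant and level computations.
#'
#' @param f Monotone scalar function.
#' @param lower,upper Bracket endpoints; `f(lower) - target` and
#'   `f(upper) - target` must differ in sign.
#' @param target Value to solve for (default 0).
#' @param tol Absolute tolerance on the argument.
#' @return The root.
#' @export
solve_monotone <- function(f, lower, upper, target = 0, tol = 1e-10) {
  flo <- f(lower) - target
  fhi <- f(upper) - target
  if (flo == 0) return(lower)
  if (fhi == 0) return(upper)
  if (sign(flo) == sign(fhi))
    stop("solve_monotone: target not bracketed on [", lower, ", ", upper, "]")
  uniroot(function(x) f(x) - target, c(lower, upper), tol = tol,
          f.lower = flo, f.upper = fhi)$root
}

#' Correlation of treatment-versus-control z statistics
#'
#' For comparisons of several treatments against a shared control arm the
#' z statistics have correlation \eqn{\sqrt{\lambda_i \lambda_j}} with
#' \eqn{\lambda_i = n_i / (n_i + n_0)} (Dunnett structure).
#'
#' @param n_treat Vector of per-treatment sample sizes.
#' @param n_control Control-arm sample size.
#' @return Correlation matrix of dimension `length(n_treat)`.
#' @examples
#' dunnett_correlation(c(70, 70), 70)[1, 2]  # 0.5 under balance
#' @export
dunnett_correlation <- function(n_treat, n_control) {
  b <- dunnett_loadings(n_treat, n_control)
  r <- tcrossprod(b)
  diag(r) <- 1
  r
}

#' @rdname dunnett_correlation
#' @details `dunnett_loadings()` returns the factor loadings
#'   \eqn{\sqrt{\lambda_i}}; the correlation matrix is their outer
#'   product off the diagonal.
#' @export
dunnett_loadings <- function(n_treat, n_control) {
  stopifnot(all(n_treat > 0), n_control > 0)
  sqrt(n_treat / (n_treat + n_control))
}

#' Information fraction of the first stage
#'
#' For a treatment-versus-control comparison of means the statistical
#' information of a stage is \eqn{(1/n_T + 1/n_C)^{-1}}.  The information
#' fraction of stage one is stage-one information divided by total
#' information.
#'
#' @param n1_treat,n1_control Stage-one sample sizes for the comparison.
#' @param n2_treat,n2_control Incremental stage-two sample sizes.
#' @return Fraction in (0, 1].
#' @examples
#' information_fraction(35, 35, 52, 53)  # 0.4
#' @export
information_fraction <- function(n1_treat, n1_control, n2_treat, n2_control) {
  stopifnot(n1_treat > 0, n1_control > 0, n2_treat >= 0, n2_control >= 0)
  i1 <- 1 / (1 / n1_treat + 1 / n1_control)
  i2 <- if (n2_treat == 0 || n2_control == 0) 0 else
    1 / (1 / n2_treat + 1 / n2_control)
  i1 / (i1 + i2)
}

# p-values of exactly 0 or 1 are clamped before probit transformation
.P_EPS <- 1e-15
clamp_p <- function(p) pmin(pmax(p, .P_EPS), 1 - .P_EPS)
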