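# Internal vectorised closure engine.
#
# The Monte-Carlo simulator must evaluate adjusted p-values, conditional
# error rates and adapted boundaries for all 2^k - 1 intersection
# hypotheses in every replicate.  This engine flattens the closure into
# "triples" (subset, hypothesis, weight), grouped by (subset, block), so
# that all subsets are processed in a handful of vectorised operations:
# block union probabilities by Gauss-Hermite conditioning on the shared
# control factor, minima by segment reduction, and adapted critical
# constants by simultaneous bisection across subsets.
#
# The engine assumes the one-factor (shared control) correlation
# structure within blocks; its results are cross-checked against the
# scalar module functions in the test suite.

.ENG_GH <- 32L

eng_build <- function(W, blk) {
  S <- nrow(W); k <- ncol(W)
  W0 <- W
  W0[is.na(W0)] <- 0
  pos <- which(W0 > 0, arr.ind = TRUE)
  s <- pos[, 1L]; j <- pos[, 2L]
  nb <- max(blk)
  gkey <- (s - 1L) * nb + blk[j]
  o <- order(gkey)
  s <- s[o]; j <- j[o]
  w <- W0[pos][o]
  g <- cumsum(!duplicated(gkey[o]))
  ng <- g[length(g)]
  grp_start <- which(!duplicated(g))
  grp_len <- tabulate(g, ng)
  grp_s <- s[grp_start]
  grp_W <- as.vector(rowsum(w, g))
  # per-subset segments over groups (grp_s is nondecreasing, covers 1..S
  # for exhaustive weight tables)
  stopifnot(identical(sort(unique(grp_s)), seq_len(S)))
  sub_start <- which(!duplicated(grp_s))
  sub_len <- tabulate(grp_s, S)
  # per-subset segments over triples
  tri_start <- which(!duplicated(s))
  tri_len <- tabulate(s, S)
  list(S = S, k = k, s = s, j = j, w = w, g = g, ng = ng,
       grp_start = grp_start, grp_len = grp_len, grp_s = grp_s,
       grp_W = grp_W, sub_start = sub_start, sub_len = sub_len,
       tri_start = tri_start, tri_len = tri_len, W0 = W0, blk = blk)
}

# segment minimum of v over contiguous segments (start, len)
seg_min <- function(v, start, len) {
  m <- v[start]
  L <- max(len)
  d <- 1L
  while (d < L) {
    sel <- len > d
    m[sel] <- pmin(m[sel], v[start[sel] + d])
    d <- d + 1L
  }
  m
}

seg_any <- function(v, start, len) {
  m <- v[start]
  L <- max(len)
  d <- 1L
  while (d < L) {
    sel <- len > d
    m[sel] <- m[sel] | v[start[sel] + d]
    d <- d + 1L
  }
  m
}

# Union probability P(∪_j Z_j >= zq_j) per (subset, block) group under the
# one-factor structure with per-hypothesis loadings b.
eng_group_union <- function(eng, zq, b) {
  bj <- b[eng$j]
  sj <- sqrt(1 - bj^2)
  gh <- gauss_hermite(.ENG_GH)
  lp <- pnorm((zq + outer(bj, gh$x)) / sj, log.p = TRUE)
  Slog <- rowsum(lp, eng$g)
  1 - as.vector(exp(Slog) %*% gh$w)
}

# Mixed-regime adjusted p-values for all subsets at once.
eng_adjusted <- function(eng, p, b) {
  p <- clamp_p(p)
  v <- p[eng$j] / eng$w
  m_g <- seg_min(v, eng$grp_start, eng$grp_len)
  q <- pmin(1, eng$w * m_g[eng$g])
  U <- eng_group_union(eng, qnorm(1 - q), b)
  # numerical guard: a union probability can come out a hair below its
  # largest single term; the adjusted p is a probability ratio in [0, 1]
  r <- pmax(U, 0) / eng$grp_W
  pmin(1, seg_min(r, eng$sub_start, eng$sub_len))
}

# Stage-one group-sequential crossings: subset rejected iff
# min_j p_j / w_j <= c1[subset].
eng_stage1_reject <- function(eng, p, c1) {
  v <- p[eng$j] / eng$w
  seg_min(v, eng$tri_start, eng$tri_len) <= c1
}

# Conditional error rates B_J for all subsets: sum over blocks of the
# conditional stage-two union probability of the preplanned test.
eng_cer_B <- function(eng, p1, c2, t, b2) {
  zp <- qnorm(1 - clamp_p(p1))
  q <- pmin(1, eng$w * c2[eng$s])
  bb <- (qnorm(1 - q) - sqrt(t) * zp[eng$j]) / sqrt(1 - t)
  U <- eng_group_union(eng, bb, b2)
  as.vector(rowsum(pmax(U, 0), eng$grp_s))
}

# Simultaneous bisection for adapted stage-two constants.
#
# rows: a sub-engine built over the effective (selected) subsets, one row
# per open intersection hypothesis; B: target conditional errors;
# p1: stage-one marginal p-values; tvec, b2: per-hypothesis adapted
# information fractions and incremental loadings.  Returns c in (0, 1];
# rows whose equality cannot be reached within (0, 1] are capped at 1
# (the adapted test then runs at conditional level f(1) <= B, which is
# conservative but valid).
eng_adapt_solve <- function(eng, B, p1, tvec, b2, iters = 26L) {
  zp <- qnorm(1 - clamp_p(p1))
  stj <- sqrt(tvec)[eng$j]
  s1t <- sqrt(1 - tvec)[eng$j]
  zpj <- zp[eng$j]
  gh <- gauss_hermite(20L)
  bj <- b2[eng$j]
  sj <- sqrt(1 - bj^2)
  M <- outer(bj, gh$x)
  lo <- rep(1e-12, eng$S)
  hi <- rep(1, eng$S)
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    q <- pmin(1, eng$w * mid[eng$s])
    bb <- (qnorm(1 - q) - stj * zpj) / s1t
    lp <- pnorm((bb + M) / sj, log.p = TRUE)
    U <- 1 - as.vector(exp(rowsum(lp, eng$g)) %*% gh$w)
    Bhat <- as.vector(rowsum(pmax(U, 0), eng$grp_s))
    up <- Bhat < B
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

# Stage-two rejection of each subset: any cumulative p-value at or below
# its per-component boundary w * c.
eng_stage2_reject <- function(eng, pcum, ctilde) {
  hit <- pcum[eng$j] <= eng$w * ctilde[eng$s]
  seg_any(hit, eng$tri_start, eng$tri_len)
}

# Closed-test elementary decisions from a subset rejection vector.
# contain[[i]]: masks containing hypothesis i (precomputed).
eng_containment <- function(k) {
  S <- bitwShiftL(1L, k) - 1L
  lapply(seq_len(k), function(i)
    which(bitwAnd(seq_len(S), bitwShiftL(1L, i - 1L)) != 0L))
}

eng_elementary <- function(rejected, contain) {
  vapply(contain, function(ix) all(rejected[ix]), TRUE)
}
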