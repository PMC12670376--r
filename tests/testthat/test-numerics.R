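test_that("bivariate normal CDF matches mvtnorm across the rho range", {
  set.seed(1)
  for (rho in c(-0.99, -0.95, -0.6, 0, 0.3, 0.7, 0.9, 0.95, 0.99)) {
    for (i in 1:5) {
      h <- rnorm(1); k <- rnorm(1)
      ref <- mvtnorm::pmvnorm(upper = c(h, k),
                              corr = matrix(c(1, rho, rho, 1), 2),
                              algorithm = mvtnorm::TVPACK(abseps = 1e-14))[1]
      expect_equal(adagraph:::bvn_lower(h, k, rho), ref, tolerance = 1e-10)
    }
  }
  # boundary cases
  expect_equal(adagraph:::bvn_lower(Inf, 1, 0.5), pnorm(1))
  expect_equal(adagraph:::bvn_lower(-Inf, 1, 0.5), 0)
  expect_equal(adagraph:::bvn_lower(0, 0, 1), 0.5)
})

test_that("one-factor lower probability agrees with generic MVN integration", {
  set.seed(2)
  for (i in 1:5) {
    d <- sample(2:5, 1)
    b <- runif(d, 0.2, 0.9)
    z <- rnorm(d, 1)
    r <- tcrossprod(b); diag(r) <- 1
    ref <- mvtnorm::pmvnorm(upper = z, corr = r,
                            algorithm = mvtnorm::Miwa(steps = 512))[1]
    expect_equal(adagraph:::onefactor_lower(z, b), ref, tolerance = 1e-7)
  }
})

test_that("two-look block probability matches an explicit 2m-dimensional MVN", {
  tt <- 0.5
  b <- sqrt(c(0.5, 0.5))
  R4 <- matrix(c(1, 0.5, sqrt(tt), 0.5 * sqrt(tt),
                 0.5, 1, 0.5 * sqrt(tt), sqrt(tt),
                 sqrt(tt), 0.5 * sqrt(tt), 1, 0.5,
                 0.5 * sqrt(tt), sqrt(tt), 0.5, 1), 4)
  for (i in 1:4) {
    set.seed(10 + i)
    u <- rnorm(2, 2); v <- rnorm(2, 2)
    ref <- mvtnorm::pmvnorm(upper = c(u, v), corr = R4,
                            algorithm = mvtnorm::Miwa(steps = 512))[1]
    expect_equal(adagraph:::twolook_lower(u, v, b, b, tt), ref,
                 tolerance = 1e-8)
  }
  # unbalanced loadings and t != 0.5 against a construction-based MC oracle
  set.seed(99)
  b1 <- sqrt(c(0.45, 0.55)); b2 <- sqrt(c(0.6, 0.35)); tt <- 0.4
  n <- 4e5
  x0 <- rnorm(n); y0 <- rnorm(n)
  z1 <- sapply(1:2, function(j) sqrt(1 - b1[j]^2) * rnorm(n) - b1[j] * x0)
  zi <- sapply(1:2, function(j) sqrt(1 - b2[j]^2) * rnorm(n) - b2[j] * y0)
  z2 <- sqrt(tt) * z1 + sqrt(1 - tt) * zi
  u <- c(1.2, 0.8); v <- c(1.0, 1.4)
  hit <- z1[, 1] <= u[1] & z1[, 2] <= u[2] & z2[, 1] <= v[1] & z2[, 2] <= v[2]
  est <- mean(hit)
  se <- sd(hit) / sqrt(n)
  expect_lt(abs(adagraph:::twolook_lower(u, v, b1, b2, tt) - est), 3 * se)
})

test_that("upper-orthant probabilities are correct and deterministic", {
  expect_equal(mvn_upper_orthant(qnorm(0.975), matrix(1)), 0.025,
               tolerance = 1e-12)
  # marginalisation: an infinite threshold drops a dimension
  r <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(mvn_upper_orthant(c(-Inf, 1.3), r),
               pnorm(1.3, lower.tail = FALSE), tolerance = 1e-9)
  # d = 3 against a Monte-Carlo oracle
  set.seed(3)
  A <- matrix(rnorm(9), 3); R <- cov2cor(crossprod(A))
  th <- rnorm(3, 0.3)
  L <- chol(R)
  n <- 5e5
  Z <- matrix(rnorm(3 * n), n) %*% L
  hit <- Z[, 1] > th[1] & Z[, 2] > th[2] & Z[, 3] > th[3]
  expect_lt(abs(mvn_upper_orthant(th, R) - mean(hit)),
            3 * sd(hit) / sqrt(n))
  # repeat calls identical (also in dimension >= 4, where QMC is seeded)
  R4 <- diag(4) * 0.5 + 0.5
  th4 <- c(0.1, 0.4, -0.2, 0.8)
  expect_identical(mvn_upper_orthant(th4, R4), mvn_upper_orthant(th4, R4))
  # monotone nonincreasing in each threshold, bounded by Bonferroni
  p0 <- mvn_upper_orthant(th, R)
  for (j in 1:3) {
    th2 <- th; th2[j] <- th2[j] + 0.5
    expect_lte(mvn_upper_orthant(th2, R), p0 + 1e-9)
  }
  expect_error(mvn_upper_orthant(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "semidefinite")
})

test_that("monotone solver hits trivial and probit targets", {
  expect_equal(solve_monotone(identity, 0, 1, target = 0.3), 0.3,
               tolerance = 1e-10)
  expect_equal(solve_monotone(pnorm, -10, 10, target = 0.975),
               qnorm(0.975), tolerance = 1e-8)
  expect_error(solve_monotone(identity, 0, 1, target = 2), "bracket")
})

test_that("Dunnett correlation follows the shared-control structure", {
  expect_equal(dunnett_correlation(c(70, 70), 70)[1, 2], 0.5)
  r <- dunnett_correlation(c(40, 90), 60)
  expect_equal(r[1, 2], sqrt((40 / 100) * (90 / 150)), tolerance = 1e-12)
  # empirical check from simulated group means
  set.seed(4)
  n <- c(30, 75); n0 <- 50; reps <- 2e5
  x0 <- rnorm(reps, sd = 1 / sqrt(n0))   # shared control mean
  z <- sapply(seq_along(n), function(j) {
    (rnorm(reps, sd = 1 / sqrt(n[j])) - x0) / sqrt(1 / n[j] + 1 / n0)
  })
  emp <- cor(z[, 1], z[, 2])
  expect_lt(abs(emp - dunnett_correlation(n, n0)[1, 2]),
            3 / sqrt(reps) * (1 - emp^2) + 0.003)
})

test_that("information fractions match the sample-size arithmetic", {
  expect_near(information_fraction(35, 35, 52, 53), 0.4, 5e-4)
  expect_equal(information_fraction(50, 50, 50, 50), 0.5)
  expect_equal(information_fraction(50, 50, 0, 0), 1)
  expect_error(information_fraction(0, 50, 50, 50))
})

test_that("error spending has the O'Brien-Fleming shape", {
  expect_near(spending_alpha1(0.5, 0.025), 0.0015253, 1e-4)
  expect_near(spending_alpha1(1, 0.025), 0.025, 1e-12)
  expect_lt(spending_alpha1(1e-4, 0.025), 1e-10)
  expect_error(spending_alpha1(0, 0.025), "fraction")
})
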