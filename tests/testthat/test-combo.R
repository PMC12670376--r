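test_that("two-stage level condition yields the printed stage-two level", {
  a1 <- spending_alpha1(0.5, 0.025)
  a2 <- solve_alpha2(a1, 0.025, sqrt(c(0.5, 0.5)))
  expect_near(a2, 0.0245, 5e-5)
  expect_near(a2, 0.0244998, 1e-6)
  # no stage-one spending: the combination function is uniform itself
  expect_equal(solve_alpha2(0, 0.025, sqrt(c(0.5, 0.5))), 0.025)
})

test_that("solved stage-two level satisfies the level condition empirically", {
  set.seed(21)
  a1 <- 0.01; alpha <- 0.025
  nu <- sqrt(c(0.5, 0.5))
  a2 <- solve_alpha2(a1, alpha, nu)
  n <- 2e6
  p1 <- runif(n); p2 <- runif(n)
  comb <- combine_pvalues(p1, p2, nu)
  hit <- p1 <= a1 | (p1 > a1 & comb <= a2)
  expect_lt(abs(mean(hit) - alpha), 3 * sqrt(alpha * (1 - alpha) / n))
})

test_that("inverse-normal combination reproduces the final-table entries", {
  nu <- sqrt(c(0.5, 0.5))
  expect_near(combine_pvalues(0.0410, 0.0209, nu), 0.0038, 5e-5)
  expect_near(combine_pvalues(0.0952, 0.1121, nu), 0.0371, 5e-5)
  expect_near(combine_pvalues(0.0900, 0.0418, nu), 0.0149, 5e-5)
  expect_near(combine_pvalues(0.5, 0.5, nu), 0.5, 1e-12)
  # clamping keeps degenerate inputs finite
  expect_gt(combine_pvalues(0, 0.5, nu), 0)
  expect_lt(combine_pvalues(1, 0.5, nu), 1)
})

test_that("interim closed test reproduces the stage-one worked example", {
  design <- schizo_design()
  expect_near(design$alpha1, 0.0015253, 1e-4)
  it <- combo_interim(design, schizo_p1)
  # every intersection containing H1 is rejected, nothing else
  k <- design$k
  for (m in 1:(2^k - 1)) {
    has1 <- bitwAnd(m, 1L) != 0L
    expect_identical(unname(it$rejected1[m]), has1)
  }
  expect_equal(it$I1r, 1L)
  expect_equal(it$I1star, 2:4)
  # spot-check adjusted p-values against the printed table
  pj <- it$pJ1
  expect_near(pj[15], 0.00088, 2e-6)   # {1,2,3,4}
  expect_near(pj[14], 0.0900, 1e-6)    # {2,3,4}
  expect_near(pj[13], 0.0006, 1e-9)    # {1,3,4}
  expect_near(pj[12], 0.0410, 1e-5)    # {3,4}
  expect_near(pj[2], 0.0952, 1e-12)    # {2}
})

test_that("interim handles the degenerate extremes", {
  design <- schizo_design()
  it1 <- combo_interim(design, rep(1, 4))
  expect_false(any(it1$rejected1))
  expect_equal(it1$I1star, 1:4)
  it0 <- combo_interim(design, rep(0, 4))
  expect_true(all(it0$rejected1))
  expect_equal(it0$I1r, 1:4)
})

test_that("the open set partitions into A, B, C as in the worked example", {
  design <- schizo_design()
  bt <- cer_boundaries(design)
  ci <- cer_interim(bt, schizo_p1)
  plan <- adaptation_plan(design, select = c("H2", "H4"),
                          graph = adapted_graph_24(), t_adapted = 0.4)
  part <- partition_open(ci, plan)
  msk <- function(J) adagraph:::subset_mask(J, 4)
  expect_setequal(part$A, c(msk(2), msk(4), msk(c(2, 4))))
  expect_setequal(part$B, msk(3))
  expect_setequal(part$C, c(msk(2:4), msk(3:4), msk(2:3)))
  # I2 = I1* leaves B and C empty; I2 = empty puts everything in B
  it <- combo_interim(design, schizo_p1)
  pall <- partition_open(it, adaptation_plan(design, select = 2:4))
  expect_length(pall$B, 0)
  expect_length(pall$C, 0)
  pnone <- partition_open(it, adaptation_plan(design, select = integer()))
  expect_length(pnone$A, 0)
  expect_length(pnone$C, 0)
  expect_setequal(pnone$B, which(!it$rejected1))
  expect_error(partition_open(it, adaptation_plan(design, select = 1L)),
               "continuing")
})

test_that("final combination test reproduces the no-adaptation tables", {
  design <- schizo_design()
  it <- combo_interim(design, schizo_p1)
  plan <- adaptation_plan(design, select = 2:4)
  fin <- combo_final(it, plan, schizo_p2_combo)
  msk <- function(J) adagraph:::subset_mask(J, 4)
  expect_near(fin$pJ2[msk(2:4)], 0.0448, 5e-5)
  expect_near(fin$pJ2[msk(3:4)], 0.0209, 5e-5)
  expect_near(fin$pJ2[msk(c(2, 4))], 0.1121, 1e-12)
  expect_near(fin$combined[msk(2:4)], 0.0158, 5e-5)
  expect_near(fin$combined[msk(3:4)], 0.0038, 5e-5)
  expect_near(fin$combined[msk(3)], 0.0012, 5e-5)
  expect_equal(unname(fin$phi), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("adaptive reweighting changes the tables but not the outcome", {
  design <- schizo_design()
  it <- combo_interim(design, schizo_p1)
  plan <- adaptation_plan(design, select = 2:4, graph = adapted_graph_234())
  fin <- combo_final(it, plan, schizo_p2_combo)
  msk <- function(J) adagraph:::subset_mask(J, 4)
  expect_near(fin$pJ2[msk(2:4)], 0.0418, 5e-5)
  expect_near(fin$pJ2[msk(3:4)], 0.0250, 5e-5)
  expect_near(fin$pJ2[msk(c(2, 4))], 0.1495, 5e-5)
  expect_near(fin$pJ2[msk(2:3)], 0.0300, 2e-4)  # coarsely printed
  expect_near(fin$combined[msk(2:4)], 0.0149, 5e-5)
  expect_near(fin$combined[msk(3:4)], 0.0045, 1e-4)
  expect_equal(unname(fin$phi), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("without stage-two evidence only early rejections survive", {
  design <- schizo_design()
  it <- combo_interim(design, schizo_p1)
  plan <- adaptation_plan(design, select = 2:4)
  fin <- combo_final(it, plan, c(H2 = 1, H3 = 1, H4 = 1))
  expect_equal(which(unname(fin$phi)), it$I1r)
})

test_that("closed-test decisions are coherent", {
  design <- schizo_design()
  # the worked example rejects H1 and H3: every containing subset must be
  # rejected too
  it0 <- combo_interim(design, schizo_p1)
  fin0 <- combo_final(it0, adaptation_plan(design, select = 2:4),
                      schizo_p2_combo)
  for (i2 in which(fin0$phi)) {
    bit <- bitwShiftL(1L, i2 - 1L)
    expect_true(all(fin0$rejected[which(bitwAnd(1:15, bit) != 0L)]))
  }
  # and on random null data
  set.seed(22)
  for (i in 1:10) {
    p1 <- null_pvalues(design)
    it <- combo_interim(design, p1)
    sel <- it$I1star
    if (!length(sel)) next
    plan <- adaptation_plan(design, select = sel)
    p2 <- stats::setNames(null_pvalues(design, 2)[sel], design$labels[sel])
    fin <- combo_final(it, plan, p2)
    # an elementary rejection implies rejection of every containing subset
    for (i2 in which(fin$phi)) {
      bit <- bitwShiftL(1L, i2 - 1L)
      masks <- which(bitwAnd(1:15, bit) != 0L)
      expect_true(all(fin$rejected[masks]))
    }
  }
})
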