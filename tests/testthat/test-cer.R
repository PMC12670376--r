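test_that("cumulative p-values reproduce the adapted worked example", {
  expect_near(cumulative_pvalue(0.0952, 0.0299, 0.4), 0.0111, 5e-5)
  expect_near(cumulative_pvalue(0.1104, 0.0586, 0.4), 0.0234, 5e-5)
  expect_near(cumulative_pvalue(0.5, 0.5, 0.37), 0.5, 1e-12)
})

test_that("preplanned boundaries match the printed design table", {
  bnd <- cer_boundaries(schizo_design())
  msk <- function(J) adagraph:::subset_mask(J, 4)
  # parametric {1,2,3,4}: c1 = 0.001564, c2 = 0.02633
  expect_near(bnd$c1[msk(1:4)], 0.001564, 5e-7)
  expect_near(bnd$c2[msk(1:4)], 0.02633, 5e-6)
  # nonparametric {2,3,4}: c1 = alpha1, c2 = 0.024409
  expect_near(bnd$c1[msk(2:4)], 0.0015253, 1e-6)
  expect_near(bnd$c2[msk(2:4)], 0.024409, 5e-7)
  # singletons: the elementary two-look group-sequential design
  expect_near(bnd$c1[msk(1)], 0.001525, 1e-6)
  expect_near(bnd$c2[msk(1)], 0.0245, 5e-5)
  # identical structure gives identical constants across subsets
  expect_equal(bnd$c2[msk(c(1, 2))], bnd$c2[msk(c(3, 4))])
  # stage-two constants exceed their stage-one counterparts
  expect_true(all(bnd$c2 > bnd$c1))
})

test_that("interim conditional errors match the printed B table", {
  bnd <- cer_boundaries(schizo_design())
  ci <- cer_interim(bnd, schizo_p1)
  msk <- function(J) adagraph:::subset_mask(J, 4)
  expect_true(all(ci$rejected1[bitwAnd(1:15, 1L) != 0L]))
  expect_false(any(ci$rejected1[bitwAnd(1:15, 1L) == 0L]))
  expect_equal(ci$I1star, 2:4)
  expect_near(ci$B[msk(3:4)], 0.1415, 5e-5)
  expect_near(ci$B[msk(2:4)], 0.1117, 5e-5)
  expect_near(ci$B[msk(2:3)], 0.1117, 5e-5)
  expect_near(ci$B[msk(c(2, 4))], 0.0702, 5e-5)
  expect_near(ci$B[msk(2)], 0.0702, 5e-5)
  expect_near(ci$B[msk(3)], 0.2179, 5e-5)
  expect_near(ci$B[msk(4)], 0.0594, 5e-5)
})

test_that("adapted boundaries reproduce the selection worked example", {
  design <- schizo_design()
  bnd <- cer_boundaries(design)
  ci <- cer_interim(bnd, schizo_p1)
  plan <- adaptation_plan(design, select = c("H2", "H4"),
                          graph = adapted_graph_24(), t_adapted = 0.4)
  ad <- cer_adapt(ci, plan)
  msk <- function(J) adagraph:::subset_mask(J, 4)
  # J_A rows: per-component boundaries w * ctilde
  expect_near(0.5 * ad$ctilde[msk(c(2, 4))], 0.0137, 5e-5)
  expect_near(ad$ctilde[msk(4)], 0.0237, 5e-5)
  expect_near(ad$ctilde[msk(2)], 0.0244, 5e-5)
  # J_C rows: restricted index set, B_J retained
  expect_near(ad$ctilde[msk(3:4)], 0.0541, 5e-5)
  expect_near(0.5 * ad$ctilde[msk(2:4)], 0.0210, 5e-5)
  expect_near(ad$ctilde[msk(2:3)], 0.0382, 1e-4)
  # J_B is never rejected at stage two
  expect_true(msk(3) %in% ad$part$B)
  fin <- cer_final(ad, schizo_p2_cer)
  expect_near(unname(fin$p_cumulative[c(2, 4)]), c(0.0111, 0.0234), 5e-5)
  expect_equal(unname(fin$phi), c(TRUE, TRUE, FALSE, TRUE))
})

test_that("mixed-case reweighting yields the printed adapted constant", {
  design <- schizo_design()
  ci <- cer_interim(cer_boundaries(design), schizo_p1)
  plan <- adaptation_plan(design, select = 2:4, graph = adapted_graph_234())
  ad <- cer_adapt(ci, plan)
  m234 <- adagraph:::subset_mask(2:4, 4)
  expect_near(ad$ctilde[m234], 0.027492, 1.5e-6)
})

test_that("no adaptation recovers the preplanned stage-two constants", {
  design <- schizo_design()
  bnd <- cer_boundaries(design)
  set.seed(31)
  for (i in 1:5) {
    p1 <- null_pvalues(design)
    # keep p-values away from the early-rejection region so subsets stay open
    p1 <- pmin(pmax(p1, 0.02), 0.98)
    ci <- cer_interim(bnd, p1)
    plan <- adaptation_plan(design, select = ci$I1star)
    ad <- cer_adapt(ci, plan)
    open <- which(!ci$rejected1)
    expect_near(ad$ctilde[open], bnd$c2[open], 1e-6)
  }
})

test_that("conditional errors fall as stage-one evidence weakens", {
  design <- schizo_design()
  bnd <- cer_boundaries(design)
  m34 <- adagraph:::subset_mask(3:4, 4)
  Bs <- sapply(c(0.05, 0.2, 0.5, 0.8), function(p3) {
    ci <- cer_interim(bnd, c(H1 = 0.5, H2 = 0.5, H3 = p3, H4 = 0.5))
    ci$B[m34]
  })
  expect_true(all(diff(Bs) < 0))
  # and the adapted constant grows with B
  plan <- adaptation_plan(design, select = 2:4, t_adapted = 0.4)
  cts <- sapply(c(0.05, 0.2, 0.5), function(p3) {
    ci <- cer_interim(bnd, c(H1 = 0.5, H2 = 0.5, H3 = p3, H4 = 0.5))
    ad <- cer_adapt(ci, plan)
    ad$ctilde[m34]
  })
  expect_true(all(diff(cts) < 0))
})

test_that("uninformative stage-two data add no rejections", {
  design <- schizo_design()
  ci <- cer_interim(cer_boundaries(design), schizo_p1)
  plan <- adaptation_plan(design, select = 2:4)
  ad <- cer_adapt(ci, plan)
  fin <- cer_final(ad, c(H2 = 1, H3 = 1, H4 = 1))
  expect_equal(which(unname(fin$phi)), ci$I1r)
})

test_that("a PCER above one triggers outright rejection", {
  # three nonparametric hypotheses with equal weights; stage-one p-values
  # just above the per-component boundary of the global intersection keep
  # it open while pushing the sum of conditional tails beyond 1
  G <- matrix(1 / 2, 3, 3); diag(G) <- 0
  design <- two_stage_design(mcp_graph(rep(1 / 3, 3), G))
  bnd <- cer_boundaries(design)
  p1 <- setNames(rep(0.00055, 3), design$labels)
  ci <- cer_interim(bnd, p1)
  m123 <- adagraph:::subset_mask(1:3, 3)
  expect_false(ci$rejected1[m123])
  expect_gte(ci$B[m123], 1)
  plan <- adaptation_plan(design, select = ci$I1star)
  ad <- cer_adapt(ci, plan)
  expect_true(ad$auto[m123])
  fin <- cer_final(ad, setNames(rep(1, length(ci$I1star)),
                                design$labels[ci$I1star]))
  expect_true(fin$rejected[m123])
})
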