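# adagraph

Graph-based, adaptive, multiarm, multiple-endpoint, two-stage closed
testing with strong familywise error rate (FWER) control.

## The problem

Confirmatory trials that compare several treatment arms with a shared
control on more than one endpoint must test many one-sided hypotheses
`H_j: δ_j = 0` while keeping the probability of any false rejection at
a one-sided level α — under *every* configuration of true and false
nulls, and even when the trial is modified mid-course.  `adagraph` is
for trial statisticians who want to

* express the team's testing priorities as a weighted directed graph
  whose node-removal rule induces weights `w_{j,J}` for every
  intersection hypothesis `H_J` of the closed test;
* test each `H_J` with a weighted Bonferroni, weighted parametric
  (Dunnett-type, exploiting the known correlation
  `corr(Z_i, Z_j) = √(λ_i λ_j)`, `λ_i = n_i/(n_i+n_0)` of
  shared-control comparisons), or mixed test, depending on which
  correlations are known;
* run a two-stage adaptive design with O'Brien-Fleming-type error
  spending at an interim analysis, early rejection, and *data-dependent*
  selection of hypotheses, re-weighting of the graph, and sample-size
  reassessment, via either of two level-preserving principles:
  * the **inverse-normal p-value combination** test
    `C(p₁, p₍₂₎) = 1 − Φ{ν₁Φ⁻¹(1−p₁) + ν₂Φ⁻¹(1−p₍₂₎)}` with
    prespecified `(α₁, α₂)` solving the two-stage level condition, or
  * the **conditional error rate (CER/PCER)** method: preplanned
    two-look group-sequential boundaries per intersection, and adapted
    stage-two constants solving
    `P(adapted test rejects | stage-one data) = B_J(χ₁)`;
* estimate operating characteristics (disjunctive power, conjunctive
  power, FWER) by simulation under arm-dropping rules with subject
  reallocation.

## Worked example

A trial compares a high dose (`H1` primary, `H3` secondary endpoint)
and a low dose (`H2`, `H4`) with a shared control, 70 subjects per arm,
interim at 50% information:

```r
library(adagraph)
design <- two_stage_design(schizophrenia_graph(),
                           corr_structure(list(1:2, 3:4), rep(sqrt(0.5), 4)),
                           alpha = 0.025, t = 0.5)
design
#> Two-stage adaptive graph-based design
#>   hypotheses: 4 (H1, H2, H3, H4)
#>   one-sided alpha = 0.025, information fraction t = 0.5
#>   stage-one spent level alpha1 = 0.001525
#>   combination stage-two level alpha2 = 0.024500
#>   combination weights nu = (0.7071, 0.7071)
```

`alpha1 = 0.001525` is the error spent at the interim; any intersection
whose stage-one adjusted p-value falls at or below it is rejected
early.  `alpha2 = 0.0245` is the level applied to the combined p-value
at the final analysis.

```r
p1 <- c(H1 = 0.00045, H2 = 0.0952, H3 = 0.0225, H4 = 0.1104)
interim <- combo_interim(design, p1)
interim
#> Interim closed test (combination method)
#>   spent level alpha1 = 0.001525
#>   intersections rejected at stage one: 8 of 15
#>   early-rejected elementary hypotheses: H1
```

All eight intersections containing `H1` have adjusted p-values below
0.001525 (the global one is 0.00088), so `H1` is rejected at the
interim.  The trial continues with `H2, H3, H4`; incremental stage-two
p-values are combined with the stage-one ones:

```r
fin <- combo_final(interim, adaptation_plan(design, select = 2:4),
                   c(H2 = 0.1121, H3 = 0.0112, H4 = 0.1153))
fin
#> Final closed test (combination method)
#>   rejected elementary hypotheses: H1, H3
```

Every intersection containing `H3` has combined p-value at or below
0.0245 (for the pair `{H3,H4}` it is 0.0038), so the closed test also
rejects `H3` — the secondary endpoint claim for the high dose.

The CER route (`cer_boundaries()`, `cer_interim()`, `cer_adapt()`,
`cer_final()`) supports the same adaptations through conditional error
rates; the methods vignette
(`vignettes/adaptive-graph-testing.Rmd`) walks through both, including
dropping an arm with reallocation of its remaining subjects and
re-weighting the survivors.

Operating characteristics of a four-arm, two-endpoint design:

```r
sc <- scenario_spec(delta = c(0.4, 0, 0, 0), rho = 0.5, rule = "conservative")
simulate_oc(sc, method = "cer", m1 = 400, m2 = 20, seed = 1)
```

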