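---
title: "Graph-based adaptive two-stage closed testing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based adaptive two-stage closed testing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adagraph)
```

## The testing problem

A confirmatory trial compares one or more treatment arms with a shared
control on several endpoints.  Each treatment-endpoint combination
contributes a one-sided elementary null hypothesis $H_j:\delta_j = 0$
against $\delta_j > 0$, and the familywise error rate (FWER) must be
strongly controlled at a one-sided level $\alpha$: the probability of
rejecting any true null may not exceed $\alpha$ under *any*
configuration of true and false nulls.  Strong control is obtained by
closed testing: the elementary hypothesis $H_i$ is rejected only if
every intersection hypothesis $H_J = \cap_{j \in J} H_j$ with $i \in J$
is rejected by a local level-$\alpha$ test.

### Graphical weighting strategies

With $k$ hypotheses there are $k \cdot 2^{k-1}$ weights
$w_{j,J}$ to assign across the closure.  `adagraph` specifies them
through a weighted directed graph (`mcp_graph()`): nodal weights
express the initial priorities, and the transition matrix
$G = (g_{ij})$ states which fraction of a removed node's weight flows
to each neighbour.  Removing node $i$ (`remove_node()`) updates

$$w_j \leftarrow w_j + w_i\, g_{ij}, \qquad
  g_{jl} \leftarrow \frac{g_{jl} + g_{ji} g_{il}}{1 - g_{ji} g_{ij}},$$

and iterating the removal over $I \setminus J$ yields $\{w_{j,J}\}$ for
every $J$ (`closure_weights()`); the result does not depend on the
removal order, which the test suite verifies by exhaustive permutation.
When the update denominator $1 - g_{ji}g_{ij}$ vanishes — the two nodes
passed all their weight to each other and both are being removed — the
reconnected edge weight is set to zero.  This is the conventional
choice; it can leave a closure entry with weight sum below one (the
weight trapped in the two-node cycle is forfeited), which remains a
valid, if conservative, weighting.

### Local tests: nonparametric, parametric, mixed

How an intersection $H_J$ is tested depends on what is known about the
joint distribution of the test statistics.  Comparisons of several
treatments against the *same* control on the *same* endpoint have z
statistics with known one-factor ("Dunnett") correlation
$\mathrm{corr}(Z_i, Z_j) = \sqrt{\lambda_i\lambda_j}$,
$\lambda_i = n_i/(n_i + n_0)$.  Correlations across endpoints involve
the unknown between-endpoint correlation and are treated as unknown.
`corr_structure()` records this knowledge as a partition of the
hypotheses into blocks with per-hypothesis factor loadings.

For a subset $J$ with weights $w_{j,J}$ (zero-weight components are
dropped throughout) the stage-wise adjusted p-value is

* **nonparametric** (`bonferroni_adjusted()`):
  $\min(1, \min_j p_j / w_{j,J})$;
* **parametric** (`parametric_adjusted()`):
  $P_{H_J}(\min_j P_j/w_{j,J} \le \min_j p_j/w_{j,J})$, an exact
  multivariate normal union probability;
* **mixed** (`mixed_adjusted()`): per block $J_h$, the parametric union
  probability divided by the block weight sum
  $\sum_{j \in J_h} w_{j,J}$, minimised over blocks and capped at one.

The mixed form contains the other two as special cases (all-singleton
blocks, respectively one block with weight sum one), and on identical
inputs the three are ordered parametric $\le$ mixed $\le$ Bonferroni.

## Two-stage adaptive procedures

Both procedures spend part of $\alpha$ at an unblinded interim analysis
at information fraction $t$ using the Lan-DeMets O'Brien-Fleming-type
function $g(t,\alpha) = 2 - 2\Phi(z_{\alpha/2}/\sqrt{t})$
(`spending_alpha1()`), allow early rejection of intersections, and then
permit data-dependent selection of the hypotheses carried forward,
re-weighting of the graph, and sample-size reassessment — without
prespecifying the adaptation rule.

After the interim, the intersections still open split into three
groups (`partition_open()`): subsets of the selected set $I_2$ (full
stage-two data), subsets of the de-selected hypotheses (no stage-two
data; these can no longer be rejected), and straddlers, which are
tested through their selected part.

### The p-value combination method

For each $H_J$ a combination test is prespecified: reject at stage one
if $p_{J,1} \le \alpha_1$, otherwise reject at the final analysis if
the inverse-normal combination

$$C(p_{J,1}, p_{J,(2)}) =
  1 - \Phi\{\nu_1 \Phi^{-1}(1-p_{J,1}) + \nu_2 \Phi^{-1}(1-p_{J,(2)})\}$$

falls at or below $\alpha_2$, where $(\alpha_1,\alpha_2)$ satisfy the
two-stage level condition solved by `solve_alpha2()` via bivariate
normal integration.  The combination weights default to
$(\sqrt{t}, \sqrt{1-t})$ and are never changed after an adaptation —
this is what makes the level exact for arbitrary data-dependent
adaptations, because the incremental stage-two adjusted p-value (with
the *adapted* weights, from the post-adaptation design) is
conditionally super-uniform.  The workflow is
`combo_interim()` → `adaptation_plan()` → `combo_final()`.

### The conditional error rate method

Here each $H_J$ gets a preplanned two-look group-sequential test with
critical constants $(c_{J,1}, c_{J,2})$: component $j$ crosses at stage
one if $p_{j,1} \le w_{j,J}\,c_{J,1}$ and at the final analysis if its
cumulative p-value $p_{j,2} = 1 - \Phi\{\sqrt{t}\,z_{p_{j,1}} +
\sqrt{1-t}\,z_{p_{j,(2)}}\}$ satisfies $p_{j,2} \le w_{j,J}\,c_{J,2}$.
The constants solve the stage-one and two-look level equations
(`cer_boundaries()`); within blocks these are exact multivariate normal
probabilities over the stage-one and cumulative z statistics (stage
correlation $\sqrt{t}$ within a hypothesis, one-factor correlation
across), across blocks the block probabilities are summed
(a conservative union bound).

Given the stage-one data, `cer_interim()` computes for every open $J$
the conditional probability $B_J$ that the preplanned test would
reject at stage two — an exact conditional error rate (CER) within a
known-correlation block, a sum of partial conditional error rates
(PCER) across blocks.  Any adapted stage-two test keeps the level as
long as its conditional rejection probability does not exceed $B_J$;
`cer_adapt()` solves the corresponding equality for the adapted
constant $\tilde c_{J,2}$ using the adapted weights, per-hypothesis
information fractions $\tilde t_j$ (from `information_fraction()` on
the realised allocations) and adapted incremental correlations.  A sum
$B_J \ge 1$ (possible only in the nonparametric/mixed regimes) makes
the constraint vacuous and $H_J$ is rejected outright.  With no
adaptation, $\tilde c_{J,2} = c_{J,2}$ exactly — the preplanned test is
always admissible, which the tests verify numerically.

## Worked example

The bundled two-dose, two-endpoint design (high/low dose versus shared
control; primary and secondary endpoint per dose) illustrates both
procedures end to end:

```{r example}
design <- two_stage_design(schizophrenia_graph(),
                           corr_structure(list(1:2, 3:4),
                                          rep(sqrt(0.5), 4)),
                           alpha = 0.025, t = 0.5)
design
p1 <- c(H1 = 0.00045, H2 = 0.0952, H3 = 0.0225, H4 = 0.1104)
interim <- combo_interim(design, p1)
interim
fin <- combo_final(interim, adaptation_plan(design, select = 2:4),
                   c(H2 = 0.1121, H3 = 0.0112, H4 = 0.1153))
fin
```

The CER route on the same data (`cer_boundaries()`, `cer_interim()`,
then dropping `H3`, reallocating its remaining subjects — adapted
information fraction 0.4 — and reweighting the survivors as
co-primaries) rejects `H2` and `H4` in addition to the early rejection
of `H1`.

## The trial simulator

`simulate_oc()` estimates disjunctive power (reject at least one false
null), conjunctive power (reject all false nulls) and the FWER for a
four-arm, two-endpoint trial: 100 subjects per arm, interim at 50%
enrolment, per-arm bivariate normal endpoints with standard deviation
1 and endpoint correlation $\rho$, one-sided pooled-variance t-tests,
and the graph of `multiarm_graph()` (equal initial weight on the four
primaries; 3/4 of a rejected primary's weight to its own secondary).

Choices the simulator fixes, and why:

* **Arm dropping** uses the stage-one *primary* marginal p-values with
  threshold rules (conservative $p \ge 0.75$, normal $\ge 0.5$,
  aggressive $\ge 0.25$, ultra: keep the single best arm, ties to the
  lowest index).
* **Reallocation**: the planned stage-two subjects of dropped arms are
  split equally over all continuing groups including control, integer
  remainder to control.  This reproduces the worked example's 52/53
  split when one of three arms is dropped and keeps the allocation
  near-balanced; other conventions would change the realised
  $\tilde t_j$ only slightly.
* **t-test p-values** feed the normal-theory machinery unchanged; with
  48-98 degrees of freedom per comparison the normal approximation
  error is far below Monte-Carlo resolution.
* **Conjunctive power** is reported as undefined for the ultra rule,
  under which all but one arm is dropped by construction.
* **CER runs** use a two-phase scheme — `m1` stage-one draws, each
  followed by `m2` stage-two draws sharing the (expensive) adapted
  boundary tables — and report the conservative standard error
  $\sqrt{\hat p(1-\hat p)/m_1}$.
* **Reproducibility**: one RNG stream per run, seeded by the `seed`
  argument; identical inputs give identical estimates.

At desk scale the package's checks run the combination method at
10,000 replicates (global-null FWER, Monte-Carlo standard error about
0.1 percentage points) and the CER method at 400 × 20 two-phase
replicates (power ordering); full-precision published tables used
500,000 replicates, which the reduced runs track within Monte-Carlo
error.

## Numerical choices

* Bivariate normal rectangle probabilities use the tetrachoric
  single-integral form with a 24-point Gauss-Legendre rule for
  $|\rho| \le 0.925$ (absolute error $\sim 10^{-14}$) and fall back to
  `mvtnorm`'s deterministic TVPACK code beyond.
* One-factor block probabilities condition on the shared control
  factor and use a 48-point Gauss-Hermite rule (32/20 points in the
  vectorised simulation engine, verified against the scalar routines
  to $10^{-8}$).  Two-look block probabilities condition on both
  stages' control factors, giving a product of bivariate CDFs under a
  two-dimensional rule.
* General correlation matrices (beyond one-factor blocks) are handled
  by `mvtnorm::pmvnorm` — deterministic algorithms up to dimension 3,
  seeded quasi-Monte-Carlo above, so repeated calls agree exactly.
* All level and boundary equations are monotone in their constant;
  roots are bracketed on the p-value scale in $[10^{-12}, 1]$ and
  solved to $10^{-10}$ (`solve_monotone()`), or by fixed-depth
  simultaneous bisection across subsets inside the simulator.
* Marginal p-values of exactly 0 or 1 are clamped to
  $[10^{-15}, 1-10^{-15}]$ before probit transformation.
* All rejection comparisons are non-strict ($\le$).

## Scope and limitations

* Two stages only; no futility boundaries, confidence intervals or
  post-adaptation estimation.
* Parametric blocks must carry the one-factor shared-control structure
  for design-level computations; the standalone adjusted-p functions
  accept arbitrary correlation matrices.
* The simulator emulates normally distributed endpoints with common
  known variance structure and equal primary/secondary effect sizes;
  real trials with delayed or non-normal outcomes, unequal variances or
  informative dropout are outside what a passing test suite
  demonstrates.
* Epsilon-edge and entangled graphs are not supported.
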