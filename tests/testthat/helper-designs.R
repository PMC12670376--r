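# Shared fixtures, built in code.

# absolute-tolerance comparison (testthat's tolerance is relative)
expect_near <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}

# Two-dose two-endpoint design: H1/H2 dose-level primaries (one block,
# balanced Dunnett correlation 0.5), H3/H4 the secondaries (second block).
schizo_design <- function() {
  two_stage_design(schizophrenia_graph(),
                   corr_structure(list(1:2, 3:4), rep(sqrt(0.5), 4)))
}

schizo_p1 <- c(H1 = 0.00045, H2 = 0.0952, H3 = 0.0225, H4 = 0.1104)
schizo_p2_combo <- c(H2 = 0.1121, H3 = 0.0112, H4 = 0.1153)
schizo_p2_cer <- c(H2 = 0.0299, H4 = 0.0586)

# Adapted stage-two graph of the worked example: reweight the three
# continuing hypotheses to (0.5, 0.25, 0.25), edges inherited from the
# reduced preplanned graph.
adapted_graph_234 <- function() {
  mcp_graph(c(H2 = 0.5, H3 = 0.25, H4 = 0.25),
            rbind(c(0, 1 / 3, 2 / 3),
                  c(1, 0, 0),
                  c(0.5, 0.5, 0)))
}

# Co-primary graph on the two selected hypotheses of the CER example.
adapted_graph_24 <- function() {
  mcp_graph(c(H2 = 0.5, H4 = 0.5), rbind(c(0, 1), c(1, 0)))
}

# Random exhaustive graph (weight sum 1, all transition rows sum to 1).
random_graph <- function(k, seed) {
  set.seed(seed)
  w <- rgamma(k, 1); w <- w / sum(w)
  G <- matrix(0, k, k)
  for (i in seq_len(k)) {
    r <- rgamma(k - 1, 1)
    G[i, -i] <- r / sum(r)
  }
  mcp_graph(w, G)
}

# Stage-wise null p-values with the design's one-factor block structure.
null_pvalues <- function(design, stage = 1) {
  b <- if (stage == 1) design$corr$loadings1 else design$corr$loadings2
  k <- design$k
  z <- numeric(k)
  for (bl in design$corr$blocks) {
    z0 <- rnorm(1)
    z[bl] <- sqrt(1 - b[bl]^2) * rnorm(length(bl)) - b[bl] * z0
  }
  1 - pnorm(z)
}
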