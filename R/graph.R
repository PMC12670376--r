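# Graph-based weighting strategies for closed testing.
#
# A weighting strategy is a directed graph: one node per elementary
# hypothesis carrying a nonnegative weight, and a transition matrix whose
# entry g[i, j] is the fraction of node i's weight handed to node j when
# node i is removed (because H_i was rejected, or because the weights of
# an intersection hypothesis not containing i are being extracted).
# Iterated node removal induces the weights w_{j,J} of every intersection
# hypothesis H_J in the closure of the elementary hypotheses.

#' Construct a graphical weighting strategy
#'
#' @param weights Nonnegative nodal weights, one per hypothesis, with
#'   `sum(weights) <= 1`.  Names, if present, become hypothesis labels.
#' @param transition Square transition matrix `g` with `g[i, j] >= 0`,
#'   zero diagonal and row sums at most 1.
#' @param labels Hypothesis labels; defaults to names of `weights` or
#'   `H1, H2, ...`.
#' @return An object of class `"mcp_graph"`.
#' @examples
#' g <- mcp_graph(
#'   weights = c(H1 = 0.5, H2 = 0.5, H3 = 0, H4 = 0),
#'   transition = rbind(c(0, .5, .5, 0), c(.5, 0, 0, .5),
#'                      c(0, 1, 0, 0),   c(1, 0, 0, 0)))
#' remove_node(g, "H1")
#' @export
mcp_graph <- function(weights, transition, labels = NULL) {
  k <- length(weights)
  transition <- as.matrix(transition)
  if (is.null(labels)) {
    labels <- names(weights)
    if (is.null(labels)) labels <- paste0("H", seq_len(k))
  }
  stopifnot(length(labels) == k, nrow(transition) == k, ncol(transition) == k)
  weights <- unname(as.numeric(weights))
  if (any(weights < -1e-12)) stop("nodal weights must be nonnegative")
  if (sum(weights) > 1 + 1e-9) stop("nodal weights must sum to at most 1")
  if (any(transition < -1e-12)) stop("transition weights must be nonnegative")
  if (any(abs(diag(transition)) > 1e-12)) stop("transition diagonal must be zero")
  if (any(rowSums(transition) > 1 + 1e-9))
    stop("transition row sums must be at most 1")
  dimnames(transition) <- list(labels, labels)
  structure(list(labels = labels, weights = stats::setNames(weights, labels),
                 transition = transition),
            class = "mcp_graph")
}

#' @export
print.mcp_graph <- function(x, ...) {
  cat("Graphical weighting strategy with", length(x$labels), "hypotheses\n")
  cat("weights:\n")
  print(round(x$weights, 6))
  cat("transition matrix:\n")
  print(round(x$transition, 6))
  invisible(x)
}

.graph_label_index <- function(graph, i) {
  if (is.character(i)) {
    idx <- match(i, graph$labels)
    if (anyNA(idx)) stop("unknown hypothesis label: ", i[is.na(idx)][1])
    idx
  } else {
    i <- as.integer(i)
    if (any(i < 1L | i > length(graph$labels)))
      stop("hypothesis index out of range")
    i
  }
}

#' Remove a node and propagate its weight
#'
#' Removes hypothesis `i` from the graph, adds `w_i * g[i, j]` to every
#' remaining nodal weight and reconnects the loose edges through
#' `g'[j, l] = (g[j, l] + g[j, i] g[i, l]) / (1 - g[j, i] g[i, j])`.
#' When the denominator vanishes (the two nodes exchanged all their
#' weight) the new edge weight is set to zero.  The input graph is not
#' modified.
#'
#' @param graph An [mcp_graph()].
#' @param i Label or index of the node to remove.
#' @return The reduced `"mcp_graph"`.
#' @export
remove_node <- function(graph, i) {
  stopifnot(inherits(graph, "mcp_graph"))
  ii <- .graph_label_index(graph, i)
  stopifnot(length(ii) == 1L)
  keep <- setdiff(seq_along(graph$labels), ii)
  g <- graph$transition
  w <- graph$weights
  new_w <- w[keep] + w[ii] * g[ii, keep]
  m <- length(keep)
  new_g <- matrix(0, m, m)
  for (a in seq_len(m)) {
    j <- keep[a]
    den <- 1 - g[j, ii] * g[ii, j]
    for (b in seq_len(m)) {
      l <- keep[b]
      if (l == j) next
      new_g[a, b] <- if (den <= 1e-14) 0 else
        (g[j, l] + g[j, ii] * g[ii, l]) / den
    }
  }
  mcp_graph(new_w, new_g, labels = graph$labels[keep])
}

#' Weights of all intersection hypotheses implied by a graph
#'
#' For every nonempty subset J of the hypothesis index set, removes the
#' nodes outside J one at a time (the result is independent of the
#' removal order) and records the resulting nodal weights
#' \eqn{\{w_{j,J}, j \in J\}}.
#'
#' @param graph An [mcp_graph()].
#' @return An object of class `"weight_table"`: a list with `labels` and
#'   a `(2^k - 1) x k` matrix `W` of weights, rows indexed by the subset
#'   bitmask (row `m` holds subset `{j : bitwAnd(m, 2^(j-1)) != 0}`);
#'   entries for hypotheses outside the subset are `NA`.
#' @examples
#' g <- mcp_graph(c(.5, .5, 0, 0),
#'                rbind(c(0, .5, .5, 0), c(.5, 0, 0, .5),
#'                      c(0, 1, 0, 0),   c(1, 0, 0, 0)))
#' wt <- closure_weights(g)
#' subset_weights(wt, c(1, 4))   # 0.75, 0.25
#' @export
closure_weights <- function(graph) {
  stopifnot(inherits(graph, "mcp_graph"))
  k <- length(graph$labels)
  if (k > 16L) stop("closure enumeration limited to 16 hypotheses")
  S <- bitwShiftL(1L, k) - 1L
  W <- matrix(NA_real_, S, k, dimnames = list(NULL, graph$labels))
  full <- S
  W[full, ] <- graph$weights
  # Memoised depth-first removal: the graph for subset J is obtained from
  # the graph of any superset J + {i} by removing node i.
  graphs <- vector("list", S)
  graphs[[full]] <- graph
  for (m in rev(seq_len(S - 1L))) {
    # find a hypothesis not in m, reuse the stored superset graph
    absent <- which(bitwAnd(m, bitwShiftL(1L, 0:(k - 1L))) == 0L)[1L]
    sup <- bitwOr(m, bitwShiftL(1L, absent - 1L))
    gsup <- graphs[[sup]]
    gm <- remove_node(gsup, graph$labels[absent])
    graphs[[m]] <- gm
    members <- which(bitwAnd(m, bitwShiftL(1L, 0:(k - 1L))) != 0L)
    W[m, members] <- gm$weights[match(graph$labels[members], gm$labels)]
  }
  structure(list(labels = graph$labels, W = W), class = "weight_table")
}

subset_mask <- function(members, k) {
  m <- 0L
  for (j in members) m <- bitwOr(m, bitwShiftL(1L, as.integer(j) - 1L))
  m
}

mask_members <- function(mask, k) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) != 0L)
}

#' Look up the weights of one intersection hypothesis
#'
#' @param wt A `"weight_table"` from [closure_weights()].
#' @param J Subset, given as labels or indices.
#' @return Named weight vector for the members of `J`.
#' @export
subset_weights <- function(wt, J) {
  stopifnot(inherits(wt, "weight_table"))
  k <- length(wt$labels)
  if (is.character(J)) J <- match(J, wt$labels)
  stopifnot(!anyNA(J), all(J >= 1), all(J <= k))
  m <- subset_mask(J, k)
  w <- wt$W[m, sort(unique(as.integer(J)))]
  stats::setNames(w, wt$labels[sort(unique(as.integer(J)))])
}

#' @export
print.weight_table <- function(x, ...) {
  k <- length(x$labels)
  cat("Closure weight table:", nrow(x$W), "intersection hypotheses over",
      k, "elementary hypotheses\n")
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x$W) > 10L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.weight_table <- function(x, ...) {
  k <- length(x$labels)
  rows <- lapply(seq_len(nrow(x$W)), function(m) {
    members <- mask_members(m, k)
    data.frame(subset = paste(x$labels[members], collapse = ","),
               label = x$labels[members],
               weight = x$W[m, members],
               row.names = NULL)
  })
  do.call(rbind, rows[order(-vapply(seq_len(nrow(x$W)), function(m)
    length(mask_members(m, k)), 1L))])
}
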