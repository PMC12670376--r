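# Configuration, serialisation and bundled worked-example fixtures.

#' Read and write graphical strategies as YAML
#'
#' The YAML layout has three fields: `labels` (ordered hypothesis
#' labels), `weights` (nodal weights in the same order) and `transition`
#' (list of rows of the transition matrix).
#'
#' @param path File path.
#' @param graph An [mcp_graph()] (for writing).
#' @return `read_graph_yaml()` returns an [mcp_graph()];
#'   `write_graph_yaml()` returns `path` invisibly.
#' @export
read_graph_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  mcp_graph(as.numeric(y$weights),
            do.call(rbind, lapply(y$transition, as.numeric)),
            labels = as.character(y$labels))
}

#' @rdname read_graph_yaml
#' @export
write_graph_yaml <- function(graph, path) {
  stopifnot(inherits(graph, "mcp_graph"))
  yaml::write_yaml(list(labels = graph$labels,
                        weights = unname(as.numeric(graph$weights)),
                        transition = lapply(seq_len(nrow(graph$transition)),
                                            function(i)
                                              unname(graph$transition[i, ]))),
                   path)
  invisible(path)
}

#' Read marginal p-values from CSV
#'
#' Expects columns `label` and `p` (and optionally `stage`).
#'
#' @param path CSV file path.
#' @param stage If the file has a `stage` column, which stage to keep.
#' @return Named numeric vector of p-values.
#' @export
read_pvalues_csv <- function(path, stage = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "p") %in% names(df)))
    stop("p-value CSV needs columns 'label' and 'p'")
  if (!is.null(stage) && "stage" %in% names(df))
    df <- df[df$stage == stage, , drop = FALSE]
  if (any(df$p < 0 | df$p > 1)) stop("p-values must lie in [0, 1]")
  stats::setNames(df$p, df$label)
}

#' Export a closure weight table as CSV
#'
#' Columns: `subset`, `label`, `weight`.
#'
#' @param wt A `"weight_table"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_table_csv <- function(wt, path) {
  utils::write.csv(as.data.frame(wt), path, row.names = FALSE)
  invisible(path)
}

#' Serialise an interim state for audit
#'
#' Writes the stage-one p-values, the per-intersection results and the
#' derived index sets to JSON so that the final analysis can be re-run
#' without recomputing the interim.
#'
#' @param interim A `"combo_interim"` or `"cer_interim"` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_interim_json <- function(interim, path) {
  design <- interim$design
  state <- list(
    method = if (inherits(interim, "combo_interim")) "combo" else "cer",
    labels = design$labels,
    alpha = design$alpha, t = design$t,
    alpha1 = design$alpha1,
    p1 = unname(interim$p1),
    rejected_masks = which(interim$rejected1),
    early_rejected = design$labels[interim$I1r],
    continuing = design$labels[interim$I1star])
  if (!is.null(interim$B)) state$B <- unname(interim$B)
  if (!is.null(interim$pJ1)) state$pJ1 <- unname(interim$pJ1)
  jsonlite::write_json(state, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load an analysis configuration
#'
#' Reads a YAML (or JSON) configuration with a `design` block (`alpha`,
#' `t`, optional `nu`, `graph` given inline or as a file path, `blocks`,
#' `loadings1`/`loadings2`) and optional `stage1`/`stage2` p-value CSV
#' paths, validating all invariants.
#'
#' @param path Configuration file path.
#' @return List with the constructed [two_stage_design()] and any
#'   p-value vectors referenced by the configuration.
#' @export
load_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  d <- cfg$design
  if (is.null(d)) stop("configuration must contain a 'design' block")
  graph <- if (is.character(d$graph))
    read_graph_yaml(file.path(dirname(path), d$graph))
  else mcp_graph(as.numeric(d$graph$weights),
                 do.call(rbind, lapply(d$graph$transition, as.numeric)),
                 labels = as.character(d$graph$labels))
  k <- length(graph$labels)
  corr <- NULL
  if (!is.null(d$blocks)) {
    l1 <- as.numeric(d$loadings1 %||% rep(sqrt(0.5), k))
    l2 <- as.numeric(d$loadings2 %||% l1)
    blocks <- lapply(d$blocks, function(b)
      if (is.character(b)) match(b, graph$labels) else as.integer(b))
    corr <- corr_structure(blocks, l1, l2)
  }
  nu <- if (is.null(d$nu)) c(sqrt(d$t), sqrt(1 - d$t)) else as.numeric(d$nu)
  if (abs(sum(nu^2) - 1) > 1e-8)
    stop("configuration error: nu1^2 + nu2^2 must equal 1")
  design <- two_stage_design(graph, corr, alpha = d$alpha %||% 0.025,
                             t = d$t %||% 0.5, nu = nu)
  out <- list(design = design, config = cfg)
  for (st in c("stage1", "stage2")) {
    if (!is.null(cfg[[st]]))
      out[[st]] <- read_pvalues_csv(file.path(dirname(path), cfg[[st]]))
  }
  out
}

#' Write the bundled worked-example fixtures
#'
#' Emits ready-to-run input files for the two-dose two-endpoint
#' schizophrenia-trial example (`"schizophrenia_combo"`,
#' `"schizophrenia_cer"`) or the four-arm two-endpoint simulation design
#' (`"fourarm_sim"`): the design YAML plus stage-wise p-value CSVs.
#'
#' @param name Fixture name.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
make_fixtures <- function(name = c("schizophrenia_combo",
                                   "schizophrenia_cer", "fourarm_sim"),
                          dir = ".") {
  name <- match.arg(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(fn) { files <<- c(files, fn); fn }
  if (name %in% c("schizophrenia_combo", "schizophrenia_cer")) {
    g <- schizophrenia_graph()
    write_graph_yaml(g, put(file.path(dir, "graph.yaml")))
    utils::write.csv(
      data.frame(label = g$labels, stage = 1L,
                 p = c(0.00045, 0.0952, 0.0225, 0.1104)),
      put(file.path(dir, "stage1.csv")), row.names = FALSE)
    if (name == "schizophrenia_combo") {
      utils::write.csv(
        data.frame(label = c("H2", "H3", "H4"), stage = 2L,
                   p = c(0.1121, 0.0112, 0.1153)),
        put(file.path(dir, "stage2.csv")), row.names = FALSE)
    } else {
      utils::write.csv(
        data.frame(label = c("H2", "H4"), stage = 2L,
                   p = c(0.0299, 0.0586)),
        put(file.path(dir, "stage2.csv")), row.names = FALSE)
    }
    yaml::write_yaml(list(design = list(graph = "graph.yaml", alpha = 0.025,
                                        t = 0.5,
                                        blocks = list(c("H1", "H2"),
                                                      c("H3", "H4"))),
                          stage1 = "stage1.csv", stage2 = "stage2.csv"),
                     put(file.path(dir, "config.yaml")))
  } else {
    write_graph_yaml(multiarm_graph(4L), put(file.path(dir, "graph.yaml")))
    yaml::write_yaml(list(design = list(graph = "graph.yaml", alpha = 0.025,
                                        t = 0.5,
                                        blocks = list(paste0("P", 1:4),
                                                      paste0("S", 1:4)))),
                     put(file.path(dir, "config.yaml")))
  }
  files
}

#' Worked-example graph: two doses, two endpoints
#'
#' The weighting strategy of a trial comparing a high and a low dose
#' with a shared control on a primary and a secondary endpoint:
#' `H1`/`H2` are the dose-level primary hypotheses (weight 1/2 each),
#' `H3`/`H4` the corresponding secondary hypotheses (weight 0).  Half of
#' a rejected primary's weight moves to its own secondary, half to the
#' other primary; a rejected secondary passes its weight to the other
#' dose's primary.
#'
#' @return An [mcp_graph()].
#' @export
schizophrenia_graph <- function() {
  mcp_graph(c(H1 = 0.5, H2 = 0.5, H3 = 0, H4 = 0),
            rbind(c(0, 0.5, 0.5, 0),
                  c(0.5, 0, 0, 0.5),
                  c(0, 1, 0, 0),
                  c(1, 0, 0, 0)))
}
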