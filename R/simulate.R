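#' Default construct-effect matrix of the generator
#'
#' Signed multipliers of \code{effect_size} for each planted gene group
#' (rows) under each non-control condition (columns). The default encodes
#' the qualitative structure of the construct panel: DUX4 and the
#' constitutively active tMALDUX4-VP16 share sign on DUX4-target groups
#' while the dominant-negative tMALDUX4-ERD is inverted on them; tMALDUX4
#' and DUX4c share sign on DUX4c-target groups and on the shared groups;
#' partial-overlap entries (DUX4's echo of DUX4c targets) are 0.5.
#'
#' @return Numeric matrix, 6 groups x 5 conditions.
#' @export
defaultEffectMatrix <- function() {
  conds <- setdiff(duxConditions(), "control")
  groups <- c("dux4_up", "dux4_down", "dux4c_up", "dux4c_down",
              "shared_up", "shared_down")
  m <- matrix(0, length(groups), length(conds),
              dimnames = list(groups, conds))
  m["dux4_up", ]     <- c( 1,  0,  1, -1,  0)
  m["dux4_down", ]   <- c(-1,  0, -1,  1,  0)
  m["dux4c_up", ]    <- c( 0.5,  1,  0.5, 0,  1)
  m["dux4c_down", ]  <- c(-0.5, -1, -0.5, 0, -1)
  m["shared_up", ]   <- c( 1,  1,  1, -1,  1)
  m["shared_down", ] <- c(-1, -1, -1,  1, -1)
  m
}

# BFS 2-colouring bipartiteness check (works on any simple undirected
# graph, named or not).
.isBipartite <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) return(TRUE)
  adj <- lapply(igraph::adjacent_vertices(g, seq_len(n)), as.integer)
  color <- rep(NA_integer_, n)
  for (start in seq_len(n)) {
    if (!is.na(color[start])) next
    color[start] <- 0L
    queue <- start
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(color[w])) {
          color[w] <- 1L - color[v]
          queue <- c(queue, w)
        } else if (color[w] == color[v]) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' Default planted group sizes for a given universe size
#'
#' 300/350 DUX4 up/down targets, 300/300 DUX4c targets and 100/100 shared
#' targets per 25,000 genes (the scale of a whole-transcriptome array),
#' scaled proportionally for other universe sizes.
#'
#' @param n_genes universe size.
#' @return Named integer vector of the six group sizes.
#' @export
defaultGroupSizes <- function(n_genes = 25000L) {
  base <- c(dux4_up = 300, dux4_down = 350, dux4c_up = 300,
            dux4c_down = 300, shared_up = 100, shared_down = 100)
  setNames(as.integer(round(base * n_genes / 25000)), names(base))
}

#' Configuration of the synthetic expression experiment
#'
#' Describes the simulated design: 6 conditions (control + 5 constructs) x
#' \code{n_replicates} animals, with planted gene groups whose log-scale
#' expression is shifted per condition according to
#' \code{construct_effect_matrix}. Defaults emulate the study design the
#' package targets: 3 replicates, an array-scale universe of 25,000 genes,
#' 300/350 planted DUX4 up/down targets, Gaussian log-scale noise of SD 1
#' and planted shifts of 3 noise-SD units.
#'
#' @param n_genes total number of genes.
#' @param n_replicates replicates per condition (>= 2).
#' @param baseline_mean,baseline_sd mean and gene-to-gene SD of the baseline
#'   log expression.
#' @param effect_size mean log-scale shift of planted genes, in units of
#'   \code{noise_sd}.
#' @param group_sizes named integer vector with entries \code{dux4_up},
#'   \code{dux4_down}, \code{dux4c_up}, \code{dux4c_down}, \code{shared_up},
#'   \code{shared_down}; must sum to at most \code{n_genes}. The default
#'   plants 300/350 DUX4 up/down targets, 300/300 DUX4c targets and 100/100
#'   shared targets per 25,000 genes, scaled proportionally with
#'   \code{n_genes}.
#' @param construct_effect_matrix signed multiplier per (group x condition);
#'   see \code{\link{defaultEffectMatrix}}.
#' @param noise_sd SD of the per-measurement Gaussian noise (log scale).
#' @param positivity_epsilon floor applied to any non-positive simulated
#'   value so downstream entropy use is safe.
#' @param seed integer random seed.
#' @return A list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_genes = 25000L,
                             n_replicates = 3L,
                             baseline_mean = 6,
                             baseline_sd = 1,
                             effect_size = 3,
                             group_sizes = defaultGroupSizes(n_genes),
                             construct_effect_matrix = defaultEffectMatrix(),
                             noise_sd = 1,
                             positivity_epsilon = 0.01,
                             seed = 1L) {
  groups <- rownames(defaultEffectMatrix())
  gs <- setNames(rep(0L, length(groups)), groups)
  gs[names(group_sizes)] <- as.integer(group_sizes)
  if (sum(gs) > n_genes)
    stop("planted group sizes (", sum(gs), ") exceed n_genes (", n_genes, ")")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (n_replicates < 2L) stop("need n_replicates >= 2")
  stopifnot(identical(rownames(construct_effect_matrix), groups))
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 effect_size = effect_size, group_sizes = gs,
                 construct_effect_matrix = construct_effect_matrix,
                 noise_sd = noise_sd,
                 positivity_epsilon = positivity_epsilon,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a construct-panel expression experiment
#'
#' Generates a gene-by-sample matrix of log-scale expression for the six
#' conditions of the panel. Each value is
#' \code{baseline_g + effect(g, condition) + N(0, noise_sd)}, where the
#' per-gene effect is \code{effect_size} times the signed multiplier of the
#' gene's group under that condition. Non-positive values are floored at
#' \code{positivity_epsilon}. The same config (including seed) always
#' reproduces the same output.
#'
#' The ground truth is carried in the row data of the returned
#' SummarizedExperiment: the planted \code{group} label plus logical
#' columns \code{dux4_target_up/down} and \code{dux4c_target_up/down}
#' marking genes whose planted pattern makes them bona fide DUX4 (or DUX4c)
#' targets (the shared groups belong to both regulators).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A \code{SummarizedExperiment}: assay \code{"exprs"}, colData
#'   \code{sample_id}/\code{condition}/\code{replicate}, rowData the ground
#'   truth, and the config in \code{metadata(se)$config}.
#' @examples
#' se <- simulateExperiment(simulationConfig(n_genes = 500, seed = 7))
#' dim(se)  # 500 x 18
#' @export
simulateExperiment <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  conds <- duxConditions()
  nrep <- config$n_replicates
  ng <- config$n_genes
  condition <- rep(conds, each = nrep)
  replicate <- rep(seq_len(nrep), times = length(conds))
  sample_id <- paste0(gsub("-", "_", condition), "_r", replicate)

  gs <- config$group_sizes
  group <- rep(c(names(gs), "null"), times = c(gs, ng - sum(gs)))
  gene_ids <- sprintf("gene%05d", seq_len(ng))

  baseline <- rnorm(ng, config$baseline_mean, config$baseline_sd)
  em <- config$construct_effect_matrix * config$effect_size * config$noise_sd
  # per-gene, per-condition planted shift (0 for control and null genes)
  shift <- matrix(0, ng, length(conds), dimnames = list(NULL, conds))
  planted <- group != "null"
  shift[planted, colnames(em)] <- em[group[planted], , drop = FALSE]

  mat <- baseline + shift[, condition] +
    matrix(rnorm(ng * length(condition), 0, config$noise_sd), ng)
  mat[mat <= 0] <- config$positivity_epsilon
  dimnames(mat) <- list(gene_ids, sample_id)

  truth <- S4Vectors::DataFrame(
    group = group,
    dux4_target_up    = group %in% c("dux4_up", "shared_up"),
    dux4_target_down  = group %in% c("dux4_down", "shared_down"),
    dux4c_target_up   = group %in% c("dux4c_up", "shared_up"),
    dux4c_target_down = group %in% c("dux4c_down", "shared_down"),
    row.names = gene_ids)

  se <- makeDuxExperiment(mat, data.frame(sample_id = sample_id,
                                          condition = condition,
                                          replicate = replicate))
  SummarizedExperiment::rowData(se) <- truth
  S4Vectors::metadata(se)$config <- config
  se
}

#' Ground-truth signature of a simulated experiment
#'
#' Convenience accessor turning the planted row-data labels of
#' \code{\link{simulateExperiment}} into a \code{SignatureSet}.
#'
#' @param se a simulated SummarizedExperiment.
#' @param regulator \code{"DUX4"} or \code{"DUX4c"}.
#' @return A \code{\linkS4class{SignatureSet}}.
#' @export
trueSignature <- function(se, regulator = c("DUX4", "DUX4c")) {
  regulator <- match.arg(regulator)
  rd <- SummarizedExperiment::rowData(se)
  if (regulator == "DUX4")
    SignatureSet("DUX4", up = rownames(se)[rd$dux4_target_up],
                 down = rownames(se)[rd$dux4_target_down])
  else
    SignatureSet("DUX4c", up = rownames(se)[rd$dux4c_target_up],
                 down = rownames(se)[rd$dux4c_target_down])
}

#' Simulate a connected interaction network
#'
#' Draws a small-world (Watts-Strogatz) or scale-free (Barabasi-Albert)
#' graph, then enforces the properties signalling entropy needs: the graph
#' is made simple, connected (disconnected components are bridged by single
#' edges) and non-bipartite (one triangle-closing edge is added if needed).
#'
#' @param n_nodes number of nodes (>= 3).
#' @param mean_degree target mean degree (>= 2).
#' @param model \code{"small_world"} or \code{"scale_free"}.
#' @param seed integer random seed.
#' @param gene_ids optional character vector (length >= \code{n_nodes}) from
#'   which node names are taken; defaults to \code{node0001, ...}.
#' @return A simple, connected, non-bipartite \code{igraph} graph.
#' @examples
#' g <- simulateNetwork(50, 4, seed = 1)
#' igraph::is_connected(g)
#' @export
simulateNetwork <- function(n_nodes, mean_degree = 4,
                            model = c("small_world", "scale_free"),
                            seed = 1L, gene_ids = NULL) {
  model <- match.arg(model)
  if (n_nodes < 3L) stop("need n_nodes >= 3")
  if (mean_degree < 2) stop("need mean_degree >= 2")
  set.seed(as.integer(seed))
  g <- if (model == "small_world") {
    igraph::sample_smallworld(dim = 1, size = n_nodes,
                              nei = max(1L, round(mean_degree / 2)), p = 0.1)
  } else {
    igraph::sample_pa(n_nodes, m = max(1L, round(mean_degree / 2)),
                      directed = FALSE)
  }
  g <- igraph::simplify(g)
  # bridge components onto the largest one
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    giant <- which.max(comp$csize)
    anchor <- which(comp$membership == giant)[1L]
    for (k in setdiff(seq_len(comp$no), giant)) {
      g <- igraph::add_edges(g, c(anchor, which(comp$membership == k)[1L]))
    }
  }
  # force an odd cycle if the draw happens to be bipartite
  if (.isBipartite(g)) {
    u <- which(igraph::degree(g) >= 2L)[1L]
    nb <- as.integer(igraph::neighbors(g, u))
    g <- igraph::add_edges(g, nb[1:2])
    g <- igraph::simplify(g)
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("node%04d", seq_len(n_nodes))
  if (length(gene_ids) < n_nodes) stop("gene_ids shorter than n_nodes")
  igraph::V(g)$name <- gene_ids[seq_len(n_nodes)]
  g
}
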