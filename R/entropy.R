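#' Restrict a network to measured genes and keep the largest component
#'
#' Signalling entropy needs an irreducible random walk, so the interaction
#' network is reduced to the nodes with measured expression and then to its
#' maximal connected component (ties between equally large components are
#' broken by the lexicographically smallest member id). A bipartite result
#' is allowed -- irreducibility alone guarantees a unique stationary vector
#' -- but is flagged with a warning because the walk is then periodic.
#'
#' @param network simple undirected igraph graph.
#' @param measured_genes character vector of gene ids with expression.
#' @return The prepared igraph graph, with attributes
#'   \code{n_components_removed} and \code{bipartite} attached as graph
#'   attributes.
#' @export
prepareNetwork <- function(network, measured_genes) {
  keep <- igraph::V(network)$name %in% measured_genes
  g <- igraph::induced_subgraph(network, which(keep))
  comp <- igraph::components(g)
  if (comp$no >= 1L) {
    sizes <- comp$csize
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      # tie-break: component containing the lexicographically smallest id
      firsts <- vapply(best, function(k)
        min(igraph::V(g)$name[comp$membership == k]), character(1L))
      best <- best[order(firsts)][1L]
    }
    g2 <- igraph::induced_subgraph(g, which(comp$membership == best))
  } else {
    g2 <- g
  }
  if (igraph::vcount(g2) < 3L)
    stop("largest measured component has fewer than 3 nodes")
  bip <- .isBipartite(g2)
  if (bip)
    warning("prepared network is bipartite; the walk is periodic but the ",
            "stationary distribution is still unique")
  g2 <- igraph::set_graph_attr(g2, "n_components_removed", comp$no - 1L)
  igraph::set_graph_attr(g2, "bipartite", bip)
}

# Expression vector aligned to the network's nodes, with the positivity
# floor applied. Errors if any node has no expression value.
.alignExpression <- function(network, expr, epsilon = 0.01) {
  nodes <- igraph::V(network)$name
  e <- expr[nodes]
  if (anyNA(e))
    stop("expression missing for network node(s): ",
         paste(head(nodes[is.na(e)], 5L), collapse = ", "))
  n_floored <- sum(e <= 0)
  if (n_floored) {
    message(n_floored, " non-positive expression value(s) floored at ", epsilon)
    e[e <= 0] <- epsilon
  }
  e
}

#' Sample-specific mass-action stochastic matrix
#'
#' Builds the transition matrix of the random walk a sample induces on the
#' interaction network under the mass-action principle: the rate of the
#' reaction between interacting proteins i and j is proportional to the
#' product of their concentrations, for which the sample's (positive,
#' log-normalised) expression is the proxy. Row-normalising gives
#' \code{p_ij = E_j / sum(E_k, k in N(i))} for neighbours j of i and 0
#' otherwise, so each row is the interaction distribution of one protein.
#'
#' @param network prepared igraph graph (see \code{\link{prepareNetwork}}).
#' @param sample_expression named numeric vector covering all network nodes;
#'   values must be positive (non-positive values are floored at
#'   \code{epsilon} with a message).
#' @param epsilon positivity floor.
#' @return Sparse row-stochastic \code{dgCMatrix} with node names on both
#'   dimensions and support exactly the network's adjacency.
#' @examples
#' tri <- igraph::make_ring(3)
#' igraph::V(tri)$name <- c("a", "b", "c")
#' stochasticMatrix(tri, c(a = 1, b = 2, c = 3))
#' @export
stochasticMatrix <- function(network, sample_expression, epsilon = 0.01) {
  e <- .alignExpression(network, sample_expression, epsilon)
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  denom <- as.vector(A %*% e)  # sum of neighbour expression per node
  if (any(denom <= 0))
    stop("node with zero total neighbour expression; cannot normalise")
  P <- Matrix::Diagonal(x = 1 / denom) %*% A %*% Matrix::Diagonal(x = e)
  dimnames(P) <- list(igraph::V(network)$name, igraph::V(network)$name)
  methods::as(P, "CsparseMatrix")
}

#' Local signalling entropies
#'
#' Shannon entropy (natural log) of each node's transition distribution,
#' quantifying how promiscuously that protein signals in the sample:
#' \code{S_i = -sum(p_ij * log(p_ij))} over the neighbours of i. A node of
#' degree 1 has entropy 0; a uniform distribution over k neighbours attains
#' the maximum log(k).
#'
#' @param P row-stochastic sparse matrix from \code{\link{stochasticMatrix}}.
#' @param units \code{"nats"} (natural log, default) or \code{"bits"}.
#' @return Named numeric vector of per-node entropies.
#' @export
localEntropies <- function(P, units = c("nats", "bits")) {
  units <- match.arg(units)
  Pt <- methods::as(P, "TsparseMatrix")
  x <- Pt@x
  contrib <- ifelse(x > 0, -x * log(x), 0)
  s <- rep(0, nrow(P))
  agg <- tapply(contrib, Pt@i, sum)
  s[as.integer(names(agg)) + 1L] <- agg
  names(s) <- rownames(P)
  if (units == "bits") s <- s / log(2)
  s
}

#' Stationary distribution of the sample-specific walk
#'
#' The stationary distribution \code{pi} satisfies \code{pi P = pi}; it is
#' the left eigenvector of \code{P} at eigenvalue 1, unique on a connected
#' network by Perron-Frobenius. Because the mass-action edge weights
#' \code{w_ij = E_i E_j} are symmetric the walk is reversible, so \code{pi}
#' has the closed form \code{pi_i = E_i * sum(E_j, j in N(i)) / Z} -- the
#' primary computation path. A verification path confirms the closed form:
#' \code{"residual"} (default) checks \code{max|pi P - pi|} directly, while
#' \code{"eigen"} solves the left eigenproblem densely and compares the two
#' vectors; either failing beyond \code{tol} is an error.
#'
#' @inheritParams stochasticMatrix
#' @param check verification mode: \code{"residual"}, \code{"eigen"} or
#'   \code{"none"}.
#' @param tol agreement tolerance for the verification path.
#' @return Named numeric vector summing to 1 with all entries > 0.
#' @examples
#' tri <- igraph::make_ring(3)
#' igraph::V(tri)$name <- c("a", "b", "c")
#' stationaryDistribution(tri, c(a = 1, b = 2, c = 3))  # 5/22, 8/22, 9/22
#' @export
stationaryDistribution <- function(network, sample_expression,
                                   check = c("residual", "eigen", "none"),
                                   tol = 1e-8, epsilon = 0.01) {
  check <- match.arg(check)
  e <- .alignExpression(network, sample_expression, epsilon)
  A <- methods::as(igraph::as_adjacency_matrix(network, sparse = TRUE), "dMatrix")
  strength <- as.vector(A %*% e)
  pi_cf <- e * strength
  pi_cf <- pi_cf / sum(pi_cf)
  names(pi_cf) <- igraph::V(network)$name
  if (check != "none") {
    P <- stochasticMatrix(network, sample_expression, epsilon)
    if (check == "residual") {
      resid <- max(abs(as.vector(pi_cf %*% P) - pi_cf))
      if (resid > tol)
        stop("stationary distribution failed verification: |pi P - pi| = ",
             format(resid))
    } else {
      pi_eig <- .leftEigenStationary(P)
      if (max(abs(pi_eig - pi_cf)) > tol)
        stop("closed-form and eigen-solved stationary distributions disagree ",
             "beyond tolerance (", format(max(abs(pi_eig - pi_cf))), ")")
    }
  }
  pi_cf
}

# Dense left eigenvector of P at the eigenvalue closest to 1, sign-fixed to
# positive entries and renormalised to sum 1.
.leftEigenStationary <- function(P) {
  ev <- eigen(t(as.matrix(P)))
  k <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, k])
  if (sum(v) < 0) v <- -v
  v <- v / sum(v)
  setNames(v, rownames(P))
}

#' Entropy rate of the sample-specific walk
#'
#' The signalling entropy of a sample: the entropy rate
#' \code{SR = sum(pi_i * S_i)} of the stationary random walk, i.e. the
#' stationary-weighted mean of the local entropies.
#'
#' @param pi stationary distribution.
#' @param S local entropies, aligned with \code{pi}.
#' @return Scalar entropy rate (same units as \code{S}).
#' @export
entropyRate <- function(pi, S) {
  if (length(pi) != length(S)) stop("pi and S have different lengths")
  if (!is.null(names(pi)) && !is.null(names(S)) &&
      !identical(names(pi), names(S)))
    stop("pi and S are not aligned on the same node order")
  sum(pi * S)
}

#' Signalling entropy of every sample
#'
#' Prepares the network once against the matrix's gene universe, then for
#' each sample builds the mass-action stochastic matrix, its local
#' entropies and stationary distribution, and reports the entropy rate.
#'
#' @param x SummarizedExperiment or gene-by-sample matrix of positive
#'   log-normalised expression.
#' @param network undirected igraph interaction network (gene ids as node
#'   names).
#' @param units \code{"nats"} or \code{"bits"}.
#' @param normalize divide SR by the log of the spectral radius of the
#'   prepared network's adjacency matrix (the maximum attainable entropy
#'   rate for uniform weights).
#' @param check verification mode passed to
#'   \code{\link{stationaryDistribution}}.
#' @param epsilon positivity floor for expression.
#' @param diagnostics also return per-node local entropies and stationary
#'   distributions (as list columns in an attribute).
#' @return data.frame with \code{sample_id}, \code{sr},
#'   \code{n_nodes_used}, \code{n_components_removed}.
#' @examples
#' se <- simulateExperiment(simulationConfig(n_genes = 300, seed = 1))
#' g <- simulateNetwork(100, 6, seed = 2, gene_ids = rownames(se))
#' head(entropyPerSample(se, g))
#' @export
entropyPerSample <- function(x, network, units = c("nats", "bits"),
                             normalize = FALSE,
                             check = c("residual", "eigen", "none"),
                             epsilon = 0.01, diagnostics = FALSE) {
  units <- match.arg(units); check <- match.arg(check)
  mat <- exprsMatrix(x)
  if (length(intersect(rownames(mat), igraph::V(network)$name)) < 3L)
    stop("matrix and network share fewer than 3 gene ids")
  g <- prepareNetwork(network, rownames(mat))
  nodes <- igraph::V(g)$name
  norm_const <- if (normalize) {
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    lam <- max(Re(eigen(A, only.values = TRUE)$values))
    log(lam) / (if (units == "bits") log(2) else 1)
  } else 1
  diag_S <- diag_pi <- vector("list", ncol(mat))
  sr <- vapply(seq_len(ncol(mat)), function(s) {
    e <- mat[nodes, s]
    P <- stochasticMatrix(g, e, epsilon)
    S <- localEntropies(P, units)
    pi <- stationaryDistribution(g, e, check = check, epsilon = epsilon)
    if (diagnostics) {
      diag_S[[s]] <<- S; diag_pi[[s]] <<- pi
    }
    entropyRate(pi, S) / norm_const
  }, numeric(1L))
  out <- data.frame(sample_id = colnames(mat), sr = sr,
                    n_nodes_used = length(nodes),
                    n_components_removed =
                      igraph::graph_attr(g, "n_components_removed"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (diagnostics) {
    attr(out, "local_entropy") <- setNames(diag_S, colnames(mat))
    attr(out, "stationary") <- setNames(diag_pi, colnames(mat))
  }
  out
}
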