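# Independent oracles and small fixtures used across the suite. These
# deliberately avoid the package's own computation paths: loops and linear
# solves instead of vectorised closed forms.

# Brute-force Benjamini-Hochberg step-up (O(m^2) definition).
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)  # rank of p[i]
    # step-up: min over k >= r of m * p_(k) / k, capped at 1
    vals <- vapply(r:m, function(k) m * p[ord[k]] / k, numeric(1))
    adj[i] <- min(1, min(vals))
  }
  adj
}

# Brute-force Pearson correlation as a covariance ratio.
bruteCor <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Entropy-rate oracle: explicit loops over the adjacency and a dense linear
# solve for the stationary distribution (independent of the package's
# detailed-balance closed form).
oracleEntropyRate <- function(graph, expr) {
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  el <- igraph::as_edgelist(graph)
  for (k in seq_len(nrow(el))) {
    A[el[k, 1], el[k, 2]] <- 1
    A[el[k, 2], el[k, 1]] <- 1
  }
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    P[i, nb] <- expr[nodes[nb]] / sum(expr[nodes[nb]])
  }
  # solve pi (P - I) = 0 with sum(pi) = 1 via an augmented system
  M <- rbind(t(P) - diag(n), rep(1, n))
  pi <- qr.solve(M, c(rep(0, n), 1))
  S <- vapply(seq_len(n), function(i) {
    pij <- P[i, P[i, ] > 0]
    -sum(pij * log(pij))
  }, numeric(1))
  list(pi = setNames(pi, nodes), S = setNames(S, nodes),
       sr = sum(pi * S), P = P)
}

# Random connected simple graph with named nodes, for property tests.
randomConnectedGraph <- function(n, p_edge = 0.15) {
  repeat {
    g <- igraph::sample_gnp(n, p_edge)
    if (igraph::is_connected(g) && igraph::ecount(g) >= n) break
  }
  igraph::V(g)$name <- sprintf("g%03d", seq_len(n))
  igraph::simplify(g)
}

# Positive random expression aligned to a graph's nodes.
randomExpression <- function(graph, lo = 0.5, hi = 10) {
  nodes <- igraph::V(graph)$name
  setNames(runif(length(nodes), lo, hi), nodes)
}

# Spectral bipartiteness oracle: a connected graph is bipartite iff its
# adjacency spectrum is symmetric about 0.
isBipartiteSpectral <- function(g) {
  lam <- eigen(as.matrix(igraph::as_adjacency_matrix(g)),
               only.values = TRUE, symmetric = TRUE)$values
  abs(max(lam) + min(lam)) < 1e-8
}

# Area under the ROC curve from score vectors via the rank-sum identity.
aurocFromScores <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Tiny hand-built differential expression table.
makeDE <- function(genes, t, p, condition = NA_character_) {
  out <- data.frame(gene = genes, effect = t, s2 = 1,
                    df = 4, t = t, p = p, p_bh = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "condition") <- condition
  out
}
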