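triangle <- function() {
  g <- igraph::make_ring(3)
  igraph::V(g)$name <- c("a", "b", "c")
  g
}

test_that("network preparation keeps the largest measured component", {
  # components of sizes 5 and 3
  g <- igraph::graph_from_edgelist(rbind(
    c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"), c("e", "a"),
    c("x", "y"), c("y", "z"), c("z", "x")), directed = FALSE)
  prep <- suppressWarnings(prepareNetwork(g, letters))
  expect_setequal(igraph::V(prep)$name, c("a", "b", "c", "d", "e"))
  expect_equal(igraph::graph_attr(prep, "n_components_removed"), 1L)
  # connected input with all nodes measured is untouched
  tri <- triangle()
  prep2 <- prepareNetwork(tri, c("a", "b", "c"))
  expect_equal(igraph::vcount(prep2), 3)
  # 4-cycle is bipartite: survives with a warning
  sq <- igraph::make_ring(4); igraph::V(sq)$name <- c("p", "q", "r", "s")
  expect_warning(prep3 <- prepareNetwork(sq, c("p", "q", "r", "s")),
                 "bipartite")
  expect_equal(igraph::vcount(prep3), 4)
  # too-small remainder is an error
  expect_error(prepareNetwork(tri, c("a", "b")), "fewer than 3")
})

test_that("mass-action stochastic matrix matches direct evaluation", {
  tri <- triangle()
  P1 <- stochasticMatrix(tri, c(a = 1, b = 1, c = 1))
  expect_equal(as.matrix(P1),
               matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3, byrow = TRUE,
                      dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  P2 <- stochasticMatrix(tri, c(a = 1, b = 2, c = 3))
  expect_equal(P2["a", ], c(a = 0, b = 2 / 5, c = 3 / 5))
  expect_equal(P2["b", ], c(a = 1 / 4, b = 0, c = 3 / 4))
  expect_equal(P2["c", ], c(a = 1 / 3, b = 2 / 3, c = 0))
  expect_equal(unname(Matrix::rowSums(P2)), rep(1, 3), tolerance = 1e-12)
})

test_that("local entropies follow the Shannon formula and its bounds", {
  tri <- triangle()
  S <- localEntropies(stochasticMatrix(tri, c(a = 1, b = 2, c = 3)))
  expect_equal(unname(S["a"]), -(0.4 * log(0.4) + 0.6 * log(0.6)),
               tolerance = 1e-12)
  expect_equal(unname(round(S["a"], 5)), 0.67301)
  # degree-1 node has zero entropy; uniform row attains log(k)
  path <- igraph::make_graph(~ a - b - c - d)
  Sp <- localEntropies(stochasticMatrix(path, c(a = 1, b = 1, c = 1, d = 1)))
  expect_equal(unname(Sp[c("a", "d")]), c(0, 0))
  expect_equal(unname(Sp["b"]), log(2), tolerance = 1e-12)
  # bits option rescales by log(2)
  Sb <- localEntropies(stochasticMatrix(tri, c(a = 1, b = 1, c = 1)), "bits")
  expect_equal(unname(Sb), rep(1, 3), tolerance = 1e-12)
})

test_that("stationary distribution: closed form, eigen route and balance", {
  tri <- triangle()
  e <- c(a = 1, b = 2, c = 3)
  pi <- stationaryDistribution(tri, e, check = "eigen")
  expect_equal(unname(pi), c(5, 8, 9) / 22, tolerance = 1e-12)
  expect_equal(sum(pi), 1, tolerance = 1e-14)
  # pi P = pi by direct multiplication
  P <- stochasticMatrix(tri, e)
  expect_equal(as.vector(pi %*% P), unname(pi), tolerance = 1e-12)
  # uniform expression on a triangle: symmetric stationary state
  expect_equal(unname(stationaryDistribution(tri, c(a = 1, b = 1, c = 1))),
               rep(1 / 3, 3), tolerance = 1e-14)
})

test_that("closed-form pi equals the eigen solution on random instances", {
  set.seed(12)
  for (i in 1:30) {
    g <- randomConnectedGraph(sample(5:40, 1))
    e <- randomExpression(g)
    P <- stochasticMatrix(g, e)
    expect_lt(max(abs(Matrix::rowSums(P) - 1)), 1e-10)
    pi <- stationaryDistribution(g, e, check = "eigen", tol = 1e-8)
    expect_true(all(pi > 0))
    # detailed balance: pi_i p_ij = pi_j p_ji on every edge
    flux <- pi * P
    expect_lt(max(abs(flux - Matrix::t(flux))), 1e-12)
    # entropy bounds: 0 <= S_i <= log(degree), SR within [min S, max S]
    S <- localEntropies(P)
    deg <- igraph::degree(g)[rownames(P)]
    expect_true(all(S >= -1e-14 & S <= log(deg) + 1e-12))
    sr <- entropyRate(pi, S)
    expect_gte(sr, min(S) - 1e-12)
    expect_lte(sr, max(S) + 1e-12)
  }
})

test_that("entropy rate matches the brute-force oracle and closed forms", {
  tri <- triangle()
  e <- c(a = 1, b = 2, c = 3)
  sr <- entropyRate(stationaryDistribution(tri, e),
                    localEntropies(stochasticMatrix(tri, e)))
  orc <- oracleEntropyRate(tri, e)
  expect_equal(sr, orc$sr, tolerance = 1e-12)
  expect_equal(sr, 0.617835, tolerance = 1e-6)
  # k-regular graphs with uniform expression: SR = log k
  for (n in c(4, 11, 26, 50)) {
    ring <- igraph::make_ring(n)
    igraph::V(ring)$name <- paste0("r", seq_len(n))
    eu <- setNames(rep(1, n), paste0("r", seq_len(n)))
    expect_equal(entropyRate(stationaryDistribution(ring, eu),
                             localEntropies(stochasticMatrix(ring, eu))),
                 log(2), tolerance = 1e-12)
  }
  K5 <- igraph::make_full_graph(5)
  igraph::V(K5)$name <- paste0("k", 1:5)
  ek <- setNames(rep(2, 5), paste0("k", 1:5))
  expect_equal(entropyRate(stationaryDistribution(K5, ek),
                           localEntropies(stochasticMatrix(K5, ek))),
               log(4), tolerance = 1e-12)
  expect_error(entropyRate(c(0.5, 0.5), c(1, 1, 1)), "length")
})

test_that("entropy is invariant under expression rescaling", {
  set.seed(2)
  g <- randomConnectedGraph(25)
  e <- randomExpression(g)
  base_P <- stochasticMatrix(g, e)
  base_sr <- entropyRate(stationaryDistribution(g, e),
                         localEntropies(base_P))
  for (c0 in c(0.1, 10, 1000)) {
    expect_equal(as.matrix(stochasticMatrix(g, c0 * e)), as.matrix(base_P),
                 tolerance = 1e-14)
    sr <- entropyRate(stationaryDistribution(g, c0 * e),
                      localEntropies(stochasticMatrix(g, c0 * e)))
    expect_equal(sr, base_sr, tolerance = 1e-13)
  }
})

test_that("per-sample entropy is deterministic and order-invariant", {
  se <- simulateExperiment(simulationConfig(n_genes = 300, seed = 8))
  g <- simulateNetwork(80, 6, seed = 3, gene_ids = rownames(se))
  ent <- entropyPerSample(se, g)
  expect_equal(nrow(ent), 18L)
  expect_true(all(is.finite(ent$sr)))
  # identical samples give identical SR
  mat <- SummarizedExperiment::assay(se)
  twin <- cbind(s1 = mat[, 1], s2 = mat[, 1])
  ent2 <- entropyPerSample(twin, g)
  expect_equal(ent2$sr[1], ent2$sr[2])
  # permuting gene order leaves SR unchanged
  perm <- sample(nrow(mat))
  ent3 <- entropyPerSample(mat[perm, ], g)
  expect_equal(ent3$sr, ent$sr, tolerance = 1e-12)
  # normalisation bounds SR/log(lambda_max) at 1
  entn <- entropyPerSample(se, g, normalize = TRUE)
  expect_true(all(entn$sr <= 1 + 1e-12))
})

test_that("flatter expression profiles raise signalling entropy", {
  # shrinking a sample's expression toward its mean flattens the walk and
  # must increase SR (the uniform walk maximises it on a regular graph)
  set.seed(15)
  g <- simulateNetwork(150, 6, seed = 15)
  nodes <- igraph::V(g)$name
  e <- setNames(runif(150, 1, 10), nodes)
  sr_raw <- entropyRate(stationaryDistribution(g, e),
                        localEntropies(stochasticMatrix(g, e)))
  shrunk <- mean(e) + 0.2 * (e - mean(e))
  sr_flat <- entropyRate(stationaryDistribution(g, shrunk),
                         localEntropies(stochasticMatrix(g, shrunk)))
  expect_gt(sr_flat, sr_raw)
})
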