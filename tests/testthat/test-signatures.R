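test_that("t-profile correlation matches direct formula evaluation", {
  a <- makeDE(paste0("g", 1:4), t = c(1, 2, 3, 4), p = rep(0.5, 4), "DUX4")
  b <- makeDE(paste0("g", 1:4), t = c(2, 1, 4, 3), p = rep(0.5, 4), "DUX4c")
  r <- correlateTProfiles(a, b)
  expect_equal(r$r, 0.6, tolerance = 1e-12)
  expect_equal(r$n, 4L)
  expect_equal(correlateTProfiles(a, a)$r, 1)
  neg <- a; neg$t <- -neg$t
  expect_equal(correlateTProfiles(a, neg)$r, -1)
  expect_error(correlateTProfiles(a[1:2, ], b[1:2, ]), "3 shared genes")
})

test_that("correlation agrees with a brute-force covariance ratio", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    a <- makeDE(paste0("g", 1:n), t = rnorm(n), p = runif(n))
    b <- makeDE(paste0("g", 1:n), t = rnorm(n), p = runif(n))
    expect_equal(correlateTProfiles(a, b)$r, bruteCor(a$t, b$t),
                 tolerance = 1e-12)
  }
})

test_that("DUX4 signature requires triple concordance with ERD inversion", {
  genes <- c("up_ok", "no_erd", "down_ok", "wrong_sign", "null")
  de_d <- makeDE(genes, t = c(2.1, 2.2, -2.0, 2.0, 0.1),
                 p = c(0.01, 0.01, 0.01, 0.01, 0.9))
  de_v <- makeDE(genes, t = c(3.0, 3.0, -2.5, 2.5, 0.2),
                 p = c(0.002, 0.002, 0.01, 0.01, 0.8))
  de_e <- makeDE(genes, t = c(-2.5, 0.3, 2.2, 2.1, -0.1),
                 p = c(0.03, 0.5, 0.02, 0.02, 0.95))
  sig <- deriveDux4Signature(de_d, de_v, de_e)
  expect_equal(upGenes(sig), "up_ok")     # ERD must be significantly down
  expect_equal(downGenes(sig), "down_ok") # mirror rule
  # all-null tables give an empty signature
  null_de <- makeDE(genes, t = rep(0.5, 5), p = rep(1, 5))
  empty <- deriveDux4Signature(null_de, null_de, null_de)
  expect_length(upGenes(empty), 0)
  expect_length(downGenes(empty), 0)
  # ties at p == alpha are excluded (strict inequality)
  tie <- makeDE("g", t = 2, p = 0.05)
  expect_length(upGenes(deriveDux4Signature(tie, tie,
                                            makeDE("g", -2, 0.05))), 0)
})

test_that("DUX4c signature requires concordant direction in both tables", {
  genes <- c("up_ok", "discordant", "one_sig")
  de_t <- makeDE(genes, t = c(2, 2, 2), p = c(0.01, 0.01, 0.01))
  de_c <- makeDE(genes, t = c(1.5, -1.5, 1.5), p = c(0.04, 0.04, 0.5))
  sig <- deriveDux4cSignature(de_t, de_c)
  expect_equal(upGenes(sig), "up_ok")
  expect_length(downGenes(sig), 0)
})

test_that("joint partition is exact set algebra", {
  s4 <- SignatureSet("DUX4", up = c("a", "b"), down = c("x", "y"))
  sc <- SignatureSet("DUX4c", up = c("b", "c"), down = c("y", "z"))
  p <- partitionJoint(s4, sc)
  expect_equal(p$up_both, "b")
  expect_equal(p$up_dux4_not_dux4c, "a")
  expect_equal(p$up_dux4c_not_dux4, "c")
  expect_equal(p$down_both, "y")
  expect_equal(p$down_dux4_not_dux4c, "x")
  expect_equal(p$down_dux4c_not_dux4, "z")
  # identical signatures: all "not" categories empty
  p2 <- partitionJoint(s4, SignatureSet("DUX4c", up = c("a", "b"),
                                        down = c("x", "y")))
  expect_length(p2$up_dux4_not_dux4c, 0)
  expect_length(p2$up_dux4c_not_dux4, 0)
  # disjoint signatures: no "both" category
  p3 <- partitionJoint(s4, SignatureSet("DUX4c", up = "q", down = "r"))
  expect_length(p3$up_both, 0)
})

test_that("partition lists are disjoint and reconstruct the signatures", {
  set.seed(9)
  for (i in 1:20) {
    pool <- paste0("g", 1:40)
    u4 <- sample(pool, 10); d4 <- sample(setdiff(pool, u4), 10)
    uc <- sample(pool, 10); dc <- sample(setdiff(pool, uc), 10)
    s4 <- SignatureSet("DUX4", u4, d4)
    sc <- SignatureSet("DUX4c", uc, dc)
    p <- partitionJoint(s4, sc)
    # pairwise disjoint within each direction family
    expect_length(intersect(p$up_both, p$up_dux4_not_dux4c), 0)
    expect_length(intersect(p$up_both, p$up_dux4c_not_dux4), 0)
    expect_length(intersect(p$down_both, p$down_dux4_not_dux4c), 0)
    expect_length(intersect(p$down_both, p$down_dux4c_not_dux4), 0)
    # unions rebuild the inputs
    expect_setequal(union(p$up_both, p$up_dux4_not_dux4c), u4)
    expect_setequal(union(p$down_both, p$down_dux4_not_dux4c), d4)
    expect_setequal(union(p$up_both, p$up_dux4c_not_dux4), uc)
    expect_setequal(union(p$down_both, p$down_dux4c_not_dux4), dc)
  }
})

test_that("triple concordance is conservative under the null", {
  # null generator: expected signature size well below 1 per 10,000 genes
  total <- 0L
  for (s in 1:3) {
    se <- simulateExperiment(simulationConfig(n_genes = 10000,
                                              effect_size = 0, seed = s))
    de <- deAllConstructs(se, c("DUX4", "tMALDUX4-VP16", "tMALDUX4-ERD"))
    sig <- deriveDux4Signature(de[["DUX4"]], de[["tMALDUX4-VP16"]],
                               de[["tMALDUX4-ERD"]])
    total <- total + length(upGenes(sig)) + length(downGenes(sig))
  }
  expect_lt(total / 3, 1)  # < 1 false signature gene per 10,000-gene run
})
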