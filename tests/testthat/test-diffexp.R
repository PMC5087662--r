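local_tiny_se <- function(values) {
  # values: list of per-condition gene-by-replicate blocks
  mat <- do.call(cbind, values)
  colnames(mat) <- unlist(lapply(names(values), function(cc)
    paste0(cc, "_r", seq_len(ncol(values[[cc]])))))
  md <- data.frame(sample_id = colnames(mat),
                   condition = rep(names(values),
                                   vapply(values, ncol, integer(1))))
  makeDuxExperiment(mat, md)
}

test_that("fitContrast computes exact two-group summaries", {
  se <- local_tiny_se(list(
    control = rbind(g1 = c(3, 3, 3), g2 = c(1, 2, 3)),
    DUX4    = rbind(g1 = c(5, 5, 5), g2 = c(1, 2, 3))))
  fit <- fitContrast(se, "DUX4")
  expect_equal(fit$effect, c(2, 0))
  expect_equal(fit$s2, c(0, 1))   # pooled: (2 + 2) / 4 for g2
  expect_equal(fit$df, c(4L, 4L))
  expect_error(fitContrast(se, "DUX4c"), "absent")
})

test_that("moderated t matches its closed forms and limits", {
  # infinite prior: z statistic
  mt <- moderatedT(effect = 2, s2 = 0.5, df = 4,
                   hyper = list(d0 = Inf, s0_2 = 1), n_cond = 3, n_ref = 3)
  expect_equal(mt$t, 2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(mt$p, 2 * pnorm(-2 / sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(round(mt$t, 3), 2.449)
  expect_equal(round(mt$p, 4), 0.0143)
  # null effect
  mt0 <- moderatedT(0, 1, 4, list(d0 = 4, s0_2 = 1), 3, 3)
  expect_equal(c(mt0$t, mt0$p), c(0, 1))
  # d0 = 0 recovers the ordinary pooled two-sample t (oracle equivalence)
  set.seed(13)
  for (i in 1:200) {
    x <- rnorm(3, 1); y <- rnorm(4)
    s2p <- ((3 - 1) * var(x) + (4 - 1) * var(y)) / 5
    tt <- t.test(x, y, var.equal = TRUE)
    mt <- moderatedT(mean(x) - mean(y), s2p, 5, list(d0 = 0, s0_2 = 1), 3, 4)
    expect_equal(mt$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(mt$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("EB hyperparameter estimation recovers simulated truth", {
  set.seed(7)
  # hierarchical draw: sigma2_g from the scaled inverse-chi-square prior
  # (d0 = 4, s0_2 = 1), then s2_g | sigma2_g ~ sigma2_g * chisq_df / df
  sigma2 <- 1 * 4 / rchisq(10000, 4)
  s2 <- sigma2 * rchisq(10000, 4) / 4
  h <- estimateEB(s2, df = 4)
  expect_lt(abs(h$d0 - 4), 0.5)
  expect_lt(abs(h$s0_2 - 1), 0.1)
  # near-zero spread forces the infinite-d0 branch
  h2 <- estimateEB(rep(c(1, 1 + 1e-9), 50), df = 4)
  expect_true(is.infinite(h2$d0))
  # two distinct values: finite output, no error
  h3 <- estimateEB(c(0.5, 2), df = 4)
  expect_true(is.finite(h3$s0_2))
  expect_error(estimateEB(c(0, 0), df = 4), "s2 > 0")
})

test_that("EB estimates agree with the limma implementation", {
  skip_if_not_installed("limma")
  set.seed(8)
  s2 <- 0.8 * rchisq(5000, 6) / 6
  h <- estimateEB(s2, df = 6)
  fd <- limma::fitFDist(s2, df1 = 6)
  expect_equal(h$d0, fd$df2, tolerance = 0.02)
  expect_equal(h$s0_2, fd$scale, tolerance = 0.02)
})

test_that("full moderated pipeline matches limma on simulated data", {
  skip_if_not_installed("limma")
  se <- simulateExperiment(simulationConfig(n_genes = 2000, seed = 31,
    group_sizes = c(dux4_up = 50L, dux4_down = 50L)))
  keep <- SummarizedExperiment::colData(se)$condition %in% c("control", "DUX4")
  mat <- SummarizedExperiment::assay(se)[, keep]
  grp <- SummarizedExperiment::colData(se)$condition[keep]
  design <- cbind(1, grp == "DUX4")
  lfit <- limma::eBayes(limma::lmFit(mat, design))
  de <- deTable(se, "DUX4", hyper = list(d0 = lfit$df.prior,
                                         s0_2 = lfit$s2.prior))
  expect_equal(de$effect, unname(lfit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(de$s2, unname(lfit$sigma^2), tolerance = 1e-10)
  expect_equal(de$t, unname(lfit$t[, 2]), tolerance = 1e-8)
  # limma caps an infinite prior df at the pooled residual df before the
  # t tail; we use the exact normal limit, so p agrees only to ~1%
  expect_equal(de$p, unname(lfit$p.value[, 2]), tolerance = 2e-2)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(adjustBH(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
  expect_equal(adjustBH(0.37), 0.37)
  expect_error(adjustBH(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(2:200, 1))
    expect_equal(adjustBH(p), bruteBH(p), tolerance = 1e-12)
    # invariance under permutation + inverse permutation
    perm <- sample(length(p))
    expect_equal(adjustBH(p[perm])[order(perm)], adjustBH(p),
                 tolerance = 1e-14)
  }
})

test_that("null simulation yields calibrated raw p-values", {
  se <- simulateExperiment(simulationConfig(n_genes = 5000, effect_size = 0,
                                            seed = 17))
  de <- deAllConstructs(se)
  pvals <- unlist(lapply(de, `[[`, "p"))
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
  # p_bh never below p, and monotone with p ranks
  for (d in de) {
    expect_true(all(d$p_bh >= d$p - 1e-14))
    expect_true(all(diff(d$p_bh[order(d$p)]) >= -1e-14))
  }
})
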