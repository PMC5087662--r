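#' Row-standardise an expression matrix
#'
#' Centres and scales each gene row to mean 0 and SD 1 across samples,
#' putting genes on a common scale before set-level comparison. The SD uses
#' the population convention (denominator n), so a row of n equally spaced
#' values maps onto fixed z positions regardless of scale. Zero-variance
#' rows cannot be standardised and are dropped with a message.
#'
#' @param mat numeric matrix with >= 2 columns.
#' @return Matrix of the same shape (minus dropped rows).
#' @examples
#' zscoreRows(rbind(g1 = c(1, 2, 3)))  # -1.2247, 0, 1.2247
#' @export
zscoreRows <- function(mat) {
  if (ncol(mat) < 2L) stop("need >= 2 samples to standardise rows")
  mu <- rowMeans(mat)
  sdv <- sqrt(rowMeans((mat - mu)^2))  # population SD
  keep <- sdv > 0
  if (any(!keep))
    message(sum(!keep), " zero-variance gene row(s) dropped")
  (mat[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
}

#' Single-sample DUX4 activity score
#'
#' Scores each sample by contrasting the expression of the regulator's
#' upregulated target genes against its downregulated ones: in a sample
#' where the regulator is active the up-targets should sit above the
#' down-targets. The default statistic is the difference of means of the
#' row-z-scored values; \code{"t_stat"} is a within-sample two-sample
#' Welch t between the two value sets, and \code{"rank_diff"} the
#' difference of mean within-sample ranks rescaled to [-1, 1].
#'
#' @param x SummarizedExperiment or numeric gene-by-sample matrix.
#' @param signature a \code{\linkS4class{SignatureSet}}.
#' @param statistic \code{"mean_diff"} (default), \code{"t_stat"} or
#'   \code{"rank_diff"}.
#' @param warn_missing_frac warn when less than this fraction of either
#'   signature list is found in the matrix (relevant for cross-species use).
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{score}, \code{n_up_used}, \code{n_down_used}.
#' @examples
#' se <- simulateExperiment(simulationConfig(n_genes = 500, seed = 1))
#' sc <- dux4Score(se, trueSignature(se, "DUX4"))
#' head(sc)
#' @export
dux4Score <- function(x, signature,
                      statistic = c("mean_diff", "t_stat", "rank_diff"),
                      warn_missing_frac = 0.5) {
  statistic <- match.arg(statistic)
  stopifnot(is(signature, "SignatureSet"))
  mat <- exprsMatrix(x)
  up <- intersect(upGenes(signature), rownames(mat))
  down <- intersect(downGenes(signature), rownames(mat))
  if (!length(up) || !length(down)) {
    stop(sprintf(
      "signature genes not found in matrix (missing %.0f%% of up, %.0f%% of down)",
      100 * (1 - length(up) / max(1L, length(upGenes(signature)))),
      100 * (1 - length(down) / max(1L, length(downGenes(signature))))))
  }
  for (side in list(c("up", length(up), length(upGenes(signature))),
                    c("down", length(down), length(downGenes(signature))))) {
    if (as.numeric(side[2L]) / as.numeric(side[3L]) < warn_missing_frac)
      warning("less than ", 100 * warn_missing_frac, "% of the ", side[1L],
              " signature found in the matrix")
  }
  z <- zscoreRows(mat)
  up <- intersect(up, rownames(z)); down <- intersect(down, rownames(z))
  score <- vapply(seq_len(ncol(z)), function(s) {
    zu <- z[up, s]; zd <- z[down, s]
    switch(statistic,
      mean_diff = mean(zu) - mean(zd),
      t_stat = if (length(zu) > 1L && length(zd) > 1L)
                 unname(t.test(zu, zd)$statistic) else mean(zu) - mean(zd),
      rank_diff = {
        rk <- rank(c(zu, zd))
        nu <- length(zu); nd <- length(zd)
        (mean(rk[seq_len(nu)]) - mean(rk[nu + seq_len(nd)])) / ((nu + nd) / 2)
      })
  }, numeric(1L))
  data.frame(sample_id = colnames(mat), score = score,
             n_up_used = length(up), n_down_used = length(down),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare biomarker scores between two sample groups
#'
#' Welch two-sample t-test of the per-sample scores between two conditions.
#'
#' @param scores data.frame from \code{\link{dux4Score}}.
#' @param metadata data.frame with \code{sample_id} and \code{condition}
#'   (or a SummarizedExperiment, whose colData is used).
#' @param group_a,group_b condition labels to compare.
#' @return list with \code{difference} (mean(group_a) - mean(group_b)),
#'   \code{t}, \code{df} and two-sided \code{p}.
#' @export
compareScoreGroups <- function(scores, metadata, group_a, group_b) {
  if (is(metadata, "SummarizedExperiment"))
    metadata <- as.data.frame(SummarizedExperiment::colData(metadata))
  cond <- metadata$condition[match(scores$sample_id, metadata$sample_id)]
  a <- scores$score[cond == group_a & !is.na(cond)]
  b <- scores$score[cond == group_b & !is.na(cond)]
  if (length(a) < 2L) stop("group absent or too small: ", group_a)
  if (length(b) < 2L) stop("group absent or too small: ", group_b)
  tt <- t.test(a, b)  # Welch
  list(difference = mean(a) - mean(b), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}
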