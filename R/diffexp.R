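#' Two-group contrast of one construct against control
#'
#' Per-gene difference of condition means, pooled within-group variance and
#' residual degrees of freedom for one construct contrasted against the
#' reference condition.
#'
#' @param x SummarizedExperiment (colData \code{condition}) or numeric
#'   matrix.
#' @param condition condition to contrast (e.g. \code{"DUX4"}).
#' @param reference reference condition (default \code{"control"}).
#' @param metadata data.frame with \code{sample_id} and \code{condition};
#'   required when \code{x} is a bare matrix.
#' @return data.frame with columns \code{gene}, \code{effect}
#'   (mean(condition) - mean(reference), log units), \code{s2} (pooled
#'   residual variance), \code{df} (residual degrees of freedom), and the
#'   group sizes \code{n_cond}, \code{n_ref} as attributes.
#' @examples
#' se <- simulateExperiment(simulationConfig(n_genes = 100, seed = 1))
#' head(fitContrast(se, "DUX4"))
#' @export
fitContrast <- function(x, condition, reference = "control", metadata = NULL) {
  mat <- exprsMatrix(x)
  cond_vec <- if (is(x, "SummarizedExperiment")) {
    as.character(SummarizedExperiment::colData(x)$condition)
  } else {
    if (is.null(metadata)) stop("metadata required with a bare matrix")
    as.character(metadata$condition[match(colnames(mat), metadata$sample_id)])
  }
  for (lev in c(condition, reference)) {
    n <- sum(cond_vec == lev, na.rm = TRUE)
    if (n == 0L) stop("condition absent from metadata: ", lev)
    if (n < 2L) stop("need >= 2 samples in group '", lev, "'")
  }
  a <- mat[, cond_vec == condition, drop = FALSE]
  b <- mat[, cond_vec == reference, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  ss1 <- rowSums((a - m1)^2); ss2 <- rowSums((b - m2)^2)
  df <- n1 + n2 - 2L
  out <- data.frame(gene = rownames(mat),
                    effect = m1 - m2,
                    s2 = (ss1 + ss2) / df,
                    df = df,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_cond") <- n1
  attr(out, "n_ref") <- n2
  out
}

# Inverse of the trigamma function by Newton iteration on 1/x scale with a
# bisection fallback; trigamma is strictly decreasing on (0, Inf).
trigammaInverse <- function(y, tol = 1e-8, max_iter = 50L) {
  vapply(y, function(yy) {
    if (yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    x <- 0.5 + 1 / yy  # good starting point (limma's choice of scale)
    for (i in seq_len(max_iter)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2L)
      x <- x + dif
      if (!is.finite(x) || x <= 0) { x <- NA_real_; break }
      if (abs(dif / x) < tol) return(x)
    }
    if (is.finite(x)) return(x)
    # bisection fallback on a wide bracket
    lo <- 1e-8; hi <- 1e8
    for (i in seq_len(200L)) {
      mid <- sqrt(lo * hi)
      if (trigamma(mid) > yy) lo <- mid else hi <- mid
      if (hi / lo - 1 < tol) break
    }
    sqrt(lo * hi)
  }, numeric(1L))
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Moment-matching estimator of the scaled inverse-chi-square prior on
#' gene-wise residual variances: the prior degrees of freedom \code{d0} and
#' prior variance \code{s0_2}. Works on the log scale: with
#' \code{e_g = log(s2_g) - digamma(df_g/2) + log(df_g/2)},
#' \code{trigamma(d0/2)} is matched to \code{var(e) - mean(trigamma(df/2))}
#' and \code{s0_2 = exp(mean(e) + digamma(d0/2) - log(d0/2))}. When the
#' observed spread is no larger than the sampling spread the prior is
#' degenerate: \code{d0 = Inf} and \code{s0_2 = exp(mean(e))}.
#'
#' @param s2 vector of gene-wise residual variances (> 0 required for at
#'   least two genes).
#' @param df residual degrees of freedom, scalar or per-gene vector.
#' @return list with \code{d0} and \code{s0_2}.
#' @examples
#' set.seed(1)
#' sigma2 <- 4 / rchisq(5000, 4)        # inverse-chi-square prior, d0 = 4
#' s2 <- sigma2 * rchisq(5000, 4) / 4   # sampling noise on 4 df
#' estimateEB(s2, 4)                    # recovers d0 near 4, s0_2 near 1
#' @export
estimateEB <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L) stop("need >= 2 genes with s2 > 0 and df > 0")
  if (all(s2[ok][1L] == s2[ok])) {
    # still fine: zero spread forces the infinite-d0 branch
  }
  if (all(s2 == 0)) stop("degenerate variance distribution: all s2 are 0")
  s2 <- s2[ok]; df <- df[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  excess <- var(e) - mean(trigamma(df / 2))
  if (!is.finite(excess) || excess <= 0) {
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  }
  d0 <- 2 * trigammaInverse(excess)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated t-statistic and p-value
#'
#' Shrinks each gene's variance toward the prior,
#' \code{s2_tilde = (d0*s0_2 + df*s2) / (d0 + df)}, and forms
#' \code{t = effect / sqrt(s2_tilde * (1/n_cond + 1/n_ref))} with a
#' two-sided p-value from the Student t distribution on \code{d0 + df}
#' degrees of freedom (standard normal when \code{d0} is infinite). With
#' \code{d0 = 0} the ordinary pooled two-sample t is recovered.
#'
#' @param effect per-gene mean difference.
#' @param s2 per-gene pooled variance.
#' @param df residual degrees of freedom (scalar or vector).
#' @param hyper list with \code{d0} and \code{s0_2}, as from
#'   \code{\link{estimateEB}}.
#' @param n_cond,n_ref group sizes.
#' @return data.frame with columns \code{t} and \code{p}.
#' @export
moderatedT <- function(effect, s2, df, hyper, n_cond, n_ref) {
  d0 <- hyper$d0; s0_2 <- hyper$s0_2
  if (is.null(d0) || is.null(s0_2) || (is.finite(d0) && d0 < 0) || s0_2 <= 0)
    stop("invalid hyperparameters")
  df <- rep_len(df, length(effect))
  s2_tilde <- if (is.infinite(d0)) rep_len(s0_2, length(effect))
              else (d0 * s0_2 + df * s2) / (d0 + df)
  se <- sqrt(s2_tilde * (1 / n_cond + 1 / n_ref))
  t <- ifelse(effect == 0, 0, effect / se)
  df_total <- d0 + df
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), df_total)
  data.frame(t = t, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector. Input values
#' outside [0, 1] are an error.
#'
#' @param p vector of p-values.
#' @return Adjusted p-values, capped at 1 and monotone in the input ranks.
#' @export
adjustBH <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Full differential-expression table for one construct
#'
#' Runs \code{\link{fitContrast}}, estimates the variance prior across all
#' genes with \code{\link{estimateEB}} (unless supplied), and returns the
#' moderated t, raw and BH-adjusted p-values.
#'
#' @inheritParams fitContrast
#' @param hyper optional hyperparameter list; estimated from the data when
#'   \code{NULL}.
#' @return data.frame with columns \code{gene}, \code{effect}, \code{s2},
#'   \code{df}, \code{t}, \code{p}, \code{p_bh}; the hyperparameters are
#'   attached as attribute \code{"hyper"}.
#' @examples
#' se <- simulateExperiment(simulationConfig(n_genes = 200, seed = 1))
#' de <- deTable(se, "DUX4")
#' head(de[order(de$p), ])
#' @export
deTable <- function(x, condition, reference = "control", metadata = NULL,
                    hyper = NULL) {
  fit <- fitContrast(x, condition, reference, metadata)
  if (is.null(hyper)) hyper <- estimateEB(fit$s2, fit$df)
  mt <- moderatedT(fit$effect, fit$s2, fit$df, hyper,
                   attr(fit, "n_cond"), attr(fit, "n_ref"))
  out <- cbind(fit, t = mt$t, p = mt$p, p_bh = adjustBH(mt$p))
  attr(out, "hyper") <- hyper
  attr(out, "condition") <- condition
  out
}

#' Differential expression for every construct against control
#'
#' @param x SummarizedExperiment with a \code{condition} column.
#' @param conditions constructs to contrast; default all non-reference
#'   conditions present.
#' @param reference reference condition.
#' @return Named list of \code{\link{deTable}} data.frames.
#' @export
deAllConstructs <- function(x, conditions = NULL, reference = "control") {
  cond_vec <- as.character(SummarizedExperiment::colData(x)$condition)
  if (is.null(conditions)) conditions <- setdiff(unique(cond_vec), reference)
  setNames(lapply(conditions, function(cc) deTable(x, cc, reference)),
           conditions)
}
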