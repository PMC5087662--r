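#' Correlate t-statistic profiles of two constructs
#'
#' Correlates the per-gene moderated t-statistics of two differential
#' expression tables over their shared genes, to quantify how similar the
#' two constructs' transcriptional landscapes are.
#'
#' @param de_a,de_b data.frames from \code{\link{deTable}} (columns
#'   \code{gene} and \code{t}).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return data.frame with \code{construct_a}, \code{construct_b}, \code{r},
#'   \code{p} and \code{n} (shared genes used).
#' @examples
#' se <- simulateExperiment(simulationConfig(n_genes = 300, seed = 1))
#' de <- deAllConstructs(se, c("DUX4", "tMALDUX4-VP16"))
#' correlateTProfiles(de[["DUX4"]], de[["tMALDUX4-VP16"]])
#' @export
correlateTProfiles <- function(de_a, de_b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(de_a$gene, de_b$gene)
  if (length(shared) < 3L)
    stop("need >= 3 shared genes; got ", length(shared))
  ta <- de_a$t[match(shared, de_a$gene)]
  tb <- de_b$t[match(shared, de_b$gene)]
  ct <- suppressWarnings(cor.test(ta, tb, method = method))
  data.frame(
    construct_a = attr(de_a, "condition") %||% NA_character_,
    construct_b = attr(de_b, "condition") %||% NA_character_,
    r = unname(ct$estimate), p = ct$p.value, n = length(shared),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All pairwise t-profile correlations
#'
#' @param de_list named list of \code{\link{deTable}} results.
#' @param method correlation method.
#' @return data.frame with one row per unordered construct pair.
#' @export
correlateAllPairs <- function(de_list, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  nm <- names(de_list)
  pairs <- utils::combn(nm, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    r <- correlateTProfiles(de_list[[pairs[1L, k]]], de_list[[pairs[2L, k]]],
                            method)
    r$construct_a <- pairs[1L, k]; r$construct_b <- pairs[2L, k]
    r
  }))
  rownames(out) <- NULL
  out
}

# Shared significance/direction helper: +1 significant up, -1 significant
# down, 0 otherwise. Ties at p == alpha are excluded (strict inequality).
.direction <- function(de, genes, alpha, use_adjusted = FALSE) {
  idx <- match(genes, de$gene)
  p <- if (use_adjusted) de$p_bh[idx] else de$p[idx]
  sign(de$t[idx]) * (p < alpha)
}

#' Derive the DUX4 target signature by triple concordance
#'
#' A gene is called a DUX4-upregulated target if it is significantly
#' upregulated by both DUX4 and the constitutively active tMALDUX4-VP16 and
#' significantly downregulated by the dominant-negative tMALDUX4-ERD; the
#' downregulated list is the mirror image. "Up/down" means t > 0 / t < 0
#' together with p < alpha (raw p by default).
#'
#' @param de_dux4,de_vp16,de_erd \code{\link{deTable}} results for DUX4,
#'   tMALDUX4-VP16 and tMALDUX4-ERD. The gene universe is the intersection
#'   of their gene columns.
#' @param alpha significance threshold (strict inequality).
#' @param use_adjusted use BH-adjusted rather than raw p-values.
#' @return A \code{\linkS4class{SignatureSet}} for regulator "DUX4".
#' @export
deriveDux4Signature <- function(de_dux4, de_vp16, de_erd, alpha = 0.05,
                                use_adjusted = FALSE) {
  universe <- Reduce(intersect, list(de_dux4$gene, de_vp16$gene, de_erd$gene))
  if (!length(universe)) stop("empty shared gene universe")
  d1 <- .direction(de_dux4, universe, alpha, use_adjusted)
  d2 <- .direction(de_vp16, universe, alpha, use_adjusted)
  d3 <- .direction(de_erd, universe, alpha, use_adjusted)
  up <- universe[d1 == 1 & d2 == 1 & d3 == -1]
  down <- universe[d1 == -1 & d2 == -1 & d3 == 1]
  SignatureSet("DUX4", up = up, down = down)
}

#' Derive the DUX4c target signature by double concordance
#'
#' A gene is called up- (down-)regulated by DUX4c if it is significantly
#' up- (down-)regulated by both DUX4c and the truncated tMALDUX4.
#'
#' @param de_tmal,de_dux4c \code{\link{deTable}} results for tMALDUX4 and
#'   DUX4c.
#' @inheritParams deriveDux4Signature
#' @return A \code{\linkS4class{SignatureSet}} for regulator "DUX4c".
#' @export
deriveDux4cSignature <- function(de_tmal, de_dux4c, alpha = 0.05,
                                 use_adjusted = FALSE) {
  universe <- intersect(de_tmal$gene, de_dux4c$gene)
  if (!length(universe)) stop("empty shared gene universe")
  d1 <- .direction(de_tmal, universe, alpha, use_adjusted)
  d2 <- .direction(de_dux4c, universe, alpha, use_adjusted)
  SignatureSet("DUX4c",
               up = universe[d1 == 1 & d2 == 1],
               down = universe[d1 == -1 & d2 == -1])
}

#' Joint partition of the DUX4 and DUX4c signatures
#'
#' Set algebra over the two signatures producing the six categories used
#' for enrichment analysis: genes regulated by one regulator but not the
#' other, and genes regulated by both, in each direction.
#'
#' @param sig_dux4,sig_dux4c \code{SignatureSet}s over the same universe.
#' @param universe optional character vector; when supplied, lists are
#'   intersected with it.
#' @return Named list of six character vectors:
#'   \code{down_dux4_not_dux4c}, \code{up_both}, \code{up_dux4c_not_dux4},
#'   \code{down_dux4c_not_dux4}, \code{down_both}, \code{up_dux4_not_dux4c}.
#' @export
partitionJoint <- function(sig_dux4, sig_dux4c, universe = NULL) {
  u4 <- upGenes(sig_dux4); d4 <- downGenes(sig_dux4)
  uc <- upGenes(sig_dux4c); dc <- downGenes(sig_dux4c)
  if (!is.null(universe)) {
    u4 <- intersect(u4, universe); d4 <- intersect(d4, universe)
    uc <- intersect(uc, universe); dc <- intersect(dc, universe)
  }
  list(down_dux4_not_dux4c = setdiff(d4, dc),
       up_both             = intersect(u4, uc),
       up_dux4c_not_dux4   = setdiff(uc, u4),
       down_dux4c_not_dux4 = setdiff(dc, d4),
       down_both           = intersect(d4, dc),
       up_dux4_not_dux4c   = setdiff(u4, uc))
}
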