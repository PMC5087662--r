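#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact test of independence for the contingency table
#' \code{rbind(c(a, b), c(c, d))}. The two-sided p-value is the sum of the
#' hypergeometric probabilities, over all tables with the same margins, of
#' the tables no more probable than the observed one (with a relative
#' tolerance of 1e-7 for floating-point ties). The reported odds ratio is
#' the sample odds ratio \code{(a*d)/(b*c)}; 0 and Inf are allowed at the
#' boundaries.
#'
#' @param a,b,c,d non-negative integer counts: query-and-set, query-not-set,
#'   set-not-query, neither.
#' @return list with \code{odds_ratio} and \code{p}.
#' @examples
#' fisherTest(3, 1, 1, 3)  # p = 0.4857, OR = 9
#' @export
fisherTest <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  N <- a + b + c + d
  K <- a + b   # row-1 margin
  n <- a + c   # column-1 margin
  if (N == 0L) stop("empty table")
  support <- max(0L, n - (N - K)):min(K, n)
  probs <- dhyper(support, K, N - K, n)
  p_obs <- dhyper(a, K, N - K, n)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c)
  if (a == 0 || d == 0) or <- if (b == 0 || c == 0) NaN else 0
  list(odds_ratio = or, p = p)
}

#' Gene-set enrichment of a query list by Fisher's exact test
#'
#' Tests each annotation set for over/under-representation in the query
#' gene list against the analysis universe, with Benjamini-Hochberg
#' correction across all tested sets. Sets smaller than
#' \code{min_set_size} after intersection with the universe are skipped
#' with a message.
#'
#' @param query_genes character vector, a subset of \code{universe}.
#' @param collection a \code{\linkS4class{GeneSetCollection}}.
#' @param universe character vector of all analysed genes.
#' @param alpha_bh BH-adjusted significance threshold for the
#'   \code{enriched} flag.
#' @param min_set_size smallest set size tested (after universe
#'   intersection).
#' @return data.frame sorted by p with one row per tested set:
#'   \code{set_name}, contingency counts \code{a,b,c,d}, \code{odds_ratio},
#'   \code{p}, \code{p_bh}, \code{enriched}.
#' @export
enrich <- function(query_genes, collection, universe, alpha_bh = 0.05,
                   min_set_size = 3L) {
  stopifnot(is(collection, "GeneSetCollection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- intersect(unique(as.character(query_genes)), universe)
  sets <- lapply(geneSets(collection), intersect, universe)
  small <- lengths(sets) < min_set_size
  if (any(small))
    message(sum(small), " set(s) smaller than ", min_set_size,
            " after universe intersection skipped")
  sets <- sets[!small]
  if (!length(sets)) {
    return(data.frame(set_name = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), odds_ratio = numeric(),
                      p = numeric(), p_bh = numeric(), enriched = logical()))
  }
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    a <- length(intersect(query, s))
    b <- length(query) - a
    cc <- length(s) - a
    d <- length(universe) - a - b - cc
    ft <- fisherTest(a, b, cc, d)
    data.frame(set_name = nm, a = a, b = b, c = cc, d = d,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- adjustBH(out$p)
  out$enriched <- out$p_bh < alpha_bh
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
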