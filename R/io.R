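#' The construct panel conditions
#'
#' Canonical condition labels of the perturbation panel: a control retrovirus
#' and five constructs (DUX4, truncated tMALDUX4, constitutively active
#' tMALDUX4-VP16, dominant-negative tMALDUX4-ERD, and DUX4c).
#'
#' @return Character vector of the six condition labels, control first.
#' @export
duxConditions <- function() {
  c("control", "DUX4", "tMALDUX4", "tMALDUX4-VP16", "tMALDUX4-ERD", "DUX4c")
}

#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text file whose first column holds gene ids and whose
#' header row holds sample ids; the body must be numeric. Duplicate gene ids
#' are handled by \code{dup_policy}: probe-level tables often carry several
#' rows per gene and the default keeps, per gene, the row with the highest
#' mean expression.
#'
#' @param path file path.
#' @param delimiter field delimiter (default tab).
#' @param dup_policy one of \code{"highest_mean"} (default), \code{"mean"}
#'   (average duplicate rows) or \code{"error"}.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
readExpression <- function(path, delimiter = "\t",
                           dup_policy = c("highest_mean", "mean", "error")) {
  dup_policy <- match.arg(dup_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = delimiter, header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no genes: file '", path, "' has a header only")
  gene_ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]  # before subsetting, which mangles dups
  if (length(sample_ids) == 0L) stop("no sample columns in '", path, "'")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("malformed numeric cell at row %d (gene '%s'), column '%s': '%s'",
                     bad[1L], gene_ids[bad[1L]], sample_ids[j], v[bad[1L]]))
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  if (anyNA(mat))
    stop("missing values in expression matrix; impute or drop before loading")
  dimnames(mat) <- list(gene_ids, sample_ids)
  collapseDuplicateGenes(mat, dup_policy)
}

# Resolve duplicated gene rows according to policy; logs how many were merged.
collapseDuplicateGenes <- function(mat, dup_policy = "highest_mean") {
  ids <- rownames(mat)
  if (!anyDuplicated(ids)) return(mat)
  if (dup_policy == "error")
    stop("duplicate gene id: ", ids[duplicated(ids)][1L])
  n_dup <- sum(duplicated(ids))
  if (dup_policy == "highest_mean") {
    ord <- order(-rowMeans(mat))
    keep <- ord[!duplicated(ids[ord])]
    out <- mat[sort(keep), , drop = FALSE]
  } else { # mean
    out <- rowsum(mat, group = ids, reorder = FALSE) /
      as.vector(table(factor(ids, levels = unique(ids))))
    rownames(out) <- unique(ids)
  }
  message(n_dup, " duplicate gene row(s) collapsed (policy: ", dup_policy, ")")
  out
}

#' Write an expression matrix as TSV
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path destination file.
#' @param delimiter field delimiter.
#' @export
writeExpression <- function(mat, path, delimiter = "\t") {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Expects columns \code{sample_id}, \code{condition} and (optionally)
#' \code{replicate}.
#'
#' @param path file path to a delimited table.
#' @param delimiter field delimiter.
#' @return A \code{data.frame} with one row per sample.
#' @export
readSampleMetadata <- function(path, delimiter = "\t") {
  md <- read.delim(path, sep = delimiter, header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  miss <- setdiff(need, colnames(md))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1L])
  md
}

#' Assemble a SummarizedExperiment from matrix and metadata
#'
#' The package's working container: the expression matrix becomes the
#' \code{"exprs"} assay and the metadata the column data. Every sample in
#' the matrix must have exactly one metadata row.
#'
#' @param mat numeric gene-by-sample matrix (gene ids as rownames).
#' @param metadata data.frame with \code{sample_id} and \code{condition}.
#' @return A \code{\link[SummarizedExperiment]{SummarizedExperiment}}.
#' @export
makeDuxExperiment <- function(mat, metadata) {
  idx <- match(colnames(mat), metadata$sample_id)
  if (anyNA(idx))
    stop("sample(s) without metadata: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "))
  cd <- S4Vectors::DataFrame(metadata[idx, , drop = FALSE])
  rownames(cd) <- colnames(mat)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat), colData = cd)
}

# Pull the expression assay out of a SummarizedExperiment or pass a matrix
# through unchanged.
exprsMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    a <- if (!is.null(nm) && "exprs" %in% nm) "exprs" else 1L
    return(SummarizedExperiment::assay(x, a))
  }
  if (!is.matrix(x)) stop("expected a matrix or SummarizedExperiment")
  x
}

#' Read an undirected interaction network
#'
#' Accepts a two-column edge list (TSV, optional header) or SIF
#' (\code{node relation node} per line). Self-loops are dropped and parallel
#' edges collapsed, with a message giving counts, so the result is always a
#' simple undirected graph.
#'
#' @param path file path.
#' @param format \code{"edge_list"} or \code{"sif"}.
#' @return An \code{\link[igraph]{igraph}} graph.
#' @export
readNetwork <- function(path, format = c("edge_list", "sif")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(lines, "[\t ]+")
  need <- if (format == "sif") 3L else 2L
  nt <- lengths(toks)
  bad <- which(nt < need)
  if (length(bad))
    stop(sprintf("line %d of '%s' has %d token(s); expected >= %d",
                 bad[1L], path, nt[bad[1L]], need))
  if (format == "sif") {
    from <- vapply(toks, `[[`, character(1L), 1L)
    to   <- vapply(toks, `[[`, character(1L), 3L)
  } else {
    from <- vapply(toks, `[[`, character(1L), 1L)
    to   <- vapply(toks, `[[`, character(1L), 2L)
    # tolerate a header such as "from\tto"
    if (identical(tolower(from[1L]), "from") && identical(tolower(to[1L]), "to")) {
      from <- from[-1L]; to <- to[-1L]
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  n_loop <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (n_loop || n_multi)
    message("network cleaned: dropped ", n_loop, " self-loop(s), collapsed ",
            n_multi, " duplicate edge(s)")
  g
}

#' Write a network as a two-column edge list
#'
#' @param graph an igraph graph.
#' @param path destination file.
#' @export
writeNetwork <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write.table(data.frame(from = el[, 1L], to = el[, 2L]), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: \code{name<TAB>description<TAB>member...}. Duplicate
#' members within a set are removed preserving order; duplicate set names
#' are an error.
#'
#' @param path file path.
#' @return A \code{\linkS4class{GeneSetCollection}}.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(GeneSetCollection())
  toks <- strsplit(lines, "\t", fixed = TRUE)
  nt <- lengths(toks)
  bad <- which(nt < 3L)
  if (length(bad))
    stop(sprintf("line %d of '%s' has %d field(s); GMT needs >= 3",
                 bad[1L], path, nt[bad[1L]]))
  nm <- vapply(toks, `[[`, character(1L), 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name: ", nm[duplicated(nm)][1L])
  desc <- vapply(toks, `[[`, character(1L), 2L)
  sets <- lapply(toks, function(t) unique(t[-(1:2)]))
  names(sets) <- nm
  GeneSetCollection(sets, desc)
}

#' Write gene sets in GMT format
#'
#' @param collection a \code{GeneSetCollection}.
#' @param path destination file.
#' @export
writeGMT <- function(collection, path) {
  stopifnot(is(collection, "GeneSetCollection"))
  sets <- geneSets(collection)
  desc <- setDescriptions(collection)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a SignatureSet as two GMT lines
#'
#' Emits one line per direction, named \code{<regulator>_up} and
#' \code{<regulator>_down}.
#'
#' @param signature a \code{SignatureSet}.
#' @param path destination file.
#' @param append append to an existing file rather than overwrite.
#' @export
writeSignatureGMT <- function(signature, path, append = FALSE) {
  stopifnot(is(signature, "SignatureSet"))
  lines <- c(
    paste(c(paste0(regulator(signature), "_up"), "upregulated targets",
            upGenes(signature)), collapse = "\t"),
    paste(c(paste0(regulator(signature), "_down"), "downregulated targets",
            downGenes(signature)), collapse = "\t"))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Rename gene identifiers via a user-supplied map
#'
#' Applies a two-column mapping (e.g. mouse-to-human orthologs) to the
#' rownames of a matrix, the nodes of a graph, or the gene lists of a
#' \code{SignatureSet}. Identifiers are opaque, case-sensitive strings;
#' entries without a mapping are dropped with a message. If several source
#' ids map to the same target, the first occurrence wins for matrices.
#'
#' @param x matrix (gene rownames), igraph graph or \code{SignatureSet}.
#' @param map data.frame whose first column is the current id and second the
#'   replacement id.
#' @return Object of the same type with identifiers renamed.
#' @export
renameGenes <- function(x, map) {
  from <- as.character(map[[1L]]); to <- as.character(map[[2L]])
  lut <- setNames(to, from)
  if (is.matrix(x)) {
    hit <- rownames(x) %in% from
    if (any(!hit))
      message(sum(!hit), " gene(s) without mapping dropped")
    x <- x[hit, , drop = FALSE]
    rownames(x) <- unname(lut[rownames(x)])
    x <- x[!duplicated(rownames(x)), , drop = FALSE]
    return(x)
  }
  if (is(x, "SignatureSet")) {
    up <- unname(lut[intersect(upGenes(x), from)])
    dn <- unname(lut[intersect(downGenes(x), from)])
    dn <- setdiff(dn, up)
    return(SignatureSet(regulator(x), up = up, down = dn))
  }
  if (igraph::is_igraph(x)) {
    nm <- igraph::V(x)$name
    keep <- nm %in% from
    if (any(!keep)) {
      message(sum(!keep), " node(s) without mapping dropped")
      x <- igraph::induced_subgraph(x, which(keep))
    }
    igraph::V(x)$name <- unname(lut[igraph::V(x)$name])
    return(igraph::simplify(x))
  }
  stop("unsupported type for renameGenes")
}
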