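# Deterministic 32-bit FNV-1a digest of the deparsed config, for the manifest.
.configDigest <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis from one configuration: (optionally)
#' simulate the experiment and network, run per-construct differential
#' expression, pairwise t-profile correlations, signature derivation and
#' joint partition, single-sample biomarker scoring, per-sample signalling
#' entropy and (when annotation sets are given) enrichment of the partition
#' lists. All intermediate tables are written as plain TSV so any stage can
#' be inspected or replaced, and a JSON manifest records the configuration
#' digest, seed and produced artifacts. Re-running with the same config
#' reproduces all outputs.
#'
#' @param config list (or path to a YAML/JSON file describing one) with
#'   entries:
#'   \describe{
#'     \item{out_dir}{output directory (required).}
#'     \item{expression, metadata}{paths to an expression TSV and metadata
#'       TSV; omit to simulate instead.}
#'     \item{simulation}{list of \code{\link{simulationConfig}} arguments
#'       used when no expression path is given.}
#'     \item{network}{path to an edge-list TSV; omit to simulate a network
#'       over the expression genes.}
#'     \item{network_nodes, network_mean_degree}{size of the simulated
#'       network (defaults 2000 nodes, mean degree 8).}
#'     \item{alpha}{signature significance threshold (default 0.05).}
#'     \item{correlation_method}{\code{"pearson"} or \code{"spearman"}.}
#'     \item{score_statistic}{statistic for \code{\link{dux4Score}}.}
#'     \item{entropy}{list of options for \code{\link{entropyPerSample}}
#'       (\code{units}, \code{normalize}, \code{check}).}
#'     \item{gene_sets}{path to a GMT file for enrichment (optional).}
#'     \item{seed}{integer seed fanned out to the stochastic stages.}
#'   }
#' @return Invisibly, the manifest list (also written to
#'   \code{out_dir/manifest.json}).
#' @examples
#' \donttest{
#' out <- tempfile("duxrun")
#' m <- runPipeline(list(out_dir = out, seed = 1,
#'                       simulation = list(n_genes = 800),
#'                       network_nodes = 150))
#' names(m$artifacts)
#' }
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                                 simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  # ---- validation before any compute ----
  if (is.null(config$out_dir)) stop("validation: config lacks 'out_dir'")
  for (f in c("expression", "metadata", "network", "gene_sets")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("validation: ", f, " path does not exist: ", config[[f]])
  }
  if (!is.null(config$expression) && is.null(config$metadata))
    stop("validation: expression given without metadata")
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  corr_method <- config$correlation_method %||% "pearson"
  score_stat <- config$score_statistic %||% "mean_diff"
  ent_opts <- config$entropy %||% list()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, paste0(...))
  artifacts <- list()
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # ---- inputs: load or simulate (stage seeds fan out from the run seed) ----
  se <- stage("input", function() {
    if (!is.null(config$expression)) {
      mat <- readExpression(config$expression)
      md <- readSampleMetadata(config$metadata)
      makeDuxExperiment(mat, md)
    } else {
      sim_args <- config$simulation %||% list()
      sim_args$seed <- sim_args$seed %||% (seed + 101L)
      simulateExperiment(do.call(simulationConfig, sim_args))
    }
  })
  stage("write_input", function() {
    writeExpression(exprsMatrix(se), out("expression.tsv"))
    write.table(as.data.frame(SummarizedExperiment::colData(se)),
                out("metadata.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    rd <- SummarizedExperiment::rowData(se)
    if (ncol(rd)) {
      write.table(data.frame(gene = rownames(se), as.data.frame(rd)),
                  out("truth.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      artifacts$truth <<- out("truth.tsv")
    }
  })
  artifacts$expression <- out("expression.tsv")
  artifacts$metadata <- out("metadata.tsv")

  network <- stage("network", function() {
    if (!is.null(config$network)) readNetwork(config$network)
    else simulateNetwork(min(config$network_nodes %||% 2000L, nrow(se)),
                         config$network_mean_degree %||% 8,
                         seed = seed + 202L, gene_ids = rownames(se))
  })
  stage("write_network", function() writeNetwork(network, out("network.tsv")))
  artifacts$network <- out("network.tsv")

  # ---- differential expression ----
  de <- stage("diffexp", function() deAllConstructs(se))
  for (nm in names(de)) {
    f <- out("de_", gsub("[^A-Za-z0-9]", "_", nm), ".tsv")
    write.table(de[[nm]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts[[paste0("de_", nm)]] <- f
  }

  # ---- correlations ----
  corr <- stage("correlations", function() correlateAllPairs(de, corr_method))
  write.table(corr, out("corr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  artifacts$correlations <- out("corr.tsv")

  # ---- signatures & partition ----
  sig4 <- stage("signature_dux4", function()
    deriveDux4Signature(de[["DUX4"]], de[["tMALDUX4-VP16"]],
                        de[["tMALDUX4-ERD"]], alpha = alpha))
  sig4c <- stage("signature_dux4c", function()
    deriveDux4cSignature(de[["tMALDUX4"]], de[["DUX4c"]], alpha = alpha))
  writeSignatureGMT(sig4, out("sig.gmt"))
  writeSignatureGMT(sig4c, out("sig.gmt"), append = TRUE)
  artifacts$signatures <- out("sig.gmt")
  part <- partitionJoint(sig4, sig4c)
  for (nm in names(part)) {
    f <- out("partition_", nm, ".txt")
    writeLines(part[[nm]], f)
    artifacts[[paste0("partition_", nm)]] <- f
  }

  # ---- biomarker score ----
  scores <- stage("score", function() {
    sig_use <- if (length(upGenes(sig4)) && length(downGenes(sig4))) sig4
               else trueSignature(se, "DUX4")
    dux4Score(se, sig_use, statistic = score_stat)
  })
  write.table(scores, out("scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  artifacts$scores <- out("scores.tsv")

  # ---- signalling entropy ----
  ent <- stage("entropy", function()
    entropyPerSample(se, network,
                     units = ent_opts$units %||% "nats",
                     normalize = isTRUE(ent_opts$normalize),
                     check = ent_opts$check %||% "residual"))
  write.table(ent, out("entropy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  artifacts$entropy <- out("entropy.tsv")

  # ---- enrichment (optional, needs annotation sets) ----
  if (!is.null(config$gene_sets)) {
    gmt <- stage("read_gene_sets", function() readGMT(config$gene_sets))
    for (nm in names(part)) {
      if (!length(part[[nm]])) next
      tab <- stage(paste0("enrich_", nm), function()
        enrich(part[[nm]], gmt, universe = rownames(se)))
      f <- out("enrich_", nm, ".tsv")
      write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts[[paste0("enrich_", nm)]] <- f
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("duxsig")),
    seed = seed,
    config_digest = .configDigest(config),
    n_genes = nrow(se), n_samples = ncol(se),
    signature_sizes = list(dux4_up = length(upGenes(sig4)),
                           dux4_down = length(downGenes(sig4)),
                           dux4c_up = length(upGenes(sig4c)),
                           dux4c_down = length(downGenes(sig4c))),
    artifacts = artifacts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
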