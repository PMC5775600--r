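#' Build a pipeline run configuration
#'
#' Collects every tunable of a run with the pipeline's canonical
#' defaults: datasets are screened at target-probe sd 0.25, co-expression
#' is called at q < 0.05, the candidate list is the top 1000 genes,
#' enrichment is called at Bonferroni-adjusted p < 0.05, and pooling
#' standardizes within each study before concatenation.
#'
#' @param targetProbe target probe identifier.
#' @param expressionDir directory containing one tab-delimited expression
#'   matrix per study (`*.tsv`; the file name stem is the study id).
#' @param annotationPath probe annotation TSV.
#' @param gmtPaths character vector of GMT files (one enrichment table is
#'   written per file).
#' @param ppiPaths character vector of PPI edge-list TSVs.
#' @param outDir output directory for the run.
#' @param targetSymbol label for the target network node; defaults to the
#'   annotation symbol of `targetProbe` at run time if empty.
#' @param sdThreshold,qThreshold,topK,topCandidates,enrichAlpha,pooling,ranking
#'   stage tunables; see slot documentation in [RunConfig].
#' @param seed seed for any stochastic stage.
#' @return a [RunConfig].
#' @export
runConfig <- function(targetProbe, expressionDir, annotationPath,
                      gmtPaths = character(), ppiPaths = character(),
                      outDir = "coin_run", targetSymbol = "",
                      sdThreshold = 0.25, qThreshold = 0.05,
                      topK = 1000L, topCandidates = 20L,
                      enrichAlpha = 0.05, pooling = "standardize",
                      ranking = "signed", seed = 1L) {
  new("RunConfig", targetProbe = targetProbe,
      targetSymbol = toupper(targetSymbol),
      sdThreshold = sdThreshold, qThreshold = qThreshold,
      topK = as.integer(topK), topCandidates = as.integer(topCandidates),
      enrichAlpha = enrichAlpha, pooling = pooling, ranking = ranking,
      expressionDir = expressionDir, annotationPath = annotationPath,
      gmtPaths = gmtPaths, ppiPaths = ppiPaths, outDir = outDir,
      seed = as.integer(seed))
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: target ", object@targetProbe,
      ", sd >= ", object@sdThreshold, ", q < ", object@qThreshold,
      ", top ", object@topK, ", ", object@pooling, " pooling\n", sep = "")
})

.configFields <- c("targetProbe", "targetSymbol", "sdThreshold",
                   "qThreshold", "topK", "topCandidates", "enrichAlpha",
                   "pooling", "ranking", "expressionDir", "annotationPath",
                   "gmtPaths", "ppiPaths", "outDir", "seed")

#' Write a RunConfig as JSON
#' @param config a [RunConfig].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  x <- stats::setNames(lapply(.configFields, function(f) slot(config, f)),
                       .configFields)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a RunConfig from JSON
#' @param path JSON path written by [writeRunConfig()].
#' @return a [RunConfig].
#' @export
readRunConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  runConfig(targetProbe = x$targetProbe, expressionDir = x$expressionDir,
            annotationPath = x$annotationPath,
            gmtPaths = as.character(x$gmtPaths %||% character()),
            ppiPaths = as.character(x$ppiPaths %||% character()),
            outDir = x$outDir, targetSymbol = x$targetSymbol %||% "",
            sdThreshold = x$sdThreshold, qThreshold = x$qThreshold,
            topK = x$topK, topCandidates = x$topCandidates,
            enrichAlpha = x$enrichAlpha, pooling = x$pooling,
            ranking = x$ranking, seed = x$seed)
}

# Run a stage, prefixing any error with the stage name and leaving a
# FAILED marker next to whatever partial outputs exist.
.stage <- function(name, outDir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0(name, ": ", conditionMessage(e)),
               file.path(outDir, "FAILED"))
    stop(name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full correlation-interaction-network pipeline
#'
#' Orchestrates filter, correlate, FDR, enrich and network
#' stages over on-disk inputs and writes every result table plus a
#' machine-readable run summary into `config@outDir`:
#' `filter_report.tsv`, `correlations.tsv` (ranked, with q-values),
#' `candidates.tsv` (gene-level top list), `enrichment_<gmt>.tsv` per
#' collection, `network.sif`, `network.graphml`, `node_weights.tsv`, and
#' `run_summary.json` with stage counts, thresholds, the pi0 estimate and
#' a content hash of every input file. Outputs are deterministic: a rerun
#' on identical inputs and configuration is byte-identical.
#'
#' The candidate list is the top `topK` of the q-significant genes when
#' more than `topK` are significant; when fewer are, the top `topK` of
#' the full ranking is used and a warning records that the list extends
#' beyond the significant set.
#'
#' @param config a [RunConfig].
#' @return path of the run directory, invisibly. Counts are in
#'   `run_summary.json`.
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "RunConfig"))
  outDir <- config@outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(outDir, "FAILED"))
  summary <- list(
    target_probe = config@targetProbe,
    thresholds = list(sd = config@sdThreshold, q = config@qThreshold,
                      top_k = config@topK,
                      enrich_alpha = config@enrichAlpha),
    pooling = config@pooling, ranking = config@ranking,
    seed = config@seed,
    package_version = as.character(utils::packageVersion("coinet")))

  exprFiles <- sort(list.files(config@expressionDir, pattern = "\\.tsv$",
                               full.names = TRUE))
  inputs <- c(exprFiles, config@annotationPath, config@gmtPaths,
              config@ppiPaths)
  summary$input_md5 <- as.list(tools::md5sum(inputs))

  datasets <- .stage("read", outDir, {
    if (!length(exprFiles))
      stop("no expression matrices found in ", config@expressionDir)
    lapply(exprFiles, readExpressionMatrix)
  })
  annotation <- .stage("read", outDir,
                       readProbeAnnotation(config@annotationPath))
  summary$input_datasets <- length(datasets)

  filt <- .stage("filter", outDir,
                 filterDatasets(datasets, config@targetProbe,
                                config@sdThreshold))
  writeFilterReport(filt$report, file.path(outDir, "filter_report.tsv"))
  summary$retained_datasets <- length(filt$retained)

  corr <- .stage("correlate", outDir, {
    pooled <- poolCompendium(filt$retained, mode = config@pooling)
    correlateTarget(pooled, config@targetProbe, annotation)
  })
  summary$tested_probes <- sum(!is.na(corr@table$p_raw))

  fdrOut <- .stage("fdr", outDir,
                   attachQ(corr, method = "storey",
                           alpha = config@qThreshold))
  corr <- fdrOut$result
  summary$fdr_method <- fdrOut$fdr@method
  summary$pi0 <- fdrOut$fdr@pi0

  sig <- .stage("select", outDir,
                selectSignificant(corr, fdrOut$fdr,
                                  alpha = config@qThreshold))
  summary$significant_probes <- nrow(sig)

  ranked <- .stage("rank", outDir, {
    full <- rankCandidates(corr, k = sum(!is.na(corr@table$r)),
                           direction = config@ranking)
    sigIds <- sig$probe_id
    if (length(sigIds) >= config@topK)
      utils::head(full[full$probe_id %in% sigIds, , drop = FALSE],
                  config@topK)
    else {
      if (nrow(full) > length(sigIds))
        warning("only ", length(sigIds), " probes are q-significant; ",
                "candidate list drawn from the full ranking")
      utils::head(full, min(config@topK, nrow(full)))
    }
  })
  ranked$rank <- seq_len(nrow(ranked))
  .writeTSV(ranked, file.path(outDir, "correlations.tsv"))
  genes <- collapseToGenes(ranked)
  targetSymbol <- config@targetSymbol
  if (!nzchar(targetSymbol)) {
    targetSymbol <- symbolsFor(annotation, config@targetProbe)
    if (!nzchar(targetSymbol)) targetSymbol <- config@targetProbe
  }
  genes <- genes[genes$gene != targetSymbol, , drop = FALSE]
  .writeTSV(genes, file.path(outDir, "candidates.tsv"))
  summary$candidate_probes <- nrow(ranked)
  summary$candidate_genes <- nrow(genes)

  sigPathwayGenes <- character()
  if (length(config@gmtPaths)) {
    enrTables <- .stage("enrich", outDir, {
      lapply(config@gmtPaths, function(g) {
        collection <- readGMT(g)
        enr <- enrich(genes$gene, collection, alpha = config@enrichAlpha)
        stem <- sub("\\.[^.]*$", "", basename(g))
        writeEnrichment(enr, file.path(outDir,
                                       paste0("enrichment_", stem, ".tsv")))
        enr
      })
    })
    summary$enriched_sets <- vapply(enrTables,
                                    function(e) sum(e$significant), 0L)
    sigPathwayGenes <- unique(unlist(lapply(enrTables, function(e)
      strsplit(e$overlap_genes[e$significant], ",", fixed = TRUE)),
      use.names = FALSE))
  }

  if (length(config@ppiPaths)) {
    net <- .stage("network", outDir, {
      ppi <- readPPIEdges(config@ppiPaths)
      net <- integrateEdges(ppi, genes$gene)
      cand <- utils::head(genes, config@topCandidates)
      attachTarget(net, targetSymbol, cand)
    })
    exportNetwork(net, file.path(outDir, "network.sif"), "sif")
    exportNetwork(net, file.path(outDir, "network.graphml"), "graphml")
    w <- nodeWeights(net, flagGenes = sigPathwayGenes)
    writeNodeWeights(w, file.path(outDir, "node_weights.tsv"))
    g <- networkGraph(net)
    summary$network_nodes <- sum(igraph::V(g)$role == "gene")
    summary$network_ppi_edges <-
      sum(igraph::edge_attr(g, "type") == "ppi")
    summary$network_candidate_edges <-
      sum(igraph::edge_attr(g, "type") == "candidate")
  }

  jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' qPCR fold change by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` within each condition,
#' `ddCt = dCt_treated - dCt_control`, fold change `2^(-ddCt)`. Satisfies
#' the reciprocal identity: swapping treated and control inverts the
#' fold change exactly.
#'
#' @param ctTargetTreated,ctRefTreated cycle thresholds of the gene of
#'   interest and the endogenous control in the treated condition.
#' @param ctTargetControl,ctRefControl the same in the control condition.
#' @return fold change (vectorized over the inputs).
#' @examples
#' ddctFoldChange(20, 15, 22, 15)  # ddCt = -2 -> fold change 4
#' @export
ddctFoldChange <- function(ctTargetTreated, ctRefTreated,
                           ctTargetControl, ctRefControl) {
  ct <- c(ctTargetTreated, ctRefTreated, ctTargetControl, ctRefControl)
  if (any(!is.finite(ct))) stop("all Ct values must be finite")
  ddct <- (ctTargetTreated - ctRefTreated) -
    (ctTargetControl - ctRefControl)
  2^(-ddct)
}
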