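#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom stats pt pnorm phyper rnorm runif sd smooth.spline predict cor complete.cases setNames
#' @importFrom utils read.delim write.table head
NULL

#' Single-study expression matrix with dataset identity
#'
#' Holds one normalized (log2-scale) probes-by-samples expression matrix
#' together with the label of the study it came from. Extends
#' [SummarizedExperiment::SummarizedExperiment] so that the usual assay,
#' `dim` and `dimnames` machinery applies; row names are probe identifiers
#' and column names are sample identifiers.
#'
#' @slot datasetId single character label identifying the study (for real
#'   compendia typically the ArrayExpress/GEO accession encoded in the file
#'   name).
#' @seealso [readExpressionMatrix()], [writeExpressionMatrix()]
#' @export
setClass("ExpressionDataset",
  contains = "SummarizedExperiment",
  representation(datasetId = "character")
)

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (length(object@datasetId) != 1L || is.na(object@datasetId) ||
      !nzchar(object@datasetId))
    msg <- c(msg, "datasetId must be a single non-empty string")
  if (nrow(object) == 0L || ncol(object) == 0L)
    msg <- c(msg, "expression matrix must have at least one probe and one sample")
  rn <- rownames(object)
  cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "probe identifiers (row names) must be present and unique")
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample identifiers (column names) must be present and unique")
  if (length(SummarizedExperiment::assays(object)) >= 1L) {
    v <- SummarizedExperiment::assay(object, 1L)
    if (!is.numeric(v) || any(!is.finite(v)))
      msg <- c(msg, "all expression values must be finite numbers")
  }
  if (length(msg)) msg else TRUE
})

#' Probe-to-gene-symbol annotation
#'
#' Long-format mapping from probe identifiers to gene symbols. A probe may
#' map to several symbols and a symbol may be hit by several probes. Symbols
#' are upper-cased on construction because public interaction databases mix
#' cases.
#'
#' @slot map data.frame with columns `probe_id`, `symbol` and `biotype`
#'   (one of `"coding"`, `"lncRNA"`, `"other"`).
#' @export
setClass("ProbeAnnotation", representation(map = "data.frame"))

setValidity("ProbeAnnotation", function(object) {
  m <- object@map
  need <- c("probe_id", "symbol", "biotype")
  if (!all(need %in% names(m)))
    return(sprintf("map must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(m) && any(!nzchar(m$probe_id) | is.na(m$probe_id)))
    return("probe_id entries must be non-empty")
  if (nrow(m) && any(m$symbol != toupper(m$symbol), na.rm = TRUE))
    return("gene symbols must be upper-cased")
  TRUE
})

#' Named gene sets with a testing universe
#'
#' A collection of named gene sets (as read from a GMT file) plus the
#' universe of symbols against which over-representation is tested. By
#' default the universe is the union of all set members; an explicit
#' background (for example all genes on the array) may be supplied instead.
#'
#' @slot sets named list of character vectors of unique member symbols.
#' @slot descriptions named character vector, one description per set.
#' @slot universe character vector, a superset of every set.
#' @seealso [readGMT()], [enrich()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character",
                 universe = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets) == 0L)
    msg <- c(msg, "collection must contain at least one gene set")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "gene sets must have unique names")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "every gene set must be non-empty")
  if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "set members must be unique within a set")
  if (!all(unlist(object@sets, use.names = FALSE) %in% object@universe))
    msg <- c(msg, "universe must be a superset of every set")
  if (length(msg)) msg else TRUE
})

#' Multi-source protein-protein interaction edge table
#'
#' Cleaned edge records `(gene_a, gene_b, source_db)` pooled across
#' interaction databases. Pairs are stored in canonical (alphabetical)
#' order, self-loops are removed, and exact duplicate (pair, source) rows
#' are dropped; the same unordered pair may still appear under several
#' sources.
#'
#' @slot edges data.frame with columns `gene_a`, `gene_b`, `source_db`.
#' @seealso [readPPIEdges()], [integrateEdges()]
#' @export
setClass("PPIEdgeTable", representation(edges = "data.frame"))

setValidity("PPIEdgeTable", function(object) {
  e <- object@edges
  need <- c("gene_a", "gene_b", "source_db")
  if (!all(need %in% names(e)))
    return(sprintf("edges must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(e$gene_a == e$gene_b)) return("self-loops are not allowed")
    if (any(e$gene_a != toupper(e$gene_a)) || any(e$gene_b != toupper(e$gene_b)))
      return("gene symbols must be upper-cased")
    if (any(e$gene_a > e$gene_b))
      return("pairs must be stored in canonical (alphabetical) order")
    if (anyDuplicated(paste(e$gene_a, e$gene_b, e$source_db)))
      return("exact duplicate (pair, source) rows are not allowed")
  }
  TRUE
})

#' Per-dataset variability filter report
#'
#' One row per input dataset recording the target probe's sample standard
#' deviation, the sample count, and whether the dataset was retained at the
#' given threshold.
#'
#' @slot table data.frame with columns `dataset_id`, `n_samples`,
#'   `target_sd`, `retained`, `reason`.
#' @slot threshold the standard-deviation cutoff used (log2-expression
#'   units); datasets with sd strictly below it are excluded.
#' @seealso [filterDatasets()]
#' @export
setClass("FilterReport",
  representation(table = "data.frame", threshold = "numeric")
)

setValidity("FilterReport", function(object) {
  t <- object@table
  need <- c("dataset_id", "n_samples", "target_sd", "retained", "reason")
  if (!all(need %in% names(t)))
    return(sprintf("table must have columns: %s", paste(need, collapse = ", ")))
  if (anyDuplicated(t$dataset_id))
    return("every dataset must appear exactly once")
  if (length(object@threshold) != 1L || object@threshold < 0)
    return("threshold must be a single non-negative number")
  ok <- t$retained == (!is.na(t$target_sd) & t$target_sd >= object@threshold &
                         t$n_samples >= 2L)
  if (nrow(t) && !all(ok))
    return("retained flag inconsistent with sd/threshold rule")
  TRUE
})

#' Pooled multi-dataset expression compendium
#'
#' The cross-dataset matrix that target-versus-all correlation runs on.
#' Under `standardize` pooling every probe row is z-scored within each
#' dataset before column-wise concatenation; under `raw` pooling values are
#' concatenated unchanged. Entries for probes absent from a contributing
#' dataset are `NA` and are skipped pairwise during correlation. Under
#' `fisher_meta` no pooled matrix exists: the member datasets are carried
#' and correlations are combined per dataset downstream.
#'
#' @slot values numeric matrix, probes by pooled samples (0 x 0 for
#'   `fisher_meta`).
#' @slot provenance data.frame with columns `sample_id`, `dataset_id`
#'   mapping each pooled column to its study.
#' @slot mode one of `"standardize"`, `"raw"`, `"fisher_meta"`.
#' @slot datasets the retained [ExpressionDataset] list (kept only for
#'   `fisher_meta`).
#' @seealso [poolCompendium()], [correlateTarget()]
#' @export
setClass("PooledCompendium",
  representation(values = "matrix", provenance = "data.frame",
                 mode = "character", datasets = "list")
)

#' Target-versus-all correlation table
#'
#' One record per non-target probe: Pearson r, the number of paired
#' observations, the exact two-sided t-based p-value, and (once FDR has
#' been applied) the Storey/BH q-value. Zero-variance probes are retained
#' with `degenerate = TRUE`, r = 0 and p = 1 for auditability; probes with
#' fewer than 3 paired observations carry `NA` r and are excluded from
#' ranking.
#'
#' @slot targetProbe the probe every record is correlated against.
#' @slot table data.frame with columns `probe_id`, `gene_symbols`, `r`,
#'   `n`, `p_raw`, `q`, `degenerate`.
#' @slot pooling the pooling mode the correlations were computed under.
#' @export
setClass("CorrelationResult",
  representation(targetProbe = "character", table = "data.frame",
                 pooling = "character")
)

setValidity("CorrelationResult", function(object) {
  t <- object@table
  need <- c("probe_id", "gene_symbols", "r", "n", "p_raw", "q", "degenerate")
  if (!all(need %in% names(t)))
    return(sprintf("table must have columns: %s", paste(need, collapse = ", ")))
  if (anyDuplicated(t$probe_id)) return("probe_id must be unique")
  r <- t$r[!is.na(t$r)]
  if (length(r) && any(abs(r) > 1 + 1e-12)) return("|r| must not exceed 1")
  p <- t$p_raw[!is.na(t$p_raw)]
  if (length(p) && (any(p < 0) || any(p > 1))) return("p_raw must lie in [0, 1]")
  TRUE
})

#' False discovery rate estimates for a vector of p-values
#'
#' @slot p the input p-values, in input order.
#' @slot q matching q-values.
#' @slot pi0 estimated proportion of true null hypotheses (1 for BH).
#' @slot method `"storey"` or `"bh"`.
#' @slot alpha significance threshold used by [selectSignificant()].
#' @seealso [qvalues()]
#' @export
setClass("FDRResult",
  representation(p = "numeric", q = "numeric", pi0 = "numeric",
                 method = "character", alpha = "numeric")
)

setValidity("FDRResult", function(object) {
  if (length(object@p) != length(object@q))
    return("p and q must have equal length")
  if (any(object@q < 0 | object@q > 1)) return("q-values must lie in [0, 1]")
  if (object@pi0 <= 0 || object@pi0 > 1) return("pi0 must lie in (0, 1]")
  if (object@method == "bh" && object@pi0 != 1) return("BH requires pi0 = 1")
  o <- order(object@p)
  if (is.unsorted(object@q[o])) return("q must be monotone non-decreasing in p")
  TRUE
})

#' Target-centred gene interaction network
#'
#' An undirected gene graph whose gene-gene edges come from unioned PPI
#' sources (edge attribute `sources`, support count `support`, edge
#' `type = "ppi"`) plus, after [attachTarget()], candidate-regulation edges
#' from the distinguished target node (`type = "candidate"`, carrying the
#' candidate's correlation `r` and `q`).
#'
#' @slot graph an [igraph::igraph] with named vertices.
#' @slot target the target node name, or `NA` before attachment.
#' @export
setClass("InteractionNetwork",
  representation(graph = "ANY", target = "character")
)

setValidity("InteractionNetwork", function(object) {
  if (!igraph::is_igraph(object@graph)) return("graph must be an igraph object")
  g <- object@graph
  if (igraph::any_loop(g)) return("self-loops are not allowed")
  et <- igraph::edge_attr(g, "type")
  if (igraph::ecount(g) && is.null(et)) return("edges must carry a type attribute")
  gg <- igraph::subgraph_from_edges(g, igraph::E(g)[et == "ppi"],
                                    delete.vertices = FALSE)
  if (igraph::any_multiple(gg))
    return("at most one gene-gene edge per unordered pair")
  TRUE
})

#' Ground truth for a synthetic expression compendium
#'
#' Parameters of the generative model used by [generateCompendium()],
#' [generateGenesets()] and [generatePPI()]. All randomness flows from the
#' single `seed`; identical parameters and seed give bit-identical output.
#'
#' @slot targetProbe probe identifier of the simulated target transcript.
#' @slot targetSymbol gene symbol of the target (used as the network node).
#' @slot plantedGenes symbols generated to correlate with the target.
#' @slot plantedR generative correlation coefficient in (0, 1).
#' @slot plantedPathway set_id of the gene set drawn from planted genes.
#' @slot nullGenes symbols of independent-noise genes.
#' @slot nDatasets,samplesPerDataset,targetSD per-dataset design:
#'   `samplesPerDataset` and `targetSD` are vectors of length `nDatasets`.
#' @slot noiseSD,batchSD residual noise sd and the sd of the per-gene,
#'   per-dataset batch offsets (log2 units).
#' @slot duplicateProbes number of planted genes that get a second probe.
#' @slot seed integer master seed.
#' @export
setClass("SyntheticTruth",
  representation(
    targetProbe = "character", targetSymbol = "character",
    plantedGenes = "character", plantedR = "numeric",
    plantedPathway = "character", nullGenes = "character",
    nDatasets = "integer", samplesPerDataset = "integer",
    targetSD = "numeric", noiseSD = "numeric", batchSD = "numeric",
    duplicateProbes = "integer", seed = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (object@plantedR <= 0 || object@plantedR >= 1)
    msg <- c(msg, "plantedR must lie strictly inside (0, 1)")
  if (length(intersect(object@plantedGenes, object@nullGenes)))
    msg <- c(msg, "planted genes must be disjoint from null genes")
  if (length(object@samplesPerDataset) != object@nDatasets ||
      length(object@targetSD) != object@nDatasets)
    msg <- c(msg, "samplesPerDataset and targetSD must have length nDatasets")
  if (any(object@samplesPerDataset < 1L))
    msg <- c(msg, "each dataset needs at least one sample")
  if (any(object@targetSD < 0)) msg <- c(msg, "targetSD must be non-negative")
  if (object@duplicateProbes > length(object@plantedGenes))
    msg <- c(msg, "duplicateProbes cannot exceed the number of planted genes")
  if (length(msg)) msg else TRUE
})

#' Declarative configuration of a full pipeline run
#'
#' Houses the pipeline's constants — the 0.25 standard-deviation dataset
#' filter, the q < 0.05 significance rule, the top-1000 candidate list, the
#' Bonferroni-adjusted p < 0.05 enrichment cutoff — together with input and
#' output paths. Round-trips losslessly through JSON via
#' [writeRunConfig()] / [readRunConfig()].
#'
#' @slot targetProbe target probe identifier.
#' @slot targetSymbol label used for the target network node.
#' @slot sdThreshold dataset filter cutoff (default 0.25).
#' @slot qThreshold co-expression significance cutoff (default 0.05).
#' @slot topK size of the candidate gene list (default 1000).
#' @slot topCandidates number of top genes wired to the target node
#'   (default 20).
#' @slot enrichAlpha Bonferroni-adjusted significance cutoff (default 0.05).
#' @slot pooling one of `"standardize"`, `"raw"`, `"fisher_meta"`.
#' @slot ranking `"signed"` (r descending) or `"absolute"` (|r| descending).
#' @slot expressionDir directory of tab-delimited expression matrices.
#' @slot annotationPath probe annotation TSV.
#' @slot gmtPaths one or more GMT files.
#' @slot ppiPaths one or more PPI edge-list TSVs.
#' @slot outDir run output directory.
#' @slot seed seed for any stochastic stage.
#' @export
setClass("RunConfig",
  representation(
    targetProbe = "character", targetSymbol = "character",
    sdThreshold = "numeric", qThreshold = "numeric",
    topK = "integer", topCandidates = "integer", enrichAlpha = "numeric",
    pooling = "character", ranking = "character",
    expressionDir = "character", annotationPath = "character",
    gmtPaths = "character", ppiPaths = "character",
    outDir = "character", seed = "integer"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@sdThreshold < 0) msg <- c(msg, "sdThreshold must be non-negative")
  if (object@qThreshold <= 0 || object@qThreshold > 1)
    msg <- c(msg, "qThreshold must lie in (0, 1]")
  if (object@enrichAlpha <= 0 || object@enrichAlpha > 1)
    msg <- c(msg, "enrichAlpha must lie in (0, 1]")
  if (object@topK < 1L) msg <- c(msg, "topK must be positive")
  if (!object@pooling %in% c("standardize", "raw", "fisher_meta"))
    msg <- c(msg, "pooling must be standardize, raw or fisher_meta")
  if (!object@ranking %in% c("signed", "absolute"))
    msg <- c(msg, "ranking must be signed or absolute")
  if (length(msg)) msg else TRUE
})
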