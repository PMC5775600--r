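#' Define the ground truth of a synthetic compendium
#'
#' Fixes every parameter of the generative model: the number of studies
#' and their sample counts, the per-study standard deviation of the
#' target transcript, the set of planted genes generated to correlate
#' with the target at coefficient `plantedR`, the independent-noise null
#' genes, the batch-offset scale, and the master seed. The defaults
#' describe a compendium of 20 studies of 40 samples each with 100
#' planted genes at generative r = 0.6 against 4900 nulls — large enough
#' that planted and null genes separate cleanly at q < 0.05, small enough
#' to regenerate in seconds.
#'
#' @param seed integer master seed; all randomness flows from it.
#' @param nDatasets number of studies.
#' @param samplesPerDataset samples per study (recycled to `nDatasets`).
#' @param nPlanted number of planted correlated genes.
#' @param plantedR generative correlation in (0, 1).
#' @param nNull number of independent-noise genes.
#' @param targetSD per-study sd of the target's log2 expression
#'   (recycled); studies below the 0.25 screen can be planted by passing
#'   smaller values.
#' @param noiseSD residual amplitude of gene rows (log2 units).
#' @param batchSD sd of the per-gene, per-study batch offsets; 0 disables
#'   batch structure.
#' @param duplicateProbes how many planted genes get a second probe (for
#'   probe-collapse testing).
#' @param targetProbe,targetSymbol,plantedPathway identifiers.
#' @return a [SyntheticTruth].
#' @export
syntheticTruth <- function(seed = 1L, nDatasets = 20L,
                           samplesPerDataset = 40L, nPlanted = 100L,
                           plantedR = 0.6, nNull = 4900L, targetSD = 0.5,
                           noiseSD = 1, batchSD = 1, duplicateProbes = 0L,
                           targetProbe = "LNC_TARGET_AT",
                           targetSymbol = "LNCTARGET",
                           plantedPathway = "PLANTED_PATHWAY") {
  if (plantedR <= 0 || plantedR >= 1)
    stop("plantedR must lie strictly inside (0, 1)")
  new("SyntheticTruth",
      targetProbe = targetProbe, targetSymbol = toupper(targetSymbol),
      plantedGenes = sprintf("PG%04d", seq_len(nPlanted)),
      plantedR = plantedR, plantedPathway = plantedPathway,
      nullGenes = sprintf("NG%04d", seq_len(nNull)),
      nDatasets = as.integer(nDatasets),
      samplesPerDataset = rep_len(as.integer(samplesPerDataset), nDatasets),
      targetSD = rep_len(as.numeric(targetSD), nDatasets),
      noiseSD = noiseSD, batchSD = batchSD,
      duplicateProbes = as.integer(duplicateProbes),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth: ", object@nDatasets, " datasets, ",
      length(object@plantedGenes), " planted genes at r = ",
      object@plantedR, ", ", length(object@nullGenes),
      " null genes, seed ", object@seed, "\n", sep = "")
})

# Probe id for a synthetic gene symbol (paste0 would recycle a
# zero-length symbol vector to one element, hence the guard).
.probeFor <- function(symbol, dup = FALSE) {
  if (!length(symbol)) return(character(0))
  paste0(symbol, if (dup) "_X_AT" else "_AT")
}

#' Generate the synthetic multi-dataset compendium
#'
#' Per study: the target row is Gaussian around a study-specific baseline
#' with the study's prescribed sd; each planted gene row is
#' `plantedR * z(target) + sqrt(1 - plantedR^2) * noise` (so its
#' generative correlation with the target is exactly `plantedR`), scaled
#' by `noiseSD` and shifted by a gene-and-study-specific batch offset
#' drawn from N(0, batchSD); null rows are pure noise with the same batch
#' structure. The batch offsets make plain (`raw`) pooling demonstrably
#' worse than per-study standardization, which is what the pooling
#' default is tested against. One probe per gene, plus a second probe for
#' the first `duplicateProbes` planted genes.
#'
#' @param truth a [SyntheticTruth].
#' @return list with components `datasets` (list of [ExpressionDataset]),
#'   `annotation` (a [ProbeAnnotation]) and `truth`.
#' @export
generateCompendium <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  set.seed(truth@seed)
  genes <- c(truth@plantedGenes, truth@nullGenes)
  nP <- length(truth@plantedGenes)
  baseline <- stats::setNames(stats::runif(length(genes), 5, 10), genes)
  dupGenes <- truth@plantedGenes[seq_len(truth@duplicateProbes)]
  a <- truth@plantedR
  b <- sqrt(1 - a^2)
  datasets <- vector("list", truth@nDatasets)
  for (d in seq_len(truth@nDatasets)) {
    nS <- truth@samplesPerDataset[d]
    tOff <- stats::rnorm(1, 0, truth@batchSD)
    targetRow <- 7 + tOff + stats::rnorm(nS, 0, truth@targetSD[d])
    z <- if (stats::sd(targetRow) > 0)
      as.numeric(scale(targetRow)) else rep(0, nS)
    mkRow <- function(sym, planted) {
      off <- stats::rnorm(1, 0, truth@batchSD)
      eps <- stats::rnorm(nS)
      signal <- if (planted) a * z + b * eps else eps
      baseline[[sym]] + off + truth@noiseSD * signal
    }
    rows <- c(
      stats::setNames(list(targetRow), truth@targetProbe),
      stats::setNames(lapply(truth@plantedGenes, mkRow, planted = TRUE),
                      .probeFor(truth@plantedGenes)),
      stats::setNames(lapply(dupGenes, mkRow, planted = TRUE),
                      .probeFor(dupGenes, dup = TRUE)),
      stats::setNames(lapply(truth@nullGenes, mkRow, planted = FALSE),
                      .probeFor(truth@nullGenes))
    )
    m <- do.call(rbind, rows)
    colnames(m) <- sprintf("S%03d", seq_len(nS))
    datasets[[d]] <- ExpressionDataset(m, sprintf("SYN%03d", d))
  }
  ann <- ProbeAnnotation(data.frame(
    probe_id = c(truth@targetProbe, .probeFor(genes),
                 .probeFor(dupGenes, dup = TRUE)),
    symbol = c(truth@targetSymbol, genes, dupGenes),
    biotype = c("lncRNA", rep("coding", length(genes) + length(dupGenes))),
    stringsAsFactors = FALSE))
  list(datasets = datasets, annotation = ann, truth = truth)
}

#' Generate gene sets with one planted enriched pathway
#'
#' The planted set draws `plantedFraction` of its members from the
#' planted correlated genes (the rest are null decoys); decoy sets are
#' sampled uniformly from the null genes. Because the query list fed to
#' [enrich()] consists mostly of planted genes, the planted set is the
#' one that should rank first by adjusted p.
#'
#' @param truth a [SyntheticTruth].
#' @param nDecoySets number of decoy sets; default 50.
#' @param setSizeRange inclusive size range for decoy sets; default
#'   c(10, 40).
#' @param plantedSetSize members in the planted set; default 40.
#' @param plantedFraction fraction of the planted set drawn from planted
#'   genes; default 1.
#' @return a [GeneSetCollection].
#' @export
generateGenesets <- function(truth, nDecoySets = 50L,
                             setSizeRange = c(10L, 40L),
                             plantedSetSize = 40L, plantedFraction = 1) {
  stopifnot(is(truth, "SyntheticTruth"),
            plantedFraction >= 0, plantedFraction <= 1)
  if (max(setSizeRange) > length(truth@nullGenes) ||
      plantedSetSize > length(truth@plantedGenes) + length(truth@nullGenes))
    stop("requested set sizes exceed the available universe")
  set.seed(truth@seed + 1L)
  nFromPlanted <- round(plantedFraction * plantedSetSize)
  planted <- c(sample(truth@plantedGenes, nFromPlanted),
               sample(truth@nullGenes, plantedSetSize - nFromPlanted))
  sets <- stats::setNames(list(sort(planted)), truth@plantedPathway)
  desc <- stats::setNames("planted enriched pathway", truth@plantedPathway)
  if (nDecoySets > 0L) {
    sizes <- sample(seq(setSizeRange[1L], setSizeRange[2L]), nDecoySets,
                    replace = TRUE)
    decoys <- lapply(sizes, function(s) sort(sample(truth@nullGenes, s)))
    names(decoys) <- sprintf("DECOY_%03d", seq_len(nDecoySets))
    sets <- c(sets, decoys)
    desc <- c(desc, stats::setNames(rep("decoy set", nDecoySets),
                                    names(decoys)))
  }
  GeneSetCollection(sets, desc)
}

#' Generate a random multi-source PPI edge table
#'
#' Erdos-Renyi edges over the planted and null genes; each edge is
#' assigned to between 1 and `nSources` synthetic source databases so
#' that union integration and support counting are exercised.
#'
#' @param truth a [SyntheticTruth].
#' @param edgeDensity edge probability in [0, 1]; default 0.01.
#' @param nSources number of synthetic source databases; default 3.
#' @return a [PPIEdgeTable].
#' @export
generatePPI <- function(truth, edgeDensity = 0.01, nSources = 3L) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (edgeDensity < 0 || edgeDensity > 1)
    stop("edgeDensity must lie in [0, 1]")
  set.seed(truth@seed + 2L)
  genes <- c(truth@plantedGenes, truth@nullGenes)
  g <- igraph::sample_gnp(length(genes), edgeDensity)
  ends <- igraph::ends(g, igraph::E(g))
  if (nrow(ends) == 0L)
    return(PPIEdgeTable(data.frame(gene_a = character(),
                                   gene_b = character(),
                                   source_db = character(),
                                   stringsAsFactors = FALSE)))
  srcNames <- sprintf("SYNDB%d", seq_len(nSources))
  nsrc <- sample.int(nSources, nrow(ends), replace = TRUE)
  keys <- matrix(stats::runif(nrow(ends) * nSources), nrow(ends))
  pick <- lapply(seq_len(nrow(ends)), function(i)
    srcNames[order(keys[i, ])[seq_len(nsrc[i])]])
  idx <- rep(seq_len(nrow(ends)), nsrc)
  PPIEdgeTable(data.frame(gene_a = genes[ends[idx, 1L]],
                          gene_b = genes[ends[idx, 2L]],
                          source_db = unlist(pick, use.names = FALSE),
                          stringsAsFactors = FALSE))
}

#' Write a synthetic compendium to disk
#'
#' Materializes the generated objects in the formats the pipeline reads:
#' one TSV expression matrix per study under `dir/expression/`, the probe
#' annotation, a GMT file, one PPI edge list per synthetic source, and a
#' `truth.json` recording the generation parameters.
#'
#' @param sim list from [generateCompendium()].
#' @param dir output directory (created if needed).
#' @param collection optional [GeneSetCollection] from
#'   [generateGenesets()].
#' @param ppi optional [PPIEdgeTable] from [generatePPI()].
#' @return `dir`, invisibly.
#' @export
writeCompendium <- function(sim, dir, collection = NULL, ppi = NULL) {
  dir.create(file.path(dir, "expression"), recursive = TRUE,
             showWarnings = FALSE)
  for (d in sim$datasets)
    writeExpressionMatrix(d, file.path(dir, "expression",
                                       paste0(datasetId(d), ".tsv")))
  writeProbeAnnotation(sim$annotation, file.path(dir, "annotation.tsv"))
  if (!is.null(collection))
    writeGMT(collection, file.path(dir, "genesets.gmt"))
  if (!is.null(ppi)) {
    for (src in unique(ppi@edges$source_db)) {
      part <- ppi@edges[ppi@edges$source_db == src, , drop = FALSE]
      .writeTSV(part, file.path(dir, paste0("ppi_", tolower(src), ".tsv")))
    }
  }
  truth <- sim$truth
  jsonlite::write_json(
    list(target_probe = truth@targetProbe,
         target_symbol = truth@targetSymbol,
         planted_genes = truth@plantedGenes,
         planted_r = truth@plantedR,
         planted_pathway = truth@plantedPathway,
         null_gene_count = length(truth@nullGenes),
         n_datasets = truth@nDatasets,
         samples_per_dataset = truth@samplesPerDataset,
         target_sd = truth@targetSD, noise_sd = truth@noiseSD,
         batch_sd = truth@batchSD, seed = truth@seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
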