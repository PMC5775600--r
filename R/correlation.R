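#' Pool retained datasets into one compendium matrix
#'
#' Under the default `standardize` mode every probe row is z-scored within
#' each dataset (mean 0, sd 1 per dataset; constant rows become all-zero)
#' before the columns are concatenated. This removes dataset-specific
#' location and scale — the batch structure that would otherwise dominate
#' a plain concatenation of heterogeneous studies — so that the pooled
#' correlation reflects within-study covariation. `raw` concatenates the
#' values unchanged. `fisher_meta` builds no pooled matrix: correlations
#' are computed per dataset and combined by [combineFisher()] downstream.
#'
#' Probes absent from a dataset are carried with that dataset's columns
#' set to `NA`, and those columns are skipped pairwise during correlation.
#'
#' @param datasets list of [ExpressionDataset] objects sharing a probe
#'   namespace (an error is raised if no probe occurs in more than one
#'   dataset when several are supplied).
#' @param mode `"standardize"` (default), `"raw"` or `"fisher_meta"`.
#' @return a [PooledCompendium].
#' @export
poolCompendium <- function(datasets,
                           mode = c("standardize", "raw", "fisher_meta")) {
  mode <- match.arg(mode)
  stopifnot(length(datasets) >= 1L)
  probeLists <- lapply(datasets, rownames)
  allProbes <- unique(unlist(probeLists, use.names = FALSE))
  if (length(datasets) > 1L) {
    occ <- table(unlist(lapply(probeLists, unique), use.names = FALSE))
    if (max(occ) == 1L)
      stop("probe namespaces are disjoint across datasets; ",
           "the compendium cannot be pooled")
  }
  prov <- do.call(rbind, lapply(datasets, function(d)
    data.frame(sample_id = paste(datasetId(d), colnames(d), sep = "."),
               dataset_id = datasetId(d), stringsAsFactors = FALSE)))
  if (mode == "fisher_meta")
    return(new("PooledCompendium",
               values = matrix(numeric(), 0L, 0L), provenance = prov,
               mode = mode, datasets = datasets))
  blocks <- lapply(datasets, function(d) {
    v <- exprValues(d)
    if (mode == "standardize") v <- .zscoreRows(v)
    out <- matrix(NA_real_, length(allProbes), ncol(v),
                  dimnames = list(allProbes, NULL))
    out[rownames(v), ] <- v
    out
  })
  pooled <- do.call(cbind, blocks)
  colnames(pooled) <- prov$sample_id
  new("PooledCompendium", values = pooled, provenance = prov, mode = mode,
      datasets = list())
}

# Row-wise z-score; rows with zero variance become all-zero (they carry no
# signal but remain auditable downstream via the degenerate flag).
.zscoreRows <- function(v) {
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  z <- (v - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Pooled values of a compendium
#' @param pooled a [PooledCompendium].
#' @return numeric probes-by-samples matrix (`NA` where a probe is absent
#'   from the contributing dataset).
#' @export
pooledValues <- function(pooled) {
  stopifnot(is(pooled, "PooledCompendium"))
  pooled@values
}

#' Sample provenance of a pooled compendium
#' @param pooled a [PooledCompendium].
#' @return data.frame with columns `sample_id`, `dataset_id`.
#' @export
pooledProvenance <- function(pooled) {
  stopifnot(is(pooled, "PooledCompendium"))
  pooled@provenance
}

setMethod("show", "PooledCompendium", function(object) {
  nd <- length(unique(object@provenance$dataset_id))
  if (object@mode == "fisher_meta")
    cat("PooledCompendium (fisher_meta): ", nd,
        " datasets, correlations combined per dataset\n", sep = "")
  else
    cat("PooledCompendium (", object@mode, "): ", nrow(object@values),
        " probes x ", ncol(object@values), " samples from ", nd,
        " datasets\n", sep = "")
})

# Vectorized Pearson of every row of `mat` against `target`, with pairwise
# complete observations. Returns r, n and the two-sided t-based p. The
# O(probes x samples) matrix-vector formulation is the hot path for
# 54k-probe compendia; tests check it against stats::cor.test.
.rowCorTarget <- function(mat, target) {
  tOK <- is.finite(target)
  u <- as.numeric(tOK)
  tv <- ifelse(tOK, target, 0)
  O <- is.finite(mat) + 0
  A <- ifelse(O == 1, mat, 0)
  n <- as.vector(O %*% u)
  Sx <- as.vector(A %*% u)
  Sy <- as.vector(O %*% (tv * u))
  Sxx <- as.vector((A * A) %*% u)
  Syy <- as.vector(O %*% (tv * tv * u))
  Sxy <- as.vector(A %*% (tv * u))
  vx <- n * Sxx - Sx^2
  vy <- n * Syy - Sy^2
  # a zero-variance row yields vx = 0 up to cancellation error of order
  # eps * n * Sxx; the relative tolerance separates that from real signal
  degx <- vx <= 1e-10 * pmax(n * Sxx, Sx^2)
  degy <- vy <= 1e-10 * pmax(n * Syy, Sy^2)
  vx[vx < 0] <- 0
  vy[vy < 0] <- 0
  denom <- sqrt(vx * vy)
  r <- ifelse(denom > 0, (n * Sxy - Sx * Sy) / denom, NA_real_)
  r <- pmin(1, pmax(-1, r))
  degenerate <- n >= 3 & (degx | degy)
  r[degenerate] <- 0
  tooFew <- n < 3
  r[tooFew] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  p[degenerate] <- 1
  p[tooFew] <- NA_real_
  list(r = r, n = as.integer(round(n)), p = p,
       degenerate = degenerate & !tooFew)
}

#' Correlate the target probe against every other probe
#'
#' Computes the Pearson product-moment correlation of the target probe's
#' pooled profile against each remaining probe, over pairwise-complete
#' columns, with the exact two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Raw p-values are reported unmodified; q-values are attached later by
#' [qvalues()] / [attachQ()]. For a `fisher_meta` compendium, per-dataset
#' correlations are combined by [combineFisher()].
#'
#' @param pooled a [PooledCompendium].
#' @param targetProbe probe identifier; must be present.
#' @param annotation optional [ProbeAnnotation] used to attach
#'   comma-joined gene symbols.
#' @return a [CorrelationResult]. Probes with zero variance get
#'   `r = 0`, `p_raw = 1` and `degenerate = TRUE`; probes with fewer than
#'   3 paired observations get `NA` r/p and are excluded from ranking.
#' @export
correlateTarget <- function(pooled, targetProbe, annotation = NULL) {
  stopifnot(is(pooled, "PooledCompendium"))
  if (pooled@mode == "fisher_meta")
    return(.correlateMeta(pooled, targetProbe, annotation))
  v <- pooled@values
  if (!targetProbe %in% rownames(v))
    stop("target probe '", targetProbe, "' absent from the pooled compendium")
  target <- v[targetProbe, ]
  mat <- v[setdiff(rownames(v), targetProbe), , drop = FALSE]
  cc <- .rowCorTarget(mat, target)
  .newCorrelationResult(rownames(mat), cc, targetProbe, pooled@mode,
                        annotation)
}

.newCorrelationResult <- function(probes, cc, targetProbe, pooling,
                                  annotation) {
  syms <- if (is.null(annotation)) rep("", length(probes)) else
    symbolsFor(annotation, probes)
  tab <- data.frame(probe_id = probes, gene_symbols = syms, r = cc$r,
                    n = cc$n, p_raw = cc$p, q = NA_real_,
                    degenerate = cc$degenerate, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("CorrelationResult", targetProbe = targetProbe, table = tab,
      pooling = pooling)
}

# fisher_meta route: per-dataset correlations combined in z-space.
.correlateMeta <- function(pooled, targetProbe, annotation) {
  perDataset <- lapply(pooled@datasets, function(d) {
    v <- exprValues(d)
    if (!targetProbe %in% rownames(v)) return(NULL)
    mat <- v[setdiff(rownames(v), targetProbe), , drop = FALSE]
    cc <- .rowCorTarget(mat, v[targetProbe, ])
    data.frame(probe_id = rownames(mat), r = cc$r, n = cc$n,
               degenerate = cc$degenerate, stringsAsFactors = FALSE)
  })
  perDataset <- Filter(Negate(is.null), perDataset)
  if (!length(perDataset))
    stop("target probe '", targetProbe, "' absent from every dataset")
  combined <- combineFisher(perDataset)
  syms <- if (is.null(annotation)) rep("", nrow(combined)) else
    symbolsFor(annotation, combined$probe_id)
  tab <- data.frame(probe_id = combined$probe_id, gene_symbols = syms,
                    r = combined$r, n = combined$n, p_raw = combined$p,
                    q = NA_real_, degenerate = combined$degenerate,
                    stringsAsFactors = FALSE)
  new("CorrelationResult", targetProbe = targetProbe, table = tab,
      pooling = "fisher_meta")
}

#' Combine per-dataset correlations with Fisher's z
#'
#' Each per-dataset r is mapped to z = atanh(r), the z-values are averaged
#' with weights (n_d - 3), and the combined coefficient is the inverse
#' transform of the weighted mean. The combined two-sided p comes from the
#' normal approximation `zbar * sqrt(sum(weights))`. Exact |r| = 1 values
#' are clipped just inside the transform's domain and flagged.
#'
#' @param perDataset list of data.frames with columns `probe_id`, `r`,
#'   `n` (and optionally `degenerate`), one per dataset.
#' @return data.frame with columns `probe_id`, `r`, `n` (summed over
#'   contributing datasets), `p`, `n_datasets`, `clipped`, `degenerate`.
#'   Probes contributing from fewer than 2 datasets with n > 3 get `NA`.
#' @export
combineFisher <- function(perDataset) {
  stopifnot(length(perDataset) >= 1L)
  long <- do.call(rbind, lapply(perDataset, function(d) {
    if (is.null(d$degenerate)) d$degenerate <- FALSE
    d[, c("probe_id", "r", "n", "degenerate")]
  }))
  long <- long[!is.na(long$r) & long$n > 3L, , drop = FALSE]
  zmax <- atanh(1 - 1e-15)
  parts <- split(long, long$probe_id)
  out <- lapply(parts, function(d) {
    clipped <- any(abs(d$r) >= 1)
    z <- pmin(zmax, pmax(-zmax, atanh(pmin(1, pmax(-1, d$r)))))
    w <- d$n - 3
    if (nrow(d) < 2L)
      return(data.frame(probe_id = d$probe_id[1L], r = NA_real_,
                        n = sum(d$n), p = NA_real_, n_datasets = nrow(d),
                        clipped = clipped, degenerate = all(d$degenerate),
                        stringsAsFactors = FALSE))
    zbar <- sum(w * z) / sum(w)
    stat <- zbar * sqrt(sum(w))
    data.frame(probe_id = d$probe_id[1L], r = tanh(zbar), n = sum(d$n),
               p = 2 * stats::pnorm(-abs(stat)), n_datasets = nrow(d),
               clipped = clipped, degenerate = all(d$degenerate),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname resultTable
#' @export
setMethod("resultTable", "CorrelationResult", function(object) object@table)

setMethod("show", "CorrelationResult", function(object) {
  t <- object@table
  cat("CorrelationResult vs '", object@targetProbe, "' (",
      object@pooling, " pooling): ", nrow(t), " probes, ",
      sum(!is.na(t$q) & t$q < 0.05), " with q < 0.05\n", sep = "")
})

#' Rank candidate probes by correlation
#'
#' Sorts records by r descending (the default, positive-correlation
#' ranking used for regulatory-candidate lists) or by |r| descending, with
#' ties broken by smaller raw p and then lexicographic probe id, and
#' returns the first `k`. Records with undefined r (too few paired
#' observations) are excluded.
#'
#' @param result a [CorrelationResult].
#' @param k number of records to return; `k = 0` gives an empty table, and
#'   `k` beyond the number of rankable records returns all with a warning.
#' @param direction `"signed"` (default) or `"absolute"`.
#' @return data.frame of the top records with a `rank` column prepended.
#' @export
rankCandidates <- function(result, k, direction = c("signed", "absolute")) {
  direction <- match.arg(direction)
  stopifnot(is(result, "CorrelationResult"), k >= 0)
  t <- result@table[!is.na(result@table$r), , drop = FALSE]
  key <- if (direction == "signed") -t$r else -abs(t$r)
  t <- t[order(key, t$p_raw, t$probe_id), , drop = FALSE]
  if (k > nrow(t)) {
    warning("k = ", k, " exceeds the ", nrow(t),
            " rankable records; returning all")
    k <- nrow(t)
  }
  out <- utils::head(t, k)
  if (nrow(out)) out <- cbind(rank = seq_len(nrow(out)), out)
  else out <- cbind(rank = integer(0), out)
  rownames(out) <- NULL
  out
}

#' Collapse a probe-level table to gene level
#'
#' For every gene symbol keeps the probe with the largest r (ties broken
#' by smaller raw p, then probe id). Probes mapping to several symbols
#' contribute to each; unannotated probes are dropped.
#'
#' @param ranked data.frame as returned by [rankCandidates()] or
#'   [resultTable()] (needs `probe_id`, `gene_symbols`, `r`, `p_raw`).
#' @return data.frame with columns `gene`, `probe_id`, `r`, `n`, `p_raw`,
#'   `q`, sorted by r descending.
#' @export
collapseToGenes <- function(ranked) {
  stopifnot(all(c("probe_id", "gene_symbols", "r", "p_raw") %in%
                  names(ranked)))
  ranked <- ranked[!is.na(ranked$r) & nzchar(ranked$gene_symbols), ,
                   drop = FALSE]
  if (!nrow(ranked))
    return(data.frame(gene = character(), probe_id = character(),
                      r = numeric(), n = integer(), p_raw = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  syms <- strsplit(ranked$gene_symbols, ",", fixed = TRUE)
  long <- ranked[rep(seq_len(nrow(ranked)), lengths(syms)), , drop = FALSE]
  long$gene <- unlist(syms, use.names = FALSE)
  long <- long[order(-long$r, long$p_raw, long$probe_id), , drop = FALSE]
  long <- long[!duplicated(long$gene), , drop = FALSE]
  if (is.null(long$n)) long$n <- NA_integer_
  if (is.null(long$q)) long$q <- NA_real_
  out <- data.frame(gene = long$gene, probe_id = long$probe_id, r = long$r,
                    n = long$n, p_raw = long$p_raw, q = long$q,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
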