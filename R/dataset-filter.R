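#' Sample standard deviation of the target probe in one dataset
#'
#' The variability screen statistic: the sample (n-1 denominator) standard
#' deviation of the target probe's log2 expression across the dataset's
#' samples. Datasets in which the target barely varies carry no
#' correlation signal and are excluded upstream of the compendium pool.
#'
#' @param dataset an [ExpressionDataset].
#' @param targetProbe probe identifier; must be present in the dataset.
#' @return non-negative number (log2-expression units); `NA` for a
#'   single-sample dataset, where the sd is undefined.
#' @examples
#' m <- matrix(c(0, 2), 1, 2, dimnames = list("T_at", c("S1", "S2")))
#' computeTargetSD(ExpressionDataset(m, "D1"), "T_at")  # sqrt(2)
#' @export
computeTargetSD <- function(dataset, targetProbe) {
  stopifnot(is(dataset, "ExpressionDataset"))
  if (!targetProbe %in% rownames(dataset))
    stop("target probe '", targetProbe, "' absent from dataset '",
         datasetId(dataset), "'")
  row <- exprValues(dataset)[targetProbe, ]
  if (length(row) < 2L) return(NA_real_)
  stats::sd(row)
}

#' Variability-based dataset filter
#'
#' Retains the datasets in which the target probe's sample standard
#' deviation is at least `threshold` (datasets with sd strictly below the
#' cutoff are filtered out, so a dataset sitting exactly on the boundary
#' is kept). Single-sample datasets are excluded with reason
#' `"insufficient samples"`.
#'
#' @param datasets list of [ExpressionDataset] objects.
#' @param targetProbe probe identifier present in every dataset.
#' @param threshold non-negative sd cutoff (log2 units); default 0.25.
#' @return list with components `report` (a [FilterReport] covering every
#'   input exactly once) and `retained` (the retained dataset list, input
#'   order preserved).
#' @export
filterDatasets <- function(datasets, targetProbe, threshold = 0.25) {
  stopifnot(length(datasets) >= 1L, threshold >= 0)
  ids <- vapply(datasets, datasetId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate dataset ids: ", ids[duplicated(ids)][1L])
  sds <- vapply(datasets, computeTargetSD, numeric(1),
                targetProbe = targetProbe)
  ns <- vapply(datasets, ncol, integer(1))
  keep <- !is.na(sds) & sds >= threshold & ns >= 2L
  reason <- ifelse(ns < 2L, "insufficient samples",
                   ifelse(keep, "", sprintf("sd below %g", threshold)))
  report <- new("FilterReport",
                table = data.frame(dataset_id = ids, n_samples = ns,
                                   target_sd = sds, retained = keep,
                                   reason = reason,
                                   stringsAsFactors = FALSE),
                threshold = threshold)
  if (!any(keep))
    stop("zero datasets retained at sd threshold ", threshold,
         "; review the threshold or the target probe")
  list(report = report, retained = datasets[keep])
}

#' @rdname resultTable
#' @export
setMethod("resultTable", "FilterReport", function(object) object@table)

#' Threshold recorded in a FilterReport
#' @param report a [FilterReport].
#' @return the sd cutoff used.
#' @export
filterThreshold <- function(report) {
  stopifnot(is(report, "FilterReport"))
  report@threshold
}

setMethod("show", "FilterReport", function(object) {
  t <- object@table
  cat("FilterReport: ", sum(t$retained), "/", nrow(t),
      " datasets retained at target-probe sd >= ", object@threshold,
      "\n", sep = "")
})

#' Write a FilterReport as TSV
#' @param report a [FilterReport].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFilterReport <- function(report, path) .writeTSV(report@table, path)
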