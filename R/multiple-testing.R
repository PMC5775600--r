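#' q-values for a vector of p-values
#'
#' Converts raw p-values into q-values, the minimum false discovery rate
#' at which each test would be called significant. The default `storey`
#' method estimates the proportion of true nulls pi0 by the smoother
#' procedure: pi0(lambda) = #\{p > lambda\} / (m * (1 - lambda)) is
#' evaluated on the grid lambda = 0, 0.05, ..., 0.90, a cubic smoothing
#' spline (3 df) is fitted, and the fit is read off at lambda = 0.90,
#' then clipped into (0, 1]. q-values are the step-up quantities
#' `pi0 * m * p_(j) / j` with a cumulative minimum from the largest p
#' down. `bh` is the same machinery with pi0 fixed at 1, i.e. the
#' Benjamini-Hochberg step-up adjustment.
#'
#' With fewer than 100 p-values the pi0 smoother is unstable, so `storey`
#' falls back to `bh` with a warning.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method `"storey"` (default) or `"bh"`.
#' @param alpha significance threshold stored for [selectSignificant()].
#' @return an [FDRResult] with q-values in input order.
#' @references Storey JD, Tibshirani R (2003) Statistical significance for
#'   genomewide studies. PNAS 100:9440-9445.
#' @export
qvalues <- function(p, method = c("storey", "bh"), alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(length(p) >= 1L)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("all p-values must lie in [0, 1]")
  m <- length(p)
  if (method == "storey" && m < 100L) {
    warning("fewer than 100 p-values: pi0 smoothing is unstable, ",
            "falling back to BH (pi0 = 1)")
    method <- "bh"
  }
  pi0 <- if (method == "storey") .estimatePi0(p) else 1
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  rank <- m:1L
  q <- pmin(1, cummin(pi0 * m * p[o] / rank))[ro]
  new("FDRResult", p = p, q = q, pi0 = pi0, method = method, alpha = alpha)
}

# Storey smoother pi0 estimate; clipped to [1e-4, 1] so q-values can never
# collapse to zero on adversarial inputs.
.estimatePi0 <- function(p, lambda = seq(0, 0.90, by = 0.05)) {
  m <- length(p)
  pi0l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(1, max(1e-4, pi0))
}

#' pi0 estimate stored in an FDRResult
#' @param fdr an [FDRResult].
#' @return the estimated proportion of true nulls (1 for BH).
#' @export
pi0Estimate <- function(fdr) {
  stopifnot(is(fdr, "FDRResult"))
  fdr@pi0
}

#' q-values stored in an FDRResult, input order
#' @param fdr an [FDRResult].
#' @return numeric vector of q-values.
#' @export
qValues <- function(fdr) {
  stopifnot(is(fdr, "FDRResult"))
  fdr@q
}

setMethod("show", "FDRResult", function(object) {
  cat("FDRResult (", object@method, "): ", length(object@p),
      " tests, pi0 = ", signif(object@pi0, 4), ", ",
      sum(object@q < object@alpha), " with q < ", object@alpha, "\n",
      sep = "")
})

#' Attach q-values to a correlation result
#'
#' Computes q-values over the correlation records with a defined p-value
#' and writes them into the `q` column. Degenerate probes (p = 1) take
#' part in the correction like any other test; probes with undefined p
#' (too few observations) keep `NA` q.
#'
#' @param result a [CorrelationResult].
#' @param method passed to [qvalues()].
#' @param alpha significance threshold recorded in the result.
#' @return list with components `result` (updated [CorrelationResult])
#'   and `fdr` (the [FDRResult]).
#' @export
attachQ <- function(result, method = c("storey", "bh"), alpha = 0.05) {
  stopifnot(is(result, "CorrelationResult"))
  t <- result@table
  ok <- !is.na(t$p_raw)
  if (!any(ok)) stop("no defined p-values to correct")
  fdr <- qvalues(t$p_raw[ok], method = method, alpha = alpha)
  t$q[ok] <- fdr@q
  result@table <- t
  list(result = result, fdr = fdr)
}

#' Select significant co-expression records
#'
#' Keeps the records whose q-value is strictly below `alpha` (a record
#' with q exactly at the threshold is not significant), sorted by r
#' descending so the correlation rank order is preserved.
#'
#' @param result a [CorrelationResult] whose records align with `fdr`
#'   (same length and p-values, in order, over the defined-p records).
#' @param fdr the matching [FDRResult].
#' @param alpha significance threshold; default 0.05.
#' @return data.frame of the significant records.
#' @export
selectSignificant <- function(result, fdr, alpha = 0.05) {
  stopifnot(is(result, "CorrelationResult"), is(fdr, "FDRResult"))
  t <- result@table
  ok <- !is.na(t$p_raw)
  if (sum(ok) != length(fdr@p))
    stop("correlation records and FDR result are misaligned: ",
         sum(ok), " defined p-values vs ", length(fdr@p), " corrected")
  if (any(abs(t$p_raw[ok] - fdr@p) > 1e-12))
    stop("correlation records and FDR result are misaligned: ",
         "p-values differ")
  t$q[ok] <- fdr@q
  sig <- t[ok, , drop = FALSE][fdr@q < alpha, , drop = FALSE]
  sig <- sig[order(-sig$r, sig$p_raw, sig$probe_id), , drop = FALSE]
  rownames(sig) <- NULL
  sig
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size `m` and caps at 1. `m` may
#' exceed the length of `p` when only a subset of the tested family is
#' being adjusted.
#'
#' @param p numeric vector of p-values.
#' @param m positive integer family size; defaults to `length(p)`.
#' @return adjusted p-values, same order as the input.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (length(m) != 1L || is.na(m) || m <= 0)
    stop("family size m must be a single positive number")
  if (m < length(p))
    stop("family size m (", m, ") is smaller than the number of p-values (",
         length(p), ")")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("all p-values must lie in [0, 1]")
  pmin(1, p * m)
}
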