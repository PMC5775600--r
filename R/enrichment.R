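#' Upper-tail hypergeometric probability
#'
#' Exact probability of observing `k` or more query genes inside a gene
#' set, P(X >= k) for X ~ Hypergeometric(N, K, n): `N` genes in the
#' universe of which `K` belong to the set, with `n` genes drawn (the
#' query list). The observed overlap is included in the tail, the
#' standard over-representation convention, so `k = 0` gives exactly 1.
#'
#' @param N universe size.
#' @param K set size within the universe.
#' @param n query-list size within the universe.
#' @param k overlap count.
#' @return P(X >= k) in (0, 1].
#' @examples
#' hypergeomUpperTail(20, 5, 5, 5)  # 1 / choose(20, 5)
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  if (K > N) stop("bound violated: K <= N required (K = ", K, ", N = ", N, ")")
  if (n > N) stop("bound violated: n <= N required (n = ", n, ", N = ", N, ")")
  if (k < 0) stop("bound violated: k >= 0 required (k = ", k, ")")
  if (k > min(K, n))
    stop("bound violated: k <= min(K, n) required (k = ", k,
         ", K = ", K, ", n = ", n, ")")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of a query gene list
#'
#' Tests every set in the collection for over-representation of the query
#' genes, relative to the collection universe or an explicit background
#' (for example all genes on the array). Query and background genes
#' absent from the universe are discarded before testing, so symbols
#' unknown to the collection cannot influence any p-value. Raw p-values
#' are Bonferroni-adjusted with family size equal to the number of sets
#' tested in this collection.
#'
#' @param queryGenes character vector of gene symbols (case-insensitive).
#' @param collection a [GeneSetCollection].
#' @param background optional character vector restricting the universe.
#' @param alpha Bonferroni-adjusted significance threshold (strict `<`)
#'   used for the `significant` flag; default 0.05.
#' @return data.frame with one row per set: `set_id`, `description`, `N`,
#'   `K`, `n`, `k`, `p_raw`, `p_adj`, `significant`, `overlap_genes`
#'   (comma-joined), sorted by `p_adj` then `p_raw` ascending.
#' @export
enrich <- function(queryGenes, collection, background = NULL,
                   alpha = 0.05) {
  stopifnot(is(collection, "GeneSetCollection"))
  uni <- collection@universe
  bg <- if (is.null(background)) uni else intersect(toupper(background), uni)
  query <- intersect(unique(toupper(queryGenes)), uni)
  if (!length(query))
    stop("query shares no symbols with the collection universe (",
         length(queryGenes), " query symbols vs universe of ",
         length(uni), "); check probe-to-symbol mapping and case")
  query <- intersect(query, bg)
  if (!length(query))
    stop("query shares no symbols with the background")
  N <- length(bg)
  n <- length(query)
  m <- length(collection@sets)
  rows <- lapply(names(collection@sets), function(id) {
    members <- intersect(collection@sets[[id]], bg)
    overlap <- intersect(query, members)
    K <- length(members)
    k <- length(overlap)
    p <- if (K == 0L) 1 else hypergeomUpperTail(N, K, n, k)
    data.frame(set_id = id, description = collection@descriptions[[id]],
               N = N, K = K, n = n, k = k, p_raw = p,
               overlap_genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_raw, m)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_adj, out$p_raw, out$set_id),
             c("set_id", "description", "N", "K", "n", "k", "p_raw",
               "p_adj", "significant", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Filter enrichment records to the significant ones
#'
#' Keeps records with Bonferroni-adjusted p strictly below `alpha`,
#' optionally with an additional raw-p reporting screen (as used when
#' quoting "p < 0.01" pathways).
#'
#' @param records data.frame from [enrich()].
#' @param alpha adjusted-p threshold in (0, 1]; default 0.05.
#' @param pRawCut optional raw-p threshold applied on top.
#' @return the filtered data.frame (possibly empty).
#' @export
filterSignificant <- function(records, alpha = 0.05, pRawCut = NULL) {
  stopifnot(alpha > 0, alpha <= 1,
            all(c("p_raw", "p_adj") %in% names(records)))
  keep <- records$p_adj < alpha
  if (!is.null(pRawCut)) keep <- keep & records$p_raw < pRawCut
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#' @param records data.frame from [enrich()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnrichment <- function(records, path) .writeTSV(records, path)
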