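#' Construct an ExpressionDataset from a numeric matrix
#'
#' @param values numeric matrix of log2-scale expression, probes in rows
#'   (row names) and samples in columns (column names).
#' @param datasetId single character study label.
#' @return an [ExpressionDataset].
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("P1", "P2", "P3"), c("S1", "S2")))
#' ExpressionDataset(m, "E-SYN-1")
#' @export
ExpressionDataset <- function(values, datasetId) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  new("ExpressionDataset", se, datasetId = as.character(datasetId))
}

#' @rdname ExpressionDataset-class
#' @export
setMethod("datasetId", "ExpressionDataset", function(object) object@datasetId)

#' @rdname ExpressionDataset-class
#' @export
setMethod("probeIds", "ExpressionDataset", function(object) rownames(object))

#' @rdname ExpressionDataset-class
#' @export
setMethod("sampleIds", "ExpressionDataset", function(object) colnames(object))

#' Expression values of an ExpressionDataset
#' @param dataset an [ExpressionDataset].
#' @return numeric probes-by-samples matrix.
#' @export
exprValues <- function(dataset) {
  stopifnot(is(dataset, "ExpressionDataset"))
  SummarizedExperiment::assay(dataset, "exprs")
}

setMethod("show", "ExpressionDataset", function(object) {
  cat("ExpressionDataset '", object@datasetId, "': ",
      nrow(object), " probes x ", ncol(object), " samples\n", sep = "")
})

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample identifiers and a first column of probe
#' identifiers; the remaining cells are log2-scale expression values.
#' Probe rows containing any missing or non-numeric entry are dropped with
#' a message: complete rows are required for paired correlation, and the
#' upstream normalization these matrices come from produces complete
#' output, so missingness signals a problem worth surfacing.
#'
#' @param path path to the tab-delimited file.
#' @param datasetId study label; defaults to the file name stem (public
#'   repository accessions are conventionally encoded there).
#' @return an [ExpressionDataset].
#' @export
readExpressionMatrix <- function(path, datasetId = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(datasetId))
    datasetId <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty expression matrix in ", path)
  probes <- raw[[1L]]
  dup <- probes[duplicated(probes)]
  if (length(dup))
    stop("duplicate probe ID in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- !is.finite(num)
  badRow <- rowSums(bad) > 0L
  if (all(badRow))
    stop("no complete probe rows in ", path)
  if (any(badRow)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    message(sum(badRow), " probe row(s) with missing/non-numeric values ",
            "dropped from ", datasetId,
            " (first at row ", idx[1L], ", column ", idx[2L] + 1L,
            ", probe ", probes[idx[1L]], ")")
  }
  num <- num[!badRow, , drop = FALSE]
  dimnames(num) <- list(probes[!badRow], colnames(raw)[-1L])
  ExpressionDataset(num, datasetId)
}

#' Write an ExpressionDataset as tab-delimited text
#'
#' Emits UTF-8, LF-terminated, tab-delimited text with a `probe_id` first
#' column; [readExpressionMatrix()] on the output reproduces the values
#' bit-identically (full double precision is printed).
#'
#' @param dataset an [ExpressionDataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(dataset, path) {
  v <- exprValues(dataset)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(v)), collapse = "\t"), con,
             sep = "\n")
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], format(v[i, ], digits = 17, trim = TRUE,
                                   scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Construct a ProbeAnnotation
#'
#' @param map data.frame with columns `probe_id`, `symbol` and optionally
#'   `biotype`; symbols are upper-cased, missing biotypes become `"other"`.
#' @return a [ProbeAnnotation].
#' @export
ProbeAnnotation <- function(map) {
  stopifnot(all(c("probe_id", "symbol") %in% names(map)))
  if (is.null(map$biotype)) map$biotype <- "other"
  map <- data.frame(probe_id = as.character(map$probe_id),
                    symbol = toupper(as.character(map$symbol)),
                    biotype = as.character(map$biotype),
                    stringsAsFactors = FALSE)
  map <- unique(map)
  new("ProbeAnnotation", map = map)
}

#' Read a probe annotation table
#'
#' Tab-delimited with a header; requires `probe_id` and `symbol` columns,
#' `biotype` optional.
#'
#' @param path annotation TSV path.
#' @return a [ProbeAnnotation].
#' @export
readProbeAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ProbeAnnotation(utils::read.delim(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
}

#' Write a probe annotation table
#' @param annotation a [ProbeAnnotation].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeProbeAnnotation <- function(annotation, path) {
  .writeTSV(annotation@map, path)
}

#' Gene symbols for a vector of probes
#'
#' @param annotation a [ProbeAnnotation].
#' @param probes character vector of probe identifiers.
#' @return character vector parallel to `probes`: comma-joined symbols, or
#'   `""` for unannotated probes.
#' @export
symbolsFor <- function(annotation, probes) {
  stopifnot(is(annotation, "ProbeAnnotation"))
  m <- annotation@map
  joined <- vapply(split(m$symbol, m$probe_id),
                   function(s) paste(sort(unique(s)), collapse = ","),
                   character(1))
  out <- joined[probes]
  out[is.na(out)] <- ""
  unname(out)
}

setMethod("show", "ProbeAnnotation", function(object) {
  cat("ProbeAnnotation: ", length(unique(object@map$probe_id)),
      " probes -> ", length(unique(object@map$symbol)), " symbols\n",
      sep = "")
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors (members are upper-cased and
#'   de-duplicated).
#' @param descriptions optional named character vector of descriptions.
#' @param universe optional explicit background; defaults to the union of
#'   all members.
#' @return a [GeneSetCollection].
#' @export
GeneSetCollection <- function(sets, descriptions = NULL, universe = NULL) {
  sets <- lapply(sets, function(s) unique(toupper(s)))
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  members <- unique(unlist(sets, use.names = FALSE))
  universe <- if (is.null(universe)) members else
    unique(c(toupper(universe), members))
  new("GeneSetCollection", sets = sets,
      descriptions = descriptions[names(sets)], universe = universe)
}

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneUniverse", "GeneSetCollection",
          function(object) object@universe)

#' @rdname GeneSetCollection-class
#' @export
setMethod("setDescriptions", "GeneSetCollection",
          function(object) object@descriptions)

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection: ", length(object@sets), " sets, universe of ",
      length(object@universe), " genes\n", sep = "")
})

#' Read gene sets in GMT format
#'
#' Each line is `set_id <TAB> description <TAB> member <TAB> member ...`.
#' Members are upper-cased and de-duplicated within a set; the universe is
#' the union of all members unless `background` supplies an explicit one.
#'
#' @param path GMT file path.
#' @param background optional character vector or path to a one-symbol-per-
#'   line background file.
#' @return a [GeneSetCollection].
#' @export
readGMT <- function(path, background = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields in ", path)
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate set_id in ", path, ": ", ids[duplicated(ids)][1L])
  members <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  empty <- which(lengths(members) == 0L)
  if (length(empty))
    stop("GMT line ", empty[1L], " has an empty member list in ", path)
  sets <- setNames(members, ids)
  desc <- setNames(vapply(fields, `[[`, character(1), 2L), ids)
  if (is.character(background) && length(background) == 1L &&
      file.exists(background))
    background <- readLines(background, warn = FALSE)
  GeneSetCollection(sets, desc, universe = background)
}

#' Write a GeneSetCollection in GMT format
#' @param collection a [GeneSetCollection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(collection, path) {
  lines <- vapply(names(collection@sets), function(id) {
    paste(c(id, collection@descriptions[[id]], collection@sets[[id]]),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Construct a PPIEdgeTable from raw records
#'
#' Upper-cases symbols, removes self-loops, canonicalizes each pair to
#' alphabetical order and drops exact duplicate (pair, source) rows.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `source_db`.
#' @return a [PPIEdgeTable].
#' @export
PPIEdgeTable <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b", "source_db") %in% names(edges)))
  a <- toupper(as.character(edges$gene_a))
  b <- toupper(as.character(edges$gene_b))
  keep <- a != b
  lo <- pmin(a, b)[keep]
  hi <- pmax(a, b)[keep]
  out <- data.frame(gene_a = lo, gene_b = hi,
                    source_db = as.character(edges$source_db)[keep],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  new("PPIEdgeTable", edges = out)
}

#' @rdname ppiEdges
#' @export
setMethod("ppiEdges", "PPIEdgeTable", function(object) object@edges)

setMethod("show", "PPIEdgeTable", function(object) {
  e <- object@edges
  cat("PPIEdgeTable: ", nrow(e), " records, ",
      length(unique(paste(e$gene_a, e$gene_b))), " unordered pairs, ",
      length(unique(e$source_db)), " source database(s)\n", sep = "")
})

#' Read and pool PPI edge lists
#'
#' Each file is tab-delimited with at least two columns of gene symbols; a
#' `source_db` column is used when present, otherwise the file name stem
#' tags the source. Files are concatenated and cleaned (upper-casing,
#' self-loop removal, exact duplicate (pair, source) removal); the same
#' unordered pair arriving from several databases keeps one record per
#' source, which is what union integration counts as support.
#'
#' @param paths character vector of edge-list file paths.
#' @return a [PPIEdgeTable].
#' @export
readPPIEdges <- function(paths) {
  stopifnot(length(paths) >= 1L)
  parts <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("PPI edge file not found: ", p)
    d <- utils::read.delim(p, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    if (ncol(d) < 2L) stop("PPI file needs at least two columns: ", p)
    src <- if ("source_db" %in% names(d)) d$source_db else
      sub("\\.[^.]*$", "", basename(p))
    out <- data.frame(gene_a = d[[1L]], gene_b = d[[2L]], source_db = src,
                      stringsAsFactors = FALSE)
    cleaned <- PPIEdgeTable(out)
    if (nrow(cleaned@edges) == 0L)
      warning("PPI file yielded zero edges after cleaning: ", p)
    cleaned@edges
  })
  PPIEdgeTable(do.call(rbind, parts))
}

#' Write a PPIEdgeTable as a TSV edge list
#' @param ppi a [PPIEdgeTable].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePPIEdges <- function(ppi, path) .writeTSV(ppi@edges, path)

# Shared TSV writer: UTF-8, LF, tab-delimited, no quoting.
.writeTSV <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cols <- lapply(df, function(x)
      if (is.numeric(x)) format(x, digits = 15, trim = TRUE) else
        as.character(x))
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}
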