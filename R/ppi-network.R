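#' Build the PPI core over a gene whitelist
#'
#' Restricts the pooled edge table to pairs whose endpoints are both in
#' the whitelist (the significant co-expressed genes after probe
#' collapse), merges duplicate unordered pairs arriving from different
#' databases into a single edge carrying the union of its sources, and
#' returns the induced network with one node per whitelist gene (isolated
#' genes keep degree 0). Integration is a union across databases: an
#' interaction reported by at least one source is kept, with the number
#' of supporting sources retained as the edge attribute `support`.
#'
#' @param ppi a [PPIEdgeTable].
#' @param geneWhitelist non-empty character vector of gene symbols.
#' @return an [InteractionNetwork] with gene-gene edges only
#'   (`type = "ppi"`).
#' @export
integrateEdges <- function(ppi, geneWhitelist) {
  stopifnot(is(ppi, "PPIEdgeTable"))
  if (!length(geneWhitelist))
    stop("gene whitelist is empty; nothing to integrate")
  wl <- sort(unique(toupper(geneWhitelist)))
  e <- ppi@edges
  e <- e[e$gene_a %in% wl & e$gene_b %in% wl, , drop = FALSE]
  if (nrow(e)) {
    key <- paste(e$gene_a, e$gene_b, sep = "\r")
    merged <- lapply(split(e, key), function(d)
      data.frame(gene_a = d$gene_a[1L], gene_b = d$gene_b[1L],
                 sources = paste(sort(unique(d$source_db)), collapse = ","),
                 support = length(unique(d$source_db)),
                 stringsAsFactors = FALSE))
    merged <- do.call(rbind, merged)
    merged <- merged[order(merged$gene_a, merged$gene_b), , drop = FALSE]
  } else {
    merged <- data.frame(gene_a = character(), gene_b = character(),
                         sources = character(), support = integer(),
                         stringsAsFactors = FALSE)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(wl), name = wl, role = "gene")
  if (nrow(merged)) {
    g <- igraph::add_edges(
      g, rbind(match(merged$gene_a, wl), match(merged$gene_b, wl)),
      type = "ppi", sources = merged$sources, support = merged$support)
  }
  new("InteractionNetwork", graph = g, target = NA_character_)
}

#' Attach the target node and its candidate edges
#'
#' Adds the distinguished target node (the transcript whose associations
#' are being predicted) and one candidate-regulation edge per supplied
#' candidate gene, each carrying the candidate's correlation `r` and `q`.
#' Candidates absent from the PPI core are added as degree-0 gene nodes.
#'
#' @param net an [InteractionNetwork] from [integrateEdges()].
#' @param target target node label; must not collide with a gene node.
#' @param candidates data.frame with columns `gene` and optionally `r`,
#'   `q` (as produced by [collapseToGenes()]), or a character vector.
#' @return the augmented [InteractionNetwork].
#' @export
attachTarget <- function(net, target, candidates) {
  stopifnot(is(net, "InteractionNetwork"))
  if (is.character(candidates))
    candidates <- data.frame(gene = candidates,
                             r = rep(NA_real_, length(candidates)),
                             q = rep(NA_real_, length(candidates)),
                             stringsAsFactors = FALSE)
  if (nrow(candidates) && is.null(candidates$r)) candidates$r <- NA_real_
  if (nrow(candidates) && is.null(candidates$q)) candidates$q <- NA_real_
  g <- net@graph
  target <- toupper(target)
  if (target %in% igraph::V(g)$name)
    stop("target label '", target, "' collides with a gene node")
  candidates$gene <- toupper(candidates$gene)
  newGenes <- setdiff(candidates$gene, igraph::V(g)$name)
  if (length(newGenes))
    g <- igraph::add_vertices(g, length(newGenes), name = newGenes,
                              role = "gene")
  g <- igraph::add_vertices(g, 1L, name = target, role = "target")
  if (nrow(candidates)) {
    ends <- rbind(match(rep(target, nrow(candidates)),
                        igraph::V(g)$name),
                  match(candidates$gene, igraph::V(g)$name))
    g <- igraph::add_edges(g, ends, type = "candidate",
                           sources = NA_character_, support = NA_integer_,
                           r = candidates$r, q = candidates$q)
  }
  new("InteractionNetwork", graph = g, target = target)
}

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkGraph", "InteractionNetwork",
          function(object) object@graph)

#' Target node of an InteractionNetwork
#' @param net an [InteractionNetwork].
#' @return the target node name, or `NA` before [attachTarget()].
#' @export
networkTarget <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  net@target
}

setMethod("show", "InteractionNetwork", function(object) {
  g <- object@graph
  et <- igraph::edge_attr(g, "type")
  cat("InteractionNetwork: ",
      sum(igraph::V(g)$role == "gene"), " gene nodes, ",
      sum(et == "ppi"), " PPI edges, ",
      sum(et == "candidate"), " candidate edges",
      if (!is.na(object@target)) paste0(" (target ", object@target, ")"),
      "\n", sep = "")
})

#' Interaction weights (neighbor counts) of the network core
#'
#' The interaction weight of a gene is its number of distinct gene-gene
#' PPI neighbors within the network; the target's candidate edges are
#' excluded so the weights characterize the PPI core itself. The
#' handshake identity sum(weights) = 2 * #(gene-gene edges) is asserted
#' on every call.
#'
#' @param net an [InteractionNetwork].
#' @param flagGenes optional character vector (for example the union of
#'   members of the significantly enriched pathways); genes in it get
#'   `flagged = TRUE`.
#' @return data.frame with columns `gene`, `weight`, `flagged`, sorted by
#'   weight descending with lexicographic tie-break.
#' @export
nodeWeights <- function(net, flagGenes = NULL) {
  stopifnot(is(net, "InteractionNetwork"))
  g <- net@graph
  et <- igraph::edge_attr(g, "type")
  gg <- igraph::subgraph_from_edges(g, igraph::E(g)[et == "ppi"],
                                    delete.vertices = FALSE)
  genes <- igraph::V(gg)$name[igraph::V(gg)$role == "gene"]
  deg <- igraph::degree(gg, v = genes)
  stopifnot(sum(deg) == 2L * sum(et == "ppi"))
  out <- data.frame(gene = genes, weight = as.integer(deg),
                    flagged = genes %in% toupper(flagGenes %||% character()),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a network for Cytoscape
#'
#' `sif` writes one line per edge, `geneA <TAB> ppi <TAB> geneB` for PPI
#' edges and `target <TAB> candidate <TAB> gene` for candidate edges (no
#' header), so the line count equals the total edge count. `graphml`
#' writes nodes with their role and edges with type/sources/support/r/q
#' attributes via [igraph::write_graph()].
#'
#' @param net an [InteractionNetwork].
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("sif", "graphml")) {
  stopifnot(is(net, "InteractionNetwork"))
  if (!format[1L] %in% c("sif", "graphml"))
    stop("unknown export format: ", format[1L])
  format <- match.arg(format)
  g <- net@graph
  if (format == "sif") {
    ends <- igraph::ends(g, igraph::E(g), names = TRUE)
    et <- igraph::edge_attr(g, "type")
    lines <- paste(ends[, 1L], ifelse(et == "ppi", "ppi", "candidate"),
                   ends[, 2L], sep = "\t")
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con, sep = "\n")
  } else {
    # graphml chokes on NA attributes; blank them out first
    for (at in c("sources", "r", "q", "support")) {
      v <- igraph::edge_attr(g, at)
      if (!is.null(v)) {
        if (is.character(v)) v[is.na(v)] <- ""
        else v[is.na(v)] <- -1
        g <- igraph::set_edge_attr(g, at, value = v)
      }
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Write an interaction-weight table as TSV
#' @param weights data.frame from [nodeWeights()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNodeWeights <- function(weights, path) .writeTSV(weights, path)
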