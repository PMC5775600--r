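edgeDF <- function(...) {
  rows <- list(...)
  data.frame(gene_a = vapply(rows, `[[`, "", 1),
             gene_b = vapply(rows, `[[`, "", 2),
             source_db = vapply(rows, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

test_that("union integration merges duplicate pairs across sources", {
  ppi <- PPIEdgeTable(edgeDF(c("A", "B", "db1"), c("B", "A", "db2"),
                             c("A", "C", "db1")))
  net <- integrateEdges(ppi, c("A", "B"))
  g <- networkGraph(net)
  expect_identical(as.integer(igraph::ecount(g)), 1L)
  expect_identical(igraph::E(g)$sources, "db1,db2")
  expect_identical(igraph::E(g)$support, 2L)
  # C is outside the whitelist: its edge is excluded, node absent
  expect_setequal(igraph::V(g)$name, c("A", "B"))
})

test_that("whitelist genes without edges stay as degree-0 nodes", {
  ppi <- PPIEdgeTable(edgeDF(c("A", "B", "db1")))
  net <- integrateEdges(ppi, c("A"))
  g <- networkGraph(net)
  expect_identical(as.integer(igraph::vcount(g)), 1L)
  expect_identical(as.integer(igraph::ecount(g)), 0L)
  expect_error(integrateEdges(ppi, character(0)), "empty")
})

test_that("integration is idempotent and input-order invariant", {
  set.seed(12)
  df <- edgeDF(c("A", "B", "db1"), c("B", "C", "db2"), c("A", "C", "db1"),
               c("C", "B", "db1"))
  wl <- c("A", "B", "C")
  canon <- function(net) {
    g <- networkGraph(net)
    e <- igraph::as_data_frame(g)
    e[order(e$from, e$to), c("from", "to", "sources", "support")]
  }
  n1 <- integrateEdges(PPIEdgeTable(df), wl)
  n2 <- integrateEdges(PPIEdgeTable(df[sample(nrow(df)), ]), wl)
  expect_identical(canon(n1), canon(n2))
  # feeding the already-merged table back in changes nothing
  e <- ppiEdges(PPIEdgeTable(df))
  n3 <- integrateEdges(PPIEdgeTable(rbind(e, e)), wl)
  expect_identical(canon(n1), canon(n3))
})

test_that("attaching the target adds candidate edges and new nodes", {
  ppi <- PPIEdgeTable(edgeDF(c("A", "B", "db1")))
  net <- integrateEdges(ppi, c("A", "B"))
  cand <- data.frame(gene = c("A", "B", "NEW"), r = c(0.9, 0.8, 0.7),
                     q = c(0.001, 0.002, 0.003))
  net2 <- attachTarget(net, "LNC1", cand)
  g <- networkGraph(net2)
  expect_identical(networkTarget(net2), "LNC1")
  et <- igraph::edge_attr(g, "type")
  expect_identical(sum(et == "candidate"), 3L)
  expect_identical(sum(et == "ppi"), 1L)
  # candidate absent from the PPI core arrives with degree 0 in the core
  w <- nodeWeights(net2)
  expect_identical(w$weight[w$gene == "NEW"], 0L)
  # target label clashing with a gene node is rejected
  expect_error(attachTarget(net, "A", cand), "collides")
  # empty candidate list still places the target node
  net3 <- attachTarget(net, "LNC1", character(0))
  expect_true("LNC1" %in% igraph::V(networkGraph(net3))$name)
  expect_identical(sum(igraph::edge_attr(networkGraph(net3),
                                         "type") == "candidate"), 0L)
})

test_that("interaction weights are gene-gene degrees, target edges excluded", {
  tri <- PPIEdgeTable(edgeDF(c("A", "B", "x"), c("B", "C", "x"),
                             c("A", "C", "x")))
  w <- nodeWeights(integrateEdges(tri, c("A", "B", "C")))
  expect_identical(w$weight, c(2L, 2L, 2L))
  star <- PPIEdgeTable(edgeDF(c("HUB", "L1", "x"), c("HUB", "L2", "x"),
                              c("HUB", "L3", "x"), c("HUB", "L4", "x"),
                              c("HUB", "L5", "x")))
  net <- integrateEdges(star, c("HUB", paste0("L", 1:5)))
  net <- attachTarget(net, "TGT", c("HUB", "L1"))
  w <- nodeWeights(net, flagGenes = c("L1", "L2"))
  expect_identical(w$gene[1], "HUB")
  expect_identical(w$weight[1], 5L)
  expect_identical(unique(w$weight[-1]), 1L)  # candidate edges not counted
  expect_identical(w$flagged, c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # ties are ordered lexicographically
  expect_identical(w$gene[-1], paste0("L", 1:5))
})

test_that("weights equal adjacency-matrix row sums on a random graph", {
  set.seed(30)
  genes <- sprintf("G%02d", 1:30)
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < 0.2
  ppi <- PPIEdgeTable(data.frame(gene_a = pairs[keep, 1],
                                 gene_b = pairs[keep, 2],
                                 source_db = "db",
                                 stringsAsFactors = FALSE))
  net <- integrateEdges(ppi, genes)
  w <- nodeWeights(net)
  adj <- matrix(0L, 30, 30, dimnames = list(genes, genes))
  e <- ppiEdges(ppi)
  for (i in seq_len(nrow(e))) {
    adj[e$gene_a[i], e$gene_b[i]] <- 1L
    adj[e$gene_b[i], e$gene_a[i]] <- 1L
  }
  expect_identical(w$weight[match(genes, w$gene)],
                   as.integer(unname(rowSums(adj))))
  # handshake identity
  expect_identical(sum(w$weight), 2L * sum(keep))
})

test_that("SIF export has one line per edge with the right relation types", {
  ppi <- PPIEdgeTable(edgeDF(c("A", "B", "x"), c("B", "C", "x")))
  net <- attachTarget(integrateEdges(ppi, c("A", "B", "C")), "TGT",
                      c("A", "C"))
  path <- tempfile(fileext = ".sif")
  exportNetwork(net, path, "sif")
  lines <- readLines(path)
  expect_identical(length(lines), 4L)  # 2 ppi + 2 candidate
  expect_identical(sum(grepl("\tppi\t", lines)), 2L)
  expect_identical(sum(grepl("\tcandidate\t", lines)), 2L)
  expect_error(exportNetwork(net, path, "dot"), "unknown")
})

test_that("GraphML export round-trips node and edge counts", {
  ppi <- PPIEdgeTable(edgeDF(c("A", "B", "x"), c("B", "C", "y")))
  net <- attachTarget(integrateEdges(ppi, c("A", "B", "C")), "TGT",
                      data.frame(gene = "A", r = 0.9, q = 0.01))
  path <- tempfile(fileext = ".graphml")
  exportNetwork(net, path, "graphml")
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_identical(igraph::vcount(g2),
                   igraph::vcount(networkGraph(net)))
  expect_identical(igraph::ecount(g2),
                   igraph::ecount(networkGraph(net)))
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C", "TGT"))
})
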