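test_that("expression matrix round-trips bit-identically through TSV", {
  set.seed(42)
  d <- makeDataset(matrix(rnorm(15, 7, 2), 3, 5), "E-RT-1")
  path <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(d, path)
  d2 <- readExpressionMatrix(path, "E-RT-1")
  expect_identical(dim(d2), c(3L, 5L))
  expect_identical(exprValues(d2), exprValues(d))
  expect_identical(datasetId(d2), "E-RT-1")
  expect_identical(probeIds(d2), probeIds(d))
  expect_identical(sampleIds(d2), sampleIds(d))
})

test_that("dataset id defaults to the file name stem", {
  d <- makeDataset(matrix(1:4, 2, 2))
  path <- file.path(tempdir(), "E-MTAB-999.tsv")
  writeExpressionMatrix(d, path)
  expect_identical(datasetId(readExpressionMatrix(path)), "E-MTAB-999")
})

test_that("duplicate probe rows are a hard error naming the probe", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tS1\tS2", "P1\t1\t2", "P1\t3\t4"), path)
  expect_error(readExpressionMatrix(path), "P1")
})

test_that("rows with missing values are dropped, logged, and counted", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tS1\tS2", "P1\t1\t2", "P2\tNA\t4", "P3\t5\t6"),
             path)
  expect_message(d <- readExpressionMatrix(path), "P2")
  expect_identical(nrow(d), 2L)  # exactly one row fewer
  expect_identical(probeIds(d), c("P1", "P3"))
})

test_that("empty or malformed expression files are hard errors", {
  path <- tempfile(fileext = ".tsv")
  writeLines("probe_id\tS1", path)
  expect_error(readExpressionMatrix(path), "empty")
  writeLines(c("probe_id\tS1", "P1\tabc"), path)
  expect_error(readExpressionMatrix(path), "complete")
})

test_that("dataset invariants are enforced at construction", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("P1", "P2"), c("S1", "S1")))
  expect_error(ExpressionDataset(m, "D"), "sample identifiers")
  m2 <- matrix(c(1, NA, 3, 4), 2, 2,
               dimnames = list(c("P1", "P2"), c("S1", "S2")))
  expect_error(ExpressionDataset(m2, "D"), "finite")
})

test_that("GMT reader builds the union universe and dedups members", {
  path <- writeGMTLines(c("SET1\tfirst\tA\tB\tC", "SET2\tsecond\tB\tD\tD"))
  gs <- readGMT(path)
  expect_setequal(geneUniverse(gs), c("A", "B", "C", "D"))
  expect_identical(geneSets(gs)$SET2, c("B", "D"))  # duplicate dropped
  expect_identical(setDescriptions(gs)[["SET1"]], "first")
})

test_that("GMT reader rejects short and memberless lines", {
  expect_error(readGMT(writeGMTLines(c("SET1\tdesc\tA", "SET2\tdesc"))),
               "line 2")
  expect_error(readGMT(writeGMTLines("SET1\tdesc")), "line 1")
  expect_error(readGMT(writeGMTLines("SET1\tdesc\t\t")), "empty member")
})

test_that("GMT writer then reader is the identity on canonical collections", {
  gs <- GeneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C", "D")),
                          c(S1 = "one", S2 = "two"))
  path <- tempfile(fileext = ".gmt")
  writeGMT(gs, path)
  gs2 <- readGMT(path)
  expect_identical(geneSets(gs2), geneSets(gs))
  expect_identical(setDescriptions(gs2), setDescriptions(gs))
  expect_setequal(geneUniverse(gs2), geneUniverse(gs))
})

test_that("PPI reader cleans, normalizes case, and pools sources", {
  f1 <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "SRC\tEGFR", "TP53\tTP53", "egfr\tgrpr"),
             f1)
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tsource_db", "SRC\tEGFR\tintact",
               "GRPR\tEGFR\tintact", "GRPR\tEGFR\tintact"), f2)
  ppi <- readPPIEdges(c(f1, f2))
  e <- ppiEdges(ppi)
  # self-loop removed, exact duplicate (pair, source) removed
  expect_identical(nrow(e), 4L)
  # same unordered pair under two sources keeps both records
  srcEgfr <- e$source_db[e$gene_a == "EGFR" & e$gene_b == "SRC"]
  expect_identical(length(srcEgfr), 2L)
  # lower-case input upper-cased and pair canonicalized
  expect_true(any(e$gene_a == "EGFR" & e$gene_b == "GRPR"))
  # total record count equals the sum of per-file cleaned counts (2 + 2)
  expect_identical(nrow(e),
                   nrow(ppiEdges(readPPIEdges(f1))) +
                     nrow(ppiEdges(readPPIEdges(f2))))
})

test_that("a PPI file yielding zero edges warns instead of erroring", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "TP53\tTP53"), f)
  expect_warning(ppi <- readPPIEdges(f), "zero edges")
  expect_identical(nrow(ppiEdges(ppi)), 0L)
})

test_that("probe annotation upper-cases symbols and joins multi-mappings", {
  ann <- ProbeAnnotation(data.frame(
    probe_id = c("p1", "p1", "p2"), symbol = c("egfr", "src", "tp53")))
  expect_identical(symbolsFor(ann, c("p1", "p2", "p9")),
                   c("EGFR,SRC", "TP53", ""))
})
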