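# Single-dataset compendium whose raw values are handed straight to the
# correlation engine.
corOf <- function(x, y) {
  d <- makeDataset(rbind(x, y), probes = c("TGT", "P"))
  pooled <- poolCompendium(list(d), mode = "raw")
  resultTable(correlateTarget(pooled, "TGT"))
}

test_that("r and p match the reference implementation on fixed vectors", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  rec <- corOf(x, y)
  ct <- cor.test(x, y)
  # frozen reference values (product-moment formula + t tail)
  expect_equal(rec$r, 0.82199493, tolerance = 1e-7)
  expect_equal(rec$p_raw, 0.08770665, tolerance = 1e-6)
  expect_equal(rec$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(rec$p_raw, ct$p.value, tolerance = 1e-10)
  expect_identical(rec$n, 5L)
})

test_that("perfect and perfectly inverted probes reach |r| = 1 with p = 0", {
  x <- c(1, 3, 2, 5, 4)
  same <- corOf(x, x)
  expect_equal(same$r, 1)
  expect_equal(same$p_raw, 0)
  flipped <- corOf(x, 10 - x)
  expect_equal(flipped$r, -1)
})

test_that("correlation is symmetric and invariant to positive affine maps", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(12)
    y <- rnorm(12)
    expect_equal(corOf(x, y)$r, corOf(y, x)$r, tolerance = 1e-12)
    a <- runif(1, 0.1, 5)
    b <- runif(1, -10, 10)
    expect_equal(corOf(a * x + b, y)$r, corOf(x, y)$r, tolerance = 1e-12)
  }
})

test_that("the engine agrees with cor.test across random matrices", {
  set.seed(99)
  m <- matrix(rnorm(10 * 30), 10, 30)
  target <- rnorm(30)
  d <- makeDataset(rbind(TGT = target, m),
                   probes = c("TGT", sprintf("P%02d", 1:10)))
  res <- resultTable(correlateTarget(poolCompendium(list(d), "raw"), "TGT"))
  for (i in 1:10) {
    ct <- cor.test(m[i, ], target)
    row <- res[res$probe_id == sprintf("P%02d", i), ]
    expect_equal(row$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(row$p_raw, ct$p.value, tolerance = 1e-10)
  }
})

test_that("zero-variance probes are flagged degenerate with r = 0, p = 1", {
  d <- makeDataset(rbind(c(1, 2, 3, 4), c(5, 5, 5, 5)),
                   probes = c("TGT", "FLAT"))
  res <- resultTable(correlateTarget(poolCompendium(list(d), "raw"), "TGT"))
  expect_true(res$degenerate)
  expect_identical(res$r, 0)
  expect_identical(res$p_raw, 1)
})

test_that("under the null the p-value distribution is uniform at the tail", {
  set.seed(1234)
  n <- 100
  probes <- 5000
  d <- makeDataset(rbind(rnorm(n), matrix(rnorm(probes * n), probes, n)),
                   probes = c("TGT", sprintf("P%04d", seq_len(probes))))
  res <- resultTable(correlateTarget(poolCompendium(list(d), "raw"), "TGT"))
  expect_equal(mean(res$p_raw < 0.05), 0.05, tolerance = 0.01 / 0.05)
  expect_true(abs(mean(res$p_raw < 0.05) - 0.05) <= 0.01)
})

test_that("standardize pooling z-scores every probe within each dataset", {
  set.seed(8)
  d1 <- makeDataset(matrix(rnorm(20, 10, 3), 4, 5), "a")
  d2 <- makeDataset(matrix(rnorm(24, 2, 1), 4, 6), "b",
                    probes = probeIds(d1))
  pooled <- poolCompendium(list(d1, d2), "standardize")
  v <- pooledValues(pooled)
  prov <- pooledProvenance(pooled)
  for (id in c("a", "b")) {
    block <- v[, prov$dataset_id == id]
    expect_equal(unname(rowMeans(block)), rep(0, 4), tolerance = 1e-12)
    expect_equal(unname(apply(block, 1, sd)), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("pooling two identical datasets reproduces the single-dataset r", {
  set.seed(21)
  m <- matrix(rnorm(25), 5, 5)
  d1 <- makeDataset(m, "a")
  d2 <- makeDataset(m, "b", probes = probeIds(d1))
  single <- resultTable(correlateTarget(poolCompendium(list(d1), "raw"),
                                        "P1"))
  both <- resultTable(correlateTarget(
    poolCompendium(list(d1, d2), "standardize"), "P1"))
  expect_equal(both$r[match(single$probe_id, both$probe_id)], single$r,
               tolerance = 1e-12)
})

test_that("a planted batch offset corrupts raw pooling but not standardize", {
  set.seed(77)
  # two studies with independent noise; study means differ jointly for
  # target and probe, which fabricates correlation under raw pooling
  mk <- function(shift, id) makeDataset(
    rbind(shift + rnorm(30), shift + rnorm(30)), id,
    probes = c("TGT", "P"))
  ds <- list(mk(0, "a"), mk(10, "b"))
  raw <- resultTable(correlateTarget(poolCompendium(ds, "raw"), "TGT"))
  std <- resultTable(correlateTarget(poolCompendium(ds, "standardize"),
                                     "TGT"))
  expect_gt(raw$r, 0.9)
  expect_lt(abs(std$r), 0.5)
})

test_that("probes absent from one dataset are used pairwise", {
  set.seed(3)
  d1 <- makeDataset(rbind(rnorm(10), rnorm(10)), "a",
                    probes = c("TGT", "P1"))
  m2 <- rbind(rnorm(8), rnorm(8), rnorm(8))
  d2 <- makeDataset(m2, "b", probes = c("TGT", "P1", "P2"))
  res <- resultTable(correlateTarget(poolCompendium(list(d1, d2), "raw"),
                                     "TGT"))
  expect_identical(res$n[res$probe_id == "P1"], 18L)
  expect_identical(res$n[res$probe_id == "P2"], 8L)
  expect_equal(res$r[res$probe_id == "P2"],
               unname(cor(m2[3, ], m2[1, ])), tolerance = 1e-12)
})

test_that("disjoint probe namespaces cannot be pooled", {
  d1 <- makeDataset(matrix(1:4, 2, 2), "a", probes = c("P1", "P2"))
  d2 <- makeDataset(matrix(1:4, 2, 2), "b", probes = c("P3", "P4"))
  expect_error(poolCompendium(list(d1, d2)), "disjoint")
})

test_that("a missing target probe is a hard error", {
  d <- makeDataset(matrix(rnorm(9), 3, 3))
  expect_error(correlateTarget(poolCompendium(list(d)), "NOPE"), "NOPE")
})

test_that("Fisher combination reduces to closed forms", {
  # identical r across studies stays put
  per <- list(data.frame(probe_id = "P", r = 0.5, n = 20L),
              data.frame(probe_id = "P", r = 0.5, n = 40L))
  comb <- combineFisher(per)
  expect_equal(comb$r, 0.5, tolerance = 1e-12)
  expect_identical(comb$n, 60L)
  # null everywhere combines to r = 0, p = 1
  per0 <- list(data.frame(probe_id = "P", r = 0, n = 20L),
               data.frame(probe_id = "P", r = 0, n = 30L))
  comb0 <- combineFisher(per0)
  expect_identical(comb0$r, 0)
  expect_identical(comb0$p, 1)
  # weighted mean in z space for unequal r
  perW <- list(data.frame(probe_id = "P", r = 0.3, n = 13L),
               data.frame(probe_id = "P", r = 0.6, n = 23L))
  zbar <- (10 * atanh(0.3) + 20 * atanh(0.6)) / 30
  expect_equal(combineFisher(perW)$r, tanh(zbar), tolerance = 1e-12)
  # exact |r| = 1 is clipped and flagged
  per1 <- list(data.frame(probe_id = "P", r = 1, n = 10L),
               data.frame(probe_id = "P", r = 0.9, n = 10L))
  expect_true(combineFisher(per1)$clipped)
  expect_true(is.finite(combineFisher(per1)$r))
})

test_that("fisher_meta pooling matches a by-hand combination", {
  set.seed(55)
  ds <- lapply(1:3, function(i)
    makeDataset(rbind(rnorm(15), rnorm(15)), paste0("d", i),
                probes = c("TGT", "P")))
  meta <- resultTable(correlateTarget(poolCompendium(ds, "fisher_meta"),
                                      "TGT"))
  rs <- vapply(ds, function(d) cor(exprValues(d)[1, ], exprValues(d)[2, ]),
               numeric(1))
  w <- rep(15 - 3, 3)
  zbar <- sum(w * atanh(rs)) / sum(w)
  expect_equal(meta$r, tanh(zbar), tolerance = 1e-12)
  expect_equal(meta$p_raw, 2 * pnorm(-abs(zbar * sqrt(sum(w)))),
               tolerance = 1e-12)
})

test_that("ranking is r-descending with p then probe-id tie-breaks", {
  tab <- data.frame(
    probe_id = c("A", "B", "C", "D", "E"),
    gene_symbols = "", r = c(0.9, 0.5, 0.7, 0.8, 0.8),
    n = 10L, p_raw = c(0.001, 0.2, 0.05, 0.01, 0.001), q = NA_real_,
    degenerate = FALSE, stringsAsFactors = FALSE)
  res <- new("CorrelationResult", targetProbe = "T", table = tab,
             pooling = "raw")
  expect_identical(rankCandidates(res, 2)$probe_id, c("A", "E"))
  # tie on r broken by smaller p
  expect_identical(rankCandidates(res, 3)$probe_id, c("A", "E", "D"))
  expect_identical(nrow(rankCandidates(res, 0)), 0L)
  expect_warning(all5 <- rankCandidates(res, 10), "exceeds")
  expect_identical(nrow(all5), 5L)
  # absolute ranking puts large negative r first
  tab$r[2] <- -0.95
  res2 <- new("CorrelationResult", targetProbe = "T", table = tab,
              pooling = "raw")
  expect_identical(rankCandidates(res2, 1, "absolute")$probe_id, "B")
})

test_that("probe-to-gene collapse keeps the best probe per symbol", {
  tab <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4"),
    gene_symbols = c("EGFR", "EGFR", "SRC,FYN", ""),
    r = c(0.9, 0.95, 0.5, 0.99), n = 10L,
    p_raw = c(0.01, 0.001, 0.1, 1e-5), q = NA_real_,
    degenerate = FALSE, stringsAsFactors = FALSE)
  genes <- collapseToGenes(tab)
  expect_identical(genes$probe_id[genes$gene == "EGFR"], "p2")
  # a multi-symbol probe feeds every symbol it maps to
  expect_setequal(genes$gene, c("EGFR", "SRC", "FYN"))
  expect_identical(genes$probe_id[genes$gene == "FYN"], "p3")
})
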