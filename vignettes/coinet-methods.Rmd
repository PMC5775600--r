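---
title: "Methods: correlation-interaction-network analysis with coinet"
author: "coinet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-interaction-network analysis with coinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coinet)
```

## The problem

Most long non-coding RNAs have no characterized function. A standard way
to generate functional hypotheses for such a transcript is
guilt-by-association: genes whose expression tracks the target across
many independent experiments are likely to share regulation or function
with it. `coinet` implements this idea as a five-stage pipeline over a
*compendium* of normalized expression matrices (one per public study,
probes in rows, log2 scale):

1. **Dataset screen** — keep only studies in which the target probe
   actually varies.
2. **Compendium-wide correlation** — Pearson correlation of the target
   probe against every other probe, with exact p-values.
3. **FDR control** — Storey q-values; co-expression is called at
   q < 0.05.
4. **Pathway over-representation** — hypergeometric tests of the top
   co-expressed genes against gene-set collections, Bonferroni-adjusted.
5. **Interaction network** — the candidates are intersected with a union
   of protein–protein interaction databases and ranked by neighbor
   count, so that hubs among the co-expressed genes stand out.

## Stage models and parameters

### Dataset screen

For each study the sample standard deviation (n − 1 denominator) of the
target probe's log2 expression is computed; studies with sd **strictly
below 0.25** are excluded (`filterDatasets()`, default
`threshold = 0.25`). The strict inequality means a study sitting exactly
on 0.25 is retained. The threshold is in log2-expression units and
presumes RMA-style normalized input. Single-sample studies, where the sd
is undefined, are excluded with an explicit reason. Filtering is per
*target probe*: if the target has several probes, each is screened (and
correlated) separately.

### Pooling the compendium

Public studies differ in location and scale (platform processing
batches, lab effects). How samples should be pooled before correlating
is genuinely open, so the package offers three modes
(`poolCompendium()`):

* `standardize` (default): every probe row is z-scored *within each
  study* before column-wise concatenation. Constant rows become all-zero
  (flagged downstream as degenerate). This removes per-study location
  and scale, which would otherwise dominate the pooled covariance — a
  gene whose mean differs between studies in step with the target's mean
  would appear correlated without any within-study covariation.
* `raw`: plain concatenation. Kept because it is what a naive pooling
  does; the synthetic generator plants batch offsets precisely so the
  tests can demonstrate `standardize` recovering more planted genes than
  `raw` on the same data.
* `fisher_meta`: no pooled matrix; correlations are computed per study,
  Fisher z-transformed, averaged with weights (n − 3) and
  back-transformed, with the combined p from the normal approximation
  (`combineFisher()`). This is the textbook meta-analytic alternative;
  it requires a probe to be measured in at least two studies with n > 3.

Probes missing from a study are carried as `NA` in that study's columns
and handled pairwise during correlation.

### Correlation and significance

`correlateTarget()` computes the product-moment correlation r of the
target row against every other row over pairwise-complete columns, and
the exact two-sided p-value from t = r·sqrt((n − 2)/(1 − r²)) on n − 2
degrees of freedom. Zero-variance probes are kept in the output with
r = 0, p = 1 and a `degenerate` flag rather than dropped, so that every
input probe is accounted for; probes with fewer than 3 paired
observations get `NA` and are excluded from ranking. Numerically, the
row-wise sums are formed by matrix–vector products (one pass over a
probes × samples matrix), and a relative tolerance of 1e−10 on the
variance terms separates true zero-variance rows from floating-point
cancellation.

q-values (`qvalues()`) follow the smoother pi0 estimate: pi0(λ) =
#{p > λ}/(m(1 − λ)) on λ = 0, 0.05, …, 0.90, cubic smoothing spline with
3 df, read off at λ = 0.90 and clipped into [1e−4, 1]; q-values are the
step-up quantities with a cumulative minimum. With fewer than 100 tests
the smoother is unstable and the function falls back to
Benjamini–Hochberg (pi0 = 1) with a warning. Significance is **strict**:
q < 0.05, so q exactly 0.05 is not called.

### Candidate list

Candidates are ranked by signed r descending (`rankCandidates()`), ties
broken by smaller p and then probe id. Signed ranking is the default
because the downstream validation concept is positive regulation by the
target; `absolute` ranking is available. The candidate list for
enrichment and the network is the top 1000 genes (`topK`), taken from
the q-significant set when it exceeds 1000 and from the full ranking
(with a warning) otherwise — the run summary reports both counts so the
interaction of the two rules is auditable. Probe-level records collapse
to gene level by keeping, for each symbol, the probe with the largest r
(`collapseToGenes()`).

### Enrichment

`enrich()` performs the upper-tail hypergeometric test P(X ≥ k) per gene
set, with N the universe size, K the set size, n the query size and k
the overlap, delegating the tail to the exact distribution function. The
default universe is the union of all set members in the collection; an
explicit background (for example all genes on the array) can be passed,
and is the defensible alternative when the collections cover only a
biased slice of the genome. Query or background symbols absent from the
universe are discarded before testing. Bonferroni's family size is the
number of sets tested in the collection at hand (collections supplied as
separate GMT files are corrected separately, mirroring per-database
reporting); significance is again strict, adjusted p < 0.05, with an
optional raw-p reporting screen (`filterSignificant(pRawCut =)`).

### Network integration

PPI edges pooled from any number of source databases are integrated by
**union**: an interaction present in at least one database is kept, and
the number of distinct supporting databases is retained as the edge's
`support` attribute for optional later filtering. The network is the
subgraph induced on the candidate genes (isolated candidates keep
degree 0); the target node is attached by `attachTarget()` with
candidate edges carrying each gene's r and q. The *interaction weight*
of a gene (`nodeWeights()`) is its number of distinct gene–gene
neighbors, excluding the target's candidate edges — including them would
add 1 uniformly and blur the hub ranking of the PPI core. The handshake
identity (weights sum to twice the edge count) is asserted on every
call. Exports are Cytoscape-consumable SIF and GraphML.

## The synthetic compendium

`syntheticTruth()` fixes the generative model;
`generateCompendium()` materializes it. Defaults: 20 studies × 40
samples, 100 planted genes, 4900 null genes, generative correlation
0.6, target sd 0.5 per study, noise sd 1, batch-offset sd 1, gene
baselines uniform on [5, 10] log2 units. Per study, the target row is
Gaussian with the study's prescribed sd; a planted gene's row is
`r·z(target) + sqrt(1 − r²)·noise` (its generative correlation with the
target is exactly `r` within the study), and every gene — planted or
null — receives a gene-by-study batch offset drawn from N(0, 1). These
sizes were chosen once as a realistic desk-scale miniature of a public
microarray compendium: hundreds of heterogeneous studies shrink to 20,
the 54k-probe array to 5k probes, and the batch offsets emulate the
between-study location shifts that motivate the `standardize` pooling
default. All randomness flows from the single seed in the truth object;
identical parameters and seed reproduce files byte for byte.

What the generator does **not** emulate: probe-level intensity models,
correlated null genes (co-expression modules unrelated to the target),
heavy-tailed noise, missing values, or platform-specific artefacts.
Passing the planted-recovery tests therefore shows the pipeline's
statistics behave as designed under a clean generative model — not that
a real compendium would yield the same recovery rates.

`generateGenesets()` plants one enriched pathway (members drawn from the
planted genes) among uniform decoy sets drawn from the nulls;
`generatePPI()` draws Erdős–Rényi edges over all genes with each edge
assigned to 1–3 synthetic source databases, exercising union
integration and support counting.

## Numerical and design choices

* Boundary conventions are strict everywhere the wording is "below"
  or "lower than": sd < 0.25 excluded, q < 0.05 and adjusted p < 0.05
  significant.
* The Fisher combination clips |r| = 1 to atanh(1 − 1e−15) and flags the
  record rather than propagating infinities.
* pi0 is clipped below at 1e−4 so q-values cannot collapse to zero on
  adversarial inputs.
* Ties in every ranking are broken deterministically (p, then
  lexicographic identifier), which together with seed-driven generation
  makes whole pipeline runs byte-identical across reruns — asserted in
  the test suite.
* Rows with missing values are dropped at ingestion (with a message):
  the expected input is complete RMA-style matrices, so missingness is
  treated as an upstream problem rather than silently imputed.
* The ΔΔCt utility (`ddctFoldChange()`) computes 2^−ΔΔCt and satisfies
  the exact reciprocal identity; it exists so qPCR validation bookkeeping
  can live next to the predictions it checks.

## Problem sizes used in the test suite

Unit tests run on compendia of 6 studies × 25 samples with 135 genes;
the end-to-end recovery checks use the full default generator (20 × 40,
5000 genes), which completes in well under a minute. The statistical
oracles compare 1000 random vector pairs against `stats::cor.test`, the
hypergeometric tail against exhaustive enumeration of all draws for
every N ≤ 12, and BH q-values against the explicit step-up formula.

## Known limitations

* Only target-versus-all correlation is computed; all-pairs co-expression
  networks, partial correlations and nonlinear measures are out of scope.
* Gene-set collections must be pre-flattened to GMT; no ontology DAG
  propagation is performed.
* The enrichment background defaults to the collection universe; results
  are sensitive to this choice, and reproducing someone else's pathway
  p-values requires knowing their background.
* PPI integration is unweighted union; confidence-scored integration
  (STRING-style) is deliberately not attempted.

## A minimal run

```{r, eval = FALSE}
truth <- syntheticTruth(seed = 1)
sim <- generateCompendium(truth)
dir <- tempfile()
writeCompendium(sim, dir, collection = generateGenesets(truth),
                ppi = generatePPI(truth))
cfg <- runConfig(
  targetProbe = "LNC_TARGET_AT",
  expressionDir = file.path(dir, "expression"),
  annotationPath = file.path(dir, "annotation.tsv"),
  gmtPaths = file.path(dir, "genesets.gmt"),
  ppiPaths = list.files(dir, "^ppi_", full.names = TRUE),
  outDir = file.path(dir, "run"))
runPipeline(cfg)
```
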