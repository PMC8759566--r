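---
title: "Methods: identifying metastasis-associated miRNAs from small-RNA sequencing"
author: "mirmet"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and design

`mirmet` implements an analysis pipeline for bulk small-RNA sequencing of
primary colorectal cancer (pCRC), normal colorectum (nCR), liver and lung
metastases with their tumour-adjacent normals (mLi/nLi, mLu/nLu) and
peritoneal metastases (PM). The scientific question is which miRNAs change
between a metastatic site and the primary tumour *beyond* what the
composition of the host organ would produce on its own: a bulk liver
metastasis contains hepatocytes, so hepatocyte miRNAs (e.g. Mir-122_5p)
look "up-regulated" in mLi vs pCRC without any tumour biology behind them.
The pipeline therefore couples a conventional count-based differential
expression engine with a normal-tissue background correction.

The repository is organised as an analysis workflow: all computation lives
in the package (`R/`), and the numbered scripts under `analysis/` are thin
narrative drivers that generate a synthetic study, run each stage, and
write tables under `results/analysis/`. Every stage is exercised by the
test suite on synthetic data with planted truth.

# Read-level quality control

Reads pass through four filters, in a fixed order:

1. **Base quality** — a read is discarded when strictly fewer than 50% of
   its bases have Phred quality above 20.
2. **Adapter trimming** — the suffix is removed at the leftmost position
   where a prefix of the 3' adapter aligns with at least 6 bases and at
   most 10% mismatches (mismatch budget `floor(0.1 × overlap)`); the
   quality string is trimmed in lockstep.
3. **Length** — trimmed reads shorter than 18 nt are discarded.
4. **Complexity** — a read is discarded when a single 1–3 nt motif,
   tandemly repeated, covers at least 80% of it. Standard QC tools flag a
   "repetitive element" read class without publishing a precise criterion;
   the tandem-coverage rule is this package's deterministic, testable
   proxy, and the threshold is configurable.

Retained reads are classified against the mature reference 5'-anchored
with at most 1 mismatch over the shorter length and at most 2 nt of 3'
length difference — a deliberate simplification of isomiR-aware aligners
that keeps classification exactly checkable against generator truth.

Sample gates (all boundaries strict, matching their usual statement):
fail when < 25% of retained reads are 20–25 nt, when > 75% of input reads
were discarded, or when < 10% of retained reads classify as miRNA. The
20–25 nt and miRNA fractions are computed over *retained* reads and the
discard fraction over *input* reads; that is the natural reading of
"reads were discarded" versus "reads were identified", and the choice is
isolated in `qc_sample()` if a sensitivity analysis is wanted. A study is
excluded when strictly more than half of its samples fail, or when any
sample's contaminant-clade fraction of classified miRNA reads exceeds
0.10 (configurable; "significant contamination" has no published numeric
threshold).

# Annotation merging and counting

Mature miRNA genes with near-identical sequences cross-map, so annotations
are merged before counting: two annotations are related when their mature
sequences differ by at most 1 mismatch over the shorter length (5'-aligned)
and at most 2 nt of 3' length difference; connected components of this
relation (union-find, transitive closure) become merged groups. Both
tolerances are configurable via `merge_config()` so the relation can be
calibrated against a real reference (on the full human MirGeneDB 2.0
catalogue the published pipeline reduces 537 annotations to 389 groups;
that external calibration is out of desk-scale scope here, but the knobs
exist). Each retained read increments exactly one group when it matches
exactly one representative sequence under the classification tolerance;
reads matching two or more groups are counted as ambiguous and dropped
(merging is the intended mechanism for cross-mapping, so residual
ambiguity is surfaced, not silently split), and unmatched reads are
tallied as unassigned. RPM denominates over miRNA-assigned reads, the
standard convention for miRNA-seq.

# Differential expression

The DE engine is a from-scratch negative-binomial GLM rather than a call
into an external DE package; the package implements the model it tests.

* **Normalization** — median-of-ratios size factors over genes with
  all-positive counts, rescaled to geometric mean 1.
* **Dispersion** — genewise method-of-moments on normalized counts using
  the pooled *within-group* variance (so planted group effects do not
  inflate dispersion): `alpha_i = max((var_i − mu_i)/mu_i², 1e-8)`. A
  robust least-squares trend `alpha(mu) = a0 + a1/mu` is fitted across
  genes (MASS::rlm, coefficients clamped non-negative), and the final
  dispersion blends genewise and trend values on the log scale with
  weight 0.5 each. There is no Cox–Reid adjustment; the blend plays the
  moderation role. Null simulations (2,000 genes, alpha 0.1, 20 vs 20)
  show rejection at nominal 0.05 between 0.048 and 0.059 and
  Kolmogorov–Smirnov distance from uniform around 0.02, which we consider
  adequate calibration for this design.
* **Wald test** — per-gene IRLS fit of
  `log mu = log s_j + b0 + b1·group`, dispersion fixed, vectorized across
  genes (all genes share the design matrix, so each IRLS step is a
  closed-form 2×2 weighted solve per gene). Convergence: relative
  deviance change below 1e-8, at most 100 iterations; non-converged genes
  get `p = NA` and are excluded from the BH denominator, as are genes
  with all-zero counts. SE comes from the observed Fisher information,
  `z = LFC/SE`, two-sided normal p.
* **Shrinkage** — posterior mean under a zero-centred normal prior:
  `LFC·v/(v + SE²)` with `v = max(mean(LFC²) − mean(SE²), 0.0625)` unless
  supplied. The published analysis used an LFC-shrinkage function whose
  prior family is not stated; the normal-prior posterior mean is adopted
  as a deliberate approximation with clean limits (exact at SE → 0,
  halves the estimate at SE² = v).
* **Multiple testing** — Benjamini–Hochberg step-up, implemented directly
  and tested against both a brute-force evaluation of the formula and
  `p.adjust`.
* **Relevance filter** — FDR < 0.05, |LFC| > 0.58 (≈1.5-fold) and mean
  expression > 100 RPM in at least one compared group, all strict. The
  filter is applied to the shrunken LFC (the quantity a results table
  would print); a config flag switches to the MLE.
* **VST** — the closed form for the fitted trend,
  `log2((1 + a1 + 2·a0·n + 2·sqrt(a0·n·(1 + a1 + a0·n)))/(4·a0))`,
  monotone and asymptotically `log2(n)`; falls back to `log2(n+1)` with a
  warning if the trend intercept is non-positive.

# Background correction

Sign convention, fixed everywhere and stamped on outputs: **positive =
higher at the metastatic / normal-site organ**. Foreground contrasts are
(metastasis vs pCRC); background contrasts are (site-normal vs nCR) and
(site-normal vs pCRC). A miRNA enters a site's background set, with its
sign, when it passes the *full* relevance filter in either background
contrast (one relevance standard throughout; requiring only FDR is a
config option). A relevant foreground call is suppressed when the
background set contains the same miRNA with the same sign; opposite-sign
background never suppresses. PM has no adjacent normal tissue, so the
signed union of the liver and lung sets is used: a PM call is suppressed
if either site's background matches its sign. The combination rule for
the two background contrasts is a `mode` flag
(`union`/`ncr_only`/`pcrc_only`/`intersection`); union is the default
because background evidence from either comparison indicates host-organ
expression.

# Cell-type-specific miRNAs

A curated marker list (45 miRNAs, `inst/extdata/celltype_mirnas.tsv`,
editable) supports composition analysis on real data; on synthetic data
the generator's own labels are used. Markers are kept when their mean
expression exceeds 100 RPM in at least one tissue (strict). The heatmap
matrix is the per-tissue mean of per-sample z-scores of RPM (z-scores are
taken across samples, not across tissue means — the per-sample values are
retained so either view can be built). PCA is computed on unit-scaled VST
values (correlation PCA, matching a correlation-circle presentation of
loadings) with a sign convention making each loading's largest-magnitude
entry positive; a flag switches to covariance PCA. Welch's two-sided
t-test with Welch–Satterthwaite degrees of freedom compares mean VST
values between tissue groups.

# Gene-set enrichment

Up-regulated miRNAs suppress their targets, so each miRNA receives
`S_miRNA = −log10(FDR)·sign(LFC)` (FDR floored at 1e-300 to stay finite;
using the post-correction FDR as the significance input, with a flag for
raw p), each gene the sum of `S_miRNA` over the distinct miRNAs predicted
to target it, and each set a logistic regression of membership on the
gene score over the universe (all interaction-map genes plus all set
members; untargeted genes are informative zeros). `b1 > 0` means "more
suppressed". The background correction feeding this stage interpolates:
with a significant same-sign background of relative magnitude
`r = min(1, |LFC_bg|/|LFC|)`, `LFC' = LFC·(1−r)` and
`FDR' = FDR + r·(1−FDR)`. No closed form is published for this step; the
interpolation is the simplest rule satisfying the stated qualitative
constraints (LFC pulled to 0, FDR pushed to 1, proportionally to the
background magnitude) with exact limits at r = 0 and r = 1, and it is
config-replaceable. Perfectly separated sets are flagged with `p = NA`
rather than reported with a meaningless slope. BH correction is applied
within each collection separately.

# qPCR validation statistics

Technical replicates are averaged within each assay (replicates are
technical and unpaired across assays, so pairwise differencing has no
basis), then ΔCq = mean target Cq − mean reference Cq per sample; groups
are compared with Welch's two-sided t-test. ΔCq is exactly invariant to
per-sample plate shifts. Spike-ins are treated as QC metadata, not
modelled.

# The synthetic-data generator

The generator defines the study conditions the tests run under:

* **Counts** — each tissue's expected profile is a mixture of cell-type
  expression programs (epithelial, hepatocyte, pneumocyte, immune,
  stromal); each sample draws its own mixing proportions from a Dirichlet
  around the tissue's mixture (concentration 200 by default — tissues
  cluster but are not homogeneous; the within-tissue composition variance
  of real cohorts is unknown, so this is an explicit free parameter),
  multiplies in planted log2 effects, rescales to a library size drawn
  uniformly from 5×10⁵–2×10⁶, and draws NB counts with variance
  `mu + alpha·mu²` (alpha 0.1 by default; 0 degenerates to Poisson).
  Planted *metastasis* effects apply to one tissue. Planted *background*
  effects for site Li apply to nLi, mLi **and PM** (Lu analogously):
  host-organ signal contaminates the bulk metastasis sample — that is
  precisely the artifact the background filter exists to remove, and it
  gives the PM union rule something to suppress.
* **Reads** — six categories (miRNA, low-quality, short, low-complexity,
  contaminant, other-RNA) with largest-remainder rounding so category
  counts are exact; miRNA reads take a mature sequence with up to 2 nt of
  3' truncation/extension (kept within 18–25 nt) plus the adapter;
  low-quality reads have at least 55% of bases at Phred ≤ 20; the
  non-miRNA RNA sequences are returned so the classifier can recognise
  them. A sidecar truth table records each read's category and insert
  length, and recovery tests read truth only from it.
* **Interactions** — each miRNA targets 20% of the gene universe
  uniformly at random, mirroring the density of predicted-target maps;
  genes in planted suppressed sets are additionally targeted by each
  planted up-regulated miRNA with probability 0.8. Dense maps keep gene
  scores continuous; with sparse maps the planted set's scores separate
  perfectly and the logistic fit degenerates.
* **qPCR** — per-sample plate shift shared between assays (cancels in
  ΔCq), biological noise (sd 1 cycle) on the target, replicate noise
  0.1 cycles; defaults n = 11 per group and ΔΔCq = −1, the scale of the
  validation experiment this emulates.

What the generator does *not* emulate: isomiR biology beyond blunt 3'
length variation, sequencing-error substitution profiles, batch effects
between studies, GC or length biases, and correlated multi-gene
expression programs beyond the mixture structure. Passing tests therefore
demonstrate correctness of the statistical machinery under its stated
model, not robustness to every artifact of real cohorts.

# Problem sizes and determinism

The test suite and acceptance script run at desk scale, chosen to keep
Monte-Carlo bands tight without excess runtime: QC exactness on 10,000
reads plus 20 seeded 1,000-read configurations; null calibration on ten
seeds of 2,000 genes at 20 vs 20; effect recovery on five seeds of 400
genes (40 planted, LFC ±1/±1.5 at 200/1,000 RPM, n = 15); background
soundness on twenty seeds of the full seven-tissue panel (250 miRNAs,
n = 10 per tissue, 10 metastasis-only, 10 background-only and 10 dual
effects per site); gene-set recovery on twenty seeds of 50 sets over
1,000 genes plus a 1,000-permutation null. Every generator is a pure
function of its arguments including the seed, and UMAP runs
single-threaded at a fixed seed.

# Known limitations

Two-group designs only (no batch covariates or multi-factor contrasts);
no outlier replacement or independent filtering; the dispersion trend is
a two-parameter reciprocal, adequate for the simulated regimes but less
flexible than spline-based trends; the background interpolation formula
is a modelling choice, not an estimate; UMAP coordinates are
reproducible only within a fixed library version.
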