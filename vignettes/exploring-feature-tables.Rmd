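---
title: "Exploring microbiome and metabolomics feature tables with microexplore"
author: "microexplore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring microbiome and metabolomics feature tables with microexplore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microexplore)
```

## The data model

Amplicon sequencing and untargeted mass spectrometry both produce a
samples-by-features table of non-negative abundances — sOTU (exact
sequence variant) read counts in the first case, MS1 bucket intensities
in the second — together with a sample-metadata table (group, time
point, extraction plate, ...) and a feature-metadata table (taxonomy,
m/z and retention time, curated names). Exploratory analysis constantly
reorders, subsets and transforms this triple, and a bug in which one
table is permuted while another is not silently corrupts every
downstream statistic.

`microexplore` therefore centers on a single S4 container,
`FeatureExperiment`, whose validity method enforces that the matrix
dimnames and the two metadata tables agree after *every* operation.
All operations are non-mutating: each returns a new experiment and
appends one record (operation name, full parameter set, timestamp) to
an operation history. `replayHistory()` re-applies the recorded
sequence to the pristine input and reproduces the derived experiment
exactly, which both documents an exploratory session and turns it into
a reproducible script. Storage may be dense or sparse
(`Matrix`-backed); the two modes are observationally equivalent, and
the test suite asserts element-wise identity between them.

```{r model}
fx <- makeCountExperiment(nPerGroup = c(10, 10), nFeatures = 100,
                          nDiff = 10, effectFold = 4, seed = 1)
fx$experiment
```

## Normalization and transforms

Sequencing depth is a nuisance parameter: counts are compositional.
The package provides the standard repertoire:

* **TSS** (`normalizeTSS`): rescale every sample to a fixed total,
  10000 by default — the usual "reads per 10k" convention that keeps
  normalized values on an interpretable pseudo-count scale.
* **Outlier-excluding TSS** (`normalizeTSSOutliers`): a single bloom
  taxon can dominate a sample and compress everything else under plain
  TSS. Features whose within-sample relative abundance exceeds
  `outlierFraction` (default 0.1) are excluded from the scaling
  denominator; relative abundances of the remainder are recomputed and
  the exclusion repeated until stable. The excluded set can only grow,
  so the iteration terminates. The final factor is applied to *all*
  features of the sample — the alternative (rescaling only the
  non-excluded ones) would break within-sample ratios; exclusions are
  reported so the analyst can see which taxa were treated as blooms.
* **CLR** (`transformCLR`): per-sample centered log-ratio with a
  pseudocount shift (default 1) handling zeros. We chose the
  pseudocount over model-based zero replacement because it is simple,
  monotone and parameter-transparent; the output sums to zero per
  sample and is flagged non-count.
* **Log** (`transformLog`): `log2(max(x, 1))` by default, so zero
  counts map to exactly 0 and ordering is preserved.
* **Binarize** (`binarize`): presence/absence with a strict `> cutoff`
  rule (default cutoff 0), the substrate of the presence/absence test.

Unit-variance scaling (`scaleFeaturesUnit`) uses the population
(divide-by-n) standard deviation; either convention is defensible, one
is fixed and documented. Zero-variance features scale to zero rather
than NaN.

## Ordering and clustering

Heatmap readability is mostly an ordering problem. Sorting is by
metadata fields (stable lexicographic, so nested orderings can be
built field by field), by feature total or prevalence, or by the
center of mass `com(f) = sum(p * x_pf) / sum(x_pf)` over the 0-based
positions `p` of a chosen sample gradient — useful for time courses.

`clusterOrder` reproduces the usual heatmap pipeline: log transform,
per-feature (or per-sample) centering and unit-variance scaling,
Euclidean distances, single-linkage agglomeration (average and
complete linkage are available behind a flag), then a dendrogram leaf
traversal. Dendrograms leave the left/right orientation of every merge
ambiguous; we fix it deterministically by visiting, at each merge, the
subtree containing the lexicographically smallest identifier first.
Keying this rule on identifiers rather than input positions makes the
final order invariant to how the input columns happened to be stored,
not just reproducible. When clustering samples the unit scaling is
applied per sample, mirroring the per-feature scaling used for
features; this per-axis symmetry is a design choice.

## The permutation tests

The differential-abundance test (`diffAbundance`) compares a
per-feature statistic between two sample groups defined by a metadata
field. The statistic is the mean difference of (optionally
transformed) values; with the default rank transform (mid-ranks within
each feature, computed over the selected samples only) it is the
rank-mean test, and with `transform = "binarize"` it is the
presence/absence test. Significance comes from the permutation
distribution under random group-label shuffles:

* **Exhaustive mode** enumerates every distinct assignment of the
  group sizes (at most 20000, above which the code asks for random
  mode); the observed labeling is one of the enumerated rows, so
  `p = count / B`.
* **Monte-Carlo mode** draws seeded label shuffles and uses the
  add-one rule `p = (1 + count) / (1 + B)`, which keeps p strictly
  positive as step-up corrections require.

Two-sided testing compares `|statistic|`; one-sided testing is a flag.
Statistic comparisons carry a relative tolerance of `1e-9` so that
floating-point ties (e.g. a reversed correlation that differs in the
last bit) count as ties.

`correlationTest` applies the same machinery to a continuous metadata
field, with Spearman (ranks, the default) or Pearson correlation as
the statistic and permutation of the field vector as the null.
Zero-variance features get statistic 0 and p = 1 by convention. The
phrase "correlating a field to feature prevalence" is ambiguous
between abundance and presence; the default correlates abundance, and
`presence = TRUE` binarizes first to give the prevalence reading —
both are documented rather than one guessed.

### Multiple testing

Three corrections are provided:

* **dsFDR** (`dsfdrControl`) operates directly on the statistic scale.
  For every candidate threshold t (the observed `|s|` values) it
  estimates
  `FDRhat(t) = min(1, mean_b #{j: |s_perm_bj| >= t} / max(1, #{j: |s_obs_j| >= t}))`,
  rejects at the smallest observed t with `FDRhat(t) <= alpha`, and
  assigns each feature the smallest `FDRhat` among thresholds that
  would reject it as its q-value (monotone non-increasing in `|s|`).
  Sparse count data have coarse p-value supports; working on the
  statistic scale avoids the power loss that p-value-based step-up
  procedures suffer there. The `min(1, .)` cap and `max(1, .)`
  denominator guard define the degenerate cases.
* **BH** (`bhControl`): the standard step-up, via `p.adjust`.
* **Filtered BH** (`filteredBhControl`): features whose smallest
  achievable p-value (computed from their own permutation-null
  support) exceeds alpha can never be rejected and only dilute the
  testing family; they are removed before BH runs on the remainder.

A property worth stating explicitly because it shapes expectations on
simulated data: any procedure calibrated at FDR alpha admits on
average about `alpha / (1 - alpha) * R` false discoveries among `R`
rejections. With alpha = 0.1 and ten true effects, roughly one null
feature accompanies the true positives in a substantial fraction of
runs — that is the definition of FDR control, not a defect. The
acceptance suite measures both the mean false-discovery proportion
(controlled at alpha) and the fraction of zero-false-positive runs
(roughly 40% under these conditions, as the calculation above
predicts).

## The annotation store and term enrichment

Curated knowledge about features — "these sequences are higher in
skin", "this metabolite is a known reagent contaminant" — is modeled
as typed annotations: a set of feature identifiers, a list of ontology
terms, and a type among higher_in, lower_in, common, high_freq,
contamination, other. The store is a local JSON-lines or TSV file
behind a small interface (`loadStore`, `featureAnnotations`,
`termScoreMatrix`), so a remote curation service could back the same
interface without touching the statistics. Ontology terms are treated
as flat labels; no expansion to ancestor terms is performed.

Term scores sum per-annotation contributions of +2 (higher_in,
high_freq), +1 (common) and -2 (lower_in). `enrichTerms` ranks each
term's scores across the features of the two groups (features with no
annotations keep score 0 — absence of a term is information), takes
the mean-rank difference as the per-term statistic, permutes *feature*
group labels for the null, and controls dsFDR at alpha.
`flagContaminants` writes a contaminant/annotated/none status column
usable as a metadata filter or heatmap track, and `mostCommonTerm`
summarizes a feature by its best-scoring candidate term, with ties
going to the earlier candidate and non-positive totals mapping to
"other" — both rules are package decisions, stated here because only
the display they feed is conventional.

## Heatmaps

`renderHeatmap` draws features as rows and samples as columns (the
display transpose of the internal convention), colors cells through a
perceptually uniform colormap on a `log2(x + 1)` display scale by
default (so zeros sit at the colormap minimum), and adds one
categorical color track per requested sample field plus an optional
feature track. Rendering is a pure view — it never reorders the
experiment; order it first with the sorting functions.

Output is composed directly by the package: PNG rasters via
`png::writePNG`, SVG and HTML as text. This makes output byte-identical
for a fixed experiment and spec, with no dependence on a graphics
device or font stack; the SVG and HTML variants carry labels and a
legend, the PNG carries the color geometry only. Track colors come
from a string hash of the category value into a fixed 64-color
palette, so a category keeps its color across runs and across
experiments; hash collisions can give two categories the same color
but never an unstable one. `exportHtml` produces a single
self-contained file — embedded full-precision JSON payload (matrix,
identifiers in display order, tracks, optional per-feature annotation
summaries) plus an inline SVG — that opens without network access.

## The synthetic-data generator

`makeCountExperiment` emulates the statistical skeleton of an amplicon
count table: log-normal baseline feature means (sdlog 1, giving the
typical orders-of-magnitude abundance spread), negative-binomial
counts with variance `mu + 0.2 * mu^2` (moderate overdispersion; 0.2
sits in the range commonly fitted to real 16S data), and per-sample
depths uniform within ±20% of the nominal depth. Effects are planted
by multiplying the group-1 means of the first `nDiff` features by
`effectFold`, leaving every null feature's mean untouched in both
groups, so the returned truth mask is exact. The metadata carry the
group, a random two-level extraction plate, and a continuous covariate
correlated at 0.8 with the first planted feature for correlation
tests.

What the generator deliberately does **not** emulate: phylogenetic
correlation between features, compositional coupling of planted
effects (a real 4-fold bloom depresses every other relative
abundance), batch structure beyond the plate label, chimeras and
denoising artifacts. Passing tests on this substrate demonstrate that
the statistics, orderings and IO behave as specified — not that any
particular biological dataset will yield a particular discovery count.

`makeAnnotationStore` plants one annotation tying a term to a chosen
feature subset and surrounds it with decoy annotations whose
term/feature assignments are exchangeable across any feature grouping,
which is exactly the null the enrichment test permutes against.

## Numerical and interface choices

* Problem sizes in the test and acceptance suites — e.g. 100 null
  fixtures of 20 x 100, 50 planted fixtures, 999-1000 permutations —
  were chosen so Monte-Carlo standard errors are small relative to the
  thresholds being checked while the whole suite runs in well under a
  minute on one core.
* Indices in the R interface are 1-based (R convention); the
  center-of-mass statistic uses 0-based positions within the chosen
  subset so the uniform-feature closed form `(k - 1) / 2` holds.
* Boundary semantics are "kept at the threshold": total-abundance
  filtering removes strictly-below-threshold features, prevalence
  filtering keeps features at exactly the minimum fraction.
* Metadata columns are kept as character unless every non-missing
  value parses as a number, in which case the column (and sort
  comparisons on it) become numeric.
* Degenerate inputs are explicit: all-zero samples error under TSS
  unless `dropZero = TRUE`; empty filter results warn and return an
  empty experiment; features with zero mass over a center-of-mass
  subset sort last with a warning.

## Command-line interface

Every module is reachable from the shell through the `microexplore`
script (in `inst/exec/`; `cliMain()` is the same entry point callable
from R). Subcommands — `load`, `transform`, `filter`, `sort`, `diff`,
`correlate`, `enrich`, `heatmap`, `fixtures` — communicate via on-disk
experiment bundles (table + metadata + history sidecar), so each step
of a shell pipeline is individually inspectable and replayable. Exit
codes: 0 success, 1 validation error, 2 usage error. Result tables are
tab-delimited with a commented header recording the tool version and
the full parameter set.

## Known limitations

Paired or blocked designs and covariate-adjusted models are out of
scope, as are rarefaction, live database clients, machine-learning
wrappers and interactive GUI widgets. The exhaustive-enumeration cap
(20000 assignments) keeps memory bounded; above it, seeded Monte Carlo
is the supported path. HDF5 BIOM (2.x) is read only if the underlying
reader supports it; the mandatory interchange dialect is BIOM-JSON 1.0.
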