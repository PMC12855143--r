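---
title: "Methods: an age-resolved single-cell thymus analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an age-resolved single-cell thymus analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thymatlas)
```

# Scope and data model

The thymus involutes with age: its cellular composition shifts (fewer
immature double-negative thymocytes, more late-differentiated cells
such as regulatory T cells), and transcription becomes noisier in some
lineages. This package implements the computational stages such an
age-resolved single-cell atlas analysis needs once a count matrix
exists — everything downstream of alignment and quantification, and
everything upstream of biological interpretation.

All stages consume and produce one container, built by
`expression_dataset()`: a sparse cells × genes integer count matrix, an
optional normalized layer of identical shape, a cell table (sample,
ordered age group, optional cluster/cell type/pseudotime, QC metrics)
and a gene table (symbol plus `is_mito`, `is_rbc`, `is_lincRNA`,
`is_senescence` flags and optional orthologue links). On disk the
matrix is Matrix Market, genes × cells — the convention of the 10x
ecosystem — and is transposed to cells × genes in memory; metadata
travel as tab-separated tables. The functions, this vignette, and
`scripts/acceptance.R` are the package's interface; each stage is a
plain R function, so a shell wrapper would add nothing over
`Rscript -e`.

# Normalization and batch residualization

Counts are scaled per cell to a common library size and
log-transformed: `normalized = ln(1 + count * scale / total)`, with
`scale = 1e4`. This is the de-facto standard of the major single-cell
toolkits; the scale factor and log base are conventions, not
measurements, and both are parameters. Cells with zero total counts
are an error, not a silent drop.

`regress_out_batch()` fits, per gene, a ridge regression of normalized
expression on one-hot batch indicators, keeping the intercept
unpenalized by centering, and replaces the layer with residuals plus
the gene's grand mean. The one-hot design with a small default penalty
(1.0) is deterministic and well-posed even though centered full
dummies are rank-deficient; as the penalty goes to zero the result
converges to ordinary least-squares residualization (verified to
1e-8 in the tests), and as it grows the layer is returned unchanged.
Single-level batch columns are a warned no-op.

# Quality control

Cells are retained when they express between `min_genes = 200` and
`max_genes = 5000` genes — inclusive bounds, matching the phrasing
"between ... and ..." — while the mitochondrial and red-blood-cell
fractions must be *strictly* below 5% and 1%, matching "less than".
This asymmetry is deliberate and pinned by the boundary fixture
`make_qc_fixture()`, which places cells at 199/200/5000/5001 detected
genes and 4.9/5.0% and 0.9/1.0% fractions. lincRNA genes are removed
*before* any metric is computed, so they never count toward detected
genes or totals; genes detected in fewer than 3 retained cells are
dropped afterwards (the same support rule the cross-species and
senescence stages reuse). Excluded cells are tallied once each, under
their first failing rule in the order gene-range, mito, rbc, so the
tallies partition the exclusions. Filtering is idempotent.

# Clustering and markers

`cluster_cells()` is a contract, not an algorithmic novelty: scale
genes to unit variance (clipped at ±10), PCA, k-nearest-neighbour
graph, Louvain community detection at resolution 0.8 under a fixed
seed. Any implementation honouring that contract is acceptable; the
package uses `stats::prcomp` and `igraph::cluster_louvain`, with
labels renumbered densely from 1 by decreasing cluster size.

`find_markers()` tests each gene per group against all other cells
with a two-sided Wilcoxon rank-sum test on the normalized layer. The
effect size is the natural-log fold change of de-logged means with
pseudocount 1. Two numerical choices matter:

* For small groups (enumeration up to 10,000 assignments) the p-value
  is computed by exhaustively enumerating group assignments of the
  midranks. The large-sample normal approximation with tie correction
  is misleading at, say, 3 vs 3 cells with heavy ties, where the exact
  attainable two-sided p for complete separation is 0.1.
* Benjamini–Hochberg adjusted p-values are always computed, but the
  retention threshold uses the raw p by default (`adjust = FALSE`) for
  cluster markers and the adjusted p for senescence contrasts,
  mirroring the different conventions those analyses usually state.
  Both are exposed.

`annotate_clusters()` assigns each cluster the annotation rule with
the highest fraction of its required markers among the cluster's
significant markers, ties broken alphabetically — a deliberately
transparent scoring that is easy to audit, not a classifier.

# Composition

Proportions are cells of a type over cells of the same sample in the
same sorting gate; the default single gate reflects whole-organ
dissociation. `test_proportion_change()` uses a Welch t-test on
per-sample proportions when both groups have at least two samples. A
one-animal-per-age design makes that impossible, so with a single
sample on either side it falls back to a two-proportion z-test on
pooled counts and *labels the result* (`method = "pooled_z"`): the
z-test treats cells, not animals, as replicates, and should be read as
within-dataset evidence only.

# The aging CV statistic

For a cell type and an age pair, all young×old absolute expression
differences are enumerated per gene on the normalized layer, and
CV = sd/mean × 100 of those distances is reported, with the sample
(n−1) standard deviation. Choices worth stating:

* Genes whose distances are all zero (μ = 0) get an undefined CV and
  are excluded from summaries — 0/0 is not evidence of low variation.
* Above `max_pairs = 1e6` pairs, a uniform subsample without
  replacement is drawn under a recorded seed; below the cap the
  enumeration is exact, and the tests pin exact agreement (to 1e-12,
  i.e. up to floating-point summation order) with an independent
  double-loop oracle.
* The CV is invariant to adding a constant to all expression values,
  and — for symmetric expression distributions — invariant to pure
  rescaling; what raises it is heavier-tailed variability, which is
  exactly what count-level variance inflation at fixed mean produces
  after the log transform.
* HVGs are selected on the union of the two age groups being compared,
  by the residual of log variance from a robust (degree-1, symmetric
  family) loess mean–variance trend, ties broken by gene id, keeping
  `ceiling(fraction × n_genes)` genes. The robust degree-1 fit matters:
  a single high-dispersion gene at an isolated mean would otherwise
  act as a leverage point and pull a local quadratic trend through
  itself.

`compare_cv()` contrasts per-gene CV distributions between cell types
or age pairs with a Wilcoxon rank-sum test. With identical inputs the
large-sample approximation returns a p-value slightly below 1 (the
continuity correction); the statistic, not the p, is the equality
check there.

# Cross-species conservation

Orthologue candidates are resolved to a one-to-one map by keeping, in
each conflicted group, the gene with the highest total expression in
its own species (ties to the lexicographically smaller id). Enriched
markers are genes detected in more than 5% of a type's cells with
log2 fold change > 0.5 over all other cells on de-logged means
(pseudocount 1e-9). Reference markers are then classified per other
species with the precedence **Conserved > Switch > Loss >
NotDetected**; Switch precedes Loss because an enriched gene is
necessarily detected, so the categories stay mutually exclusive. The
overall label is Conserved only when every species agrees; otherwise
the weakest per-species category is reported, with the per-species
detail kept in the output. "Detected" re-uses the ≥1 count in ≥3
cells rule. A detection-level complement
(`classify_expression_overlap()`) classifies conserved / gain / loss
of *expression* per (gene, cell type) on detection fractions alone.
Cross-species embedding and integration are out of scope: matched
cell-type labels are an input.

# Senescence trends

`build_library()` unions aging-gene lists after case folding and
synonym canonicalization, recording provenance; it is order-invariant.
The published libraries behind such analyses are cited rather than
printed in most papers, so the library ships as a user input plus the
generator's flags. "Expressed" means ≥1 count in ≥3 cells of the age
group. Age contrasts use the same Wilcoxon/log-fold-change machinery
as the marker stage, thresholded at |avg_logFC| > 0.25 and adjusted
p < 0.05 within each (cell type, contrast). Per-gene trends over ≥3
age groups are the sign of the Spearman correlation between per-age
mean expression and age rank, with |ρ| < 0.5 reported as "mixed".

# Pseudotime modules

Pseudotime is an input (from any trajectory tool, or the simulator);
graph learning is not reimplemented. Cells are ranked into
equal-frequency bins (ties by cell id; sizes differ by ≤1). The
statistic — the maximum over bins of the standardized bin-mean
deviation, with a pooled within-bin sd — realizes "different in *any*
bin"; an F-like variance-ratio alternative sits behind
`stat = "frat"`. The permutation p uses the add-one estimator, so the
smallest attainable p is 1/(n_perm+1), and constant genes are defined
to statistic 0, p 1. Significant genes' binned profiles are smoothed
(window-3 moving average, edge-shrunk), z-scored (constant profiles
become zeros, with a degeneracy warning), and clustered by average
linkage on correlation distance; the tree is cut at a user-set K, and
modules are numbered by profile-peak position so module 1 always
peaks earliest.

K is a parameter, not an estimate: published module counts (e.g. 17)
are data-specific. `suggest_module_count()` prints a silhouette-based
suggestion but the pipeline never applies it automatically. The bin
count defaults to 20; for large K the bins must out-resolve the
expected module spacing, so analyses at K = 17 here use 40 bins
(roughly 2.4 bins per module onset) — with 20 bins, adjacent module
templates can land in the same bin and merge.

# The synthetic-data generator

`generate_dataset()` draws counts from a Gamma–Poisson (negative
binomial) model — the community-standard generative stand-in for UMI
counts. Gene baselines are log-normal (meanlog log 0.5, sdlog 1,
i.e. typical sparse UMI depth per gene); cell types multiply their
marker genes by exp(effect); senescence-flagged genes drift by
exp(direction × shift × age rank), age acting through rank because age
groups are ordinal; mito/rbc/lincRNA classes are rescaled to fixed
shares of the expected library (2%, 0.3%, 1%); and per-(age, type)
variance inflation rescales the count variance at unchanged mean by
adjusting the NB size parameter. The default scene mirrors an aging
thymus qualitatively: four ordered ages, eight types, a
regulatory-T-like fraction rising 1.7% → 7.2% and double-negative-like
fractions falling, dispersion θ = 2, marker effect 1.5 on the natural
log scale.

`generate_lineage()` plants module structure directly on the log
scale: true pseudotime ~ Uniform(0,1), Gaussian-bump templates of
width 0.5/K at onsets (k−½)/K, amplitude 3, Gaussian noise sd 0.5,
flat noise genes at baseline 1; the count layer is the rounded inverse
log1p. `make_qc_fixture()` is fully deterministic and enumerates every
QC boundary.

What the generator does *not* emulate — and hence what passing tests
cannot show about real data: ambient RNA, doublets, batch chemistry
effects, zero-inflation beyond NB, gene–gene correlation within cell
types, and branching topologies. Recovery results on these simulations
validate the estimators' logic and calibration, not their robustness
to artefacts.

# Validation scales and determinism

Every stochastic stage takes an explicit seed and is bitwise
reproducible given it. The test and acceptance suites validate at the
following problem sizes, chosen to make the statistical claims
testable while keeping a full run in minutes on one core: CV-inflation
recovery over 100 simulation seeds (300 cells/group, 200 genes,
inflation ×3); permutation type-I error on 2000 null genes (400 cells,
999 permutations); module recovery at K = 17 with 40 genes/module and
1000 cells; conservation-classifier agreement with an exhaustive
oracle over 1000 randomized cases; composition power (100 seeds) and
calibration (500 seeds) in a 20-sample scene of 1000-cell samples.

# Known limitations

* The composition z-test fallback cannot separate animal effects from
  sampling noise; with one animal per age that is a property of the
  design, not the test.
* The CV statistic is undefined for genes with no expression
  difference in any pair, and its comparison across cell types
  inherits the usual caveats of unequal cell numbers; pair
  subsampling above the cap adds Monte-Carlo noise, recorded via
  `n_pairs_used`.
* Orthologue resolution by expression is a heuristic; sequence-based
  orthology is out of scope.
* Cluster annotation scores marker presence only; it does not weigh
  expression magnitude or penalize missing markers beyond coverage.
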