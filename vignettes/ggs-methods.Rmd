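---
title: "Greedy gene set selection and expression imputation: methods and design"
author: "ggsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy gene set selection and expression imputation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggsel)
```

## The problem

Genome-wide expression assays are too expensive to run on very large
sample collections (archival FFPE tissue in particular), so most targeted
studies measure a few dozen to a few hundred genes. Within a fixed tissue
and disease context, however, gene expression is strongly and stably
correlated, so a well-chosen panel of *directly measured* (DM) genes
carries information about many genes that were never assayed — the same
logic by which tag SNPs stand in for untyped variants through linkage
disequilibrium. `ggsel` chooses such a panel from a co-expression network
and then trains per-gene regression models that infer the unmeasured
expression, with rank-based accuracy evaluation that transfers across
platforms.

This is only sensible for stable co-expression systems (e.g. a fixed
tumor type assayed at one disease stage). In dynamic systems such as
differentiation, where the correlation structure itself changes, the
inferred panel has no validity.

## The pipeline

1. **Filtering.** Genes that are not expressed carry no exploitable
   correlation. For each gene we compute the 90th percentile of its
   expression across samples (`quantileFilter()`, linear-interpolation
   quantile, `stats::quantile` type 7) and drop genes below a cutoff
   (default 5 on the log-like array scale, chosen to sit between the two
   modes of the typically bimodal quantile distribution). The quantile
   convention is not forced by the method; type 7 is documented as the
   package convention because it is the default in the analysis
   environments this field uses. Both the quantile level and the cutoff
   are parameters.
2. **Correlation and thresholding.** `geneCorrelation()` computes the
   all-pairs Pearson matrix on the filtered, log-scale (unscaled) data;
   `binarize()` thresholds its absolute value at `|r_P|` (typical grid:
   0.60, 0.65, 0.70) into a binary adjacency. Negative correlation is as
   predictive as positive, hence the absolute value; a pair exactly at
   the threshold is an edge.
3. **Eligibility.** A gene is *eligible* at fold redundancy `n` when it
   has at least `n` neighbors (`eligibleGenes()`). Only eligible genes
   can be selected or predicted, so the adjacency is restricted to the
   eligible-by-eligible submatrix before selection
   (`restrictToEligible()`). Eligibility is computed once, on the full
   adjacency, and not re-iterated after restriction: restriction can push
   the degree of a redundancy-2+ gene below its redundancy, but we treat
   eligibility as a property of the original network, keep the behavior
   deterministic and single-pass, and leave the restriction step explicit
   in the API so the alternative can be composed by hand.
4. **Greedy selection (GGS).** `ggsSelect()` loops four operations until
   the DM set reaches the requested size: sort genes by degree in a
   *working* adjacency; add the highest-degree gene to the DM set; move
   genes that are now correlated with at least `redundancy` DM genes into
   the predictable set; remove all edges incident to the new DM and
   predictable genes from the working adjacency. Edge removal is the
   essential step — it stops the selection from spending the whole budget
   inside one dense, mutually-correlated neighborhood, which is exactly
   what the `rankedDegreeSelect()` control (top-k by degree, no removal)
   does wrong.
5. **Imputation.** For each predictable gene, the predictors are all DM
   genes adjacent to it in the *original* adjacency
   (`predictorSets()`). After per-dataset min-max scaling to [0, 1],
   `trainModels()` fits a random forest of regression trees when there
   are at least two predictors and otherwise a polynomial least-squares
   model; `predictExpression()` applies the models to any dataset that
   contains the required genes, and `evaluatePredictions()` scores each
   gene by the Spearman rank correlation between observed and predicted
   values, with a bootstrapped standard error on the mean.

## Design decisions at genuinely open points

**Predictability bookkeeping.** The four-operation loop removes edges as
it goes, which creates an ambiguity: when testing whether a gene has
`redundancy` DM neighbors, do pruned edges still count? We count
neighbors in the original adjacency, via counters maintained
incrementally as DM genes are added, while degree sorting uses the pruned
matrix. Under the literal-pruning reading a gene's edge to a DM gene
disappears at the moment that gene is selected, so no gene could ever
accumulate two DM neighbors and redundancy ≥ 2 would be unsatisfiable;
original-adjacency counting is the only reading under which
multi-redundancy selection is coherent. The literal variant remains
available (`prunedPredictability = TRUE`) for comparison, and the 4-cycle
unit test documents the observable difference.

**Tie-breaking.** Degree ties are broken toward the lexicographically
smallest gene identifier, compared in byte (C-locale) order. Any fixed
rule would do; a deterministic one is required for reproducible panels
and for oracle testing, and byte order is platform-independent.

**Candidate seeding.** A hypothesis-driven candidate set (e.g. a
prognostic signature) is added to the DM set wholesale before any greedy
iteration, predictability counters are updated in bulk, and greedy
augmentation proceeds on the pruned graph. `dmSize` counts the
*additional* greedy genes by default, since the natural question is "what
do k extra assays buy me"; `candidatesCountTotal = TRUE` gives total-set
semantics. Candidates absent from the network stay in the DM list — they
will still be assayed — but contribute no edges, and a warning names
them.

**Early exhaustion.** If no open gene has pruned degree ≥ 1 before the
budget is spent, selection stops and records the shortfall rather than
padding with isolated genes, which would add measurement cost and no
predictive value.

**Polynomial degree.** The single-predictor model is least squares on
intercept + x + x², i.e. two polynomial terms beyond the intercept. The
degree is a parameter (`degree`), so a linear or cubic variant is one
argument away. With two or more predictors a random forest (500 trees by
default, `randomForest` regression defaults otherwise, seeded) is used;
forest hyperparameters are recorded in the model metadata.

**Scaling scope.** Min-max scaling is computed per gene per dataset:
training, testing, and each validation cohort are scaled independently.
Nothing is carried across datasets — deliberately, because evaluation is
rank-based (invariant to monotone per-gene transforms, which the test
suite asserts) and per-dataset scaling is robust to platform-wide
location/scale differences. Absolute-expression prediction is out of
scope; predictions are not clipped to [0, 1] by default.

**Missing data.** Matrices with missing cells are rejected at ingestion
with the offending coordinates, rather than handled pairwise-complete
downstream. The skip rule at prediction time (a model is applied only
when its response and all its predictors are present in the dataset) is
the one place where dataset composition differences are tolerated, and
skipped models are counted in the evaluation.

## The synthetic data model

`syntheticSpec()` describes a single-factor-per-block generative model:
each block of genes shares a latent standard-normal factor, and gene
expression is `loading * factor + N(0, noiseSd²)` shifted to a plausible
log-expression baseline (mean 8). The expected within-block Pearson
correlation is then

    r = loading² / (loading² + noiseSd²)

so the planted structure is analytically known: at a threshold strictly
between the within-block and background correlations every block is a
clique and nothing else has edges, eligible counts are block arithmetic,
and greedy selection resolves blocks round-robin — with
`dmSize = redundancy × nBlocks` the predictable count is exactly
`nBlocks × (blockSize − redundancy)` (`plantedExpectations()`).
Independent background genes supply the null edge distribution, and a
configurable fraction of genes is planted below the expression cutoff so
the filter has real work to do. A paired validation cohort (same blocks,
new samples, optionally different noise) exercises cross-dataset
evaluation.

The defaults — 5 blocks × 10 genes, 500 samples, expected within-block
r = 0.8, 100 background genes, 20 % low-expression genes — give strong
separation: the null correlation at n = 500 has standard deviation
≈ 0.045, so a 0.6 threshold is ~13σ from the background and well below
the planted 0.8. Gaussian factors and noise are a deliberate
simplification: real array data have heavier tails, probe effects, batch
structure and overlapping pathway membership, none of which the generator
emulates. Passing the planted-recovery tests therefore demonstrates
algorithmic correctness under clean separation, not expected performance
on real cohorts, where thresholds sit inside the bulk of the correlation
distribution and recovery is necessarily partial.

## Numerical and degenerate-input choices

- Correlation matrices are symmetrized (`(r + t(r))/2`) and the diagonal
  pinned to 1 before thresholding, so floating-point dust cannot create
  asymmetric edges.
- Constant genes are errors, not silent drops, in both `geneCorrelation()`
  (undefined correlation) and `minmaxScale()` (zero range): they should
  have been removed by the filter, and silently dropping them would
  desynchronize gene universes between stages.
- `trainTestSplit()` assigns `round(fraction × n)` samples to training
  (clamped so both partitions are non-empty) after a seeded shuffle; no
  stratification.
- Spearman correlations use average ranks for ties; a constant predicted
  vector has undefined rank correlation and is excluded from the mean
  (this is only reachable with degenerate forests).
- The bootstrap standard error is the SD of the means of `B` seeded
  resamples (default 1000); singleton or constant inputs give 0.
- All stochastic steps (split, forest, bootstrap, simulation) take
  explicit seeds, applied via `withr::with_seed` so the caller's RNG
  state is never disturbed.

## Complexity

The co-expression graph is held as a dense adjacency matrix — O(n²)
space. Each greedy iteration re-derives degrees from the working matrix
and zeroes at most n rows/columns, O(n²) work, so a k-gene selection is
O(k·n²); the iteration count equals the requested DM size short of early
exhaustion, which the test suite asserts. The parameter sweep exploits
greedy nesting — for a fixed threshold and redundancy, the DM list at
size k is a prefix of the list at any larger size — so one long run per
(threshold, redundancy) pair serves all 16 DM sizes of the default
3 × 3 × 16 = 144-run grid.

## Problem sizes in the test suite

The suite validates the greedy implementation against an independently
coded naive reference on 200 random graphs of up to 200 vertices,
recovers the planted structure of the default 150-gene × 500-sample
simulation exactly, and runs imputation checks with hundreds of training
samples and tens of response genes; full-pipeline runs use a 4-block,
150-sample simulation. These sizes were chosen so the whole suite
completes in well under a minute while still covering every code path at
scales where the asymptotic behavior (greedy nesting, exhaustion,
plateau) is visible.

## Limitations

- Pairwise correlation only; no partial correlations or higher-order
  interactions.
- The greedy panel is not guaranteed optimal; exhaustive or
  integer-programming search is out of scope by design.
- Gene matching across datasets is exact, case-sensitive symbol
  equality; symbol harmonization belongs upstream.
- Platform normalization, probe summarization, batch correction and
  duplicate-sample screening are out of scope: the input is assumed
  filtered-ready and normalized to a log-like scale.
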