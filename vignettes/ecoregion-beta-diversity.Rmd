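---
title: "Partitioning alpha- and beta-diversity correlates across ecoregions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning alpha- and beta-diversity correlates across ecoregions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoregionbeta)
```

## The question the package answers

Mountain hotspots hold floras whose composition turns over sharply from
one ecoregion to the next. Four candidate explanations compete for that
turnover: climate (assemblages track temperature and precipitation),
elevation (assemblages track the altitudinal profile), substrate
(narrow endemics in particular are often confined to specific
lithologies such as serpentines or gypsum outcrops), and plain
geography (dispersal limitation produces distance decay of similarity
regardless of the environment). These explanations are mutually
correlated — high places are cold, nearby places share rocks — so
deciding among them needs more than four separate correlations.

`ecoregionbeta` implements a complete workflow for that decision. The
analysis unit is the *ecoregion*: a territory with homogeneous
climatic, topographic and geological features, represented by its
1-km² cell grid. The flora is a presence/absence matrix of taxa by
ecoregions, split into an *endemic element* (taxa confined to the
hotspot) and a *nonendemic element* (all other natives), because the
drivers of the two guilds are expected to differ.

The workflow has four stages:

1. **Dissimilarity construction.** Floristic distances use the Sørensen
   index on presence/absence, `1 - 2a / (2a + b + c)`. Substrate
   distances use Bray–Curtis on relative surface fractions of lithology
   categories. Climatic and altitudinal distances are Euclidean on
   standardized variables. Geographic distance between two irregular
   ecoregions is the mean planar distance over all cross pairs of their
   cells, which summarises the full distribution of cell-pair distances
   instead of a single centroid.
2. **Variable selection (BIO-ENV).** The climatic and altitudinal
   variable subsets entering the regression are not chosen by hand:
   an exhaustive search keeps the subset whose Euclidean distance
   matrix maximizes the Spearman rank correlation with the community
   dissimilarities.
3. **Pattern description.** UPGMA clustering with multiscale-bootstrap
   AU support and detrended correspondence analysis describe the
   floristic structure; PCA of the environmental table plus simple
   linear models describe alpha-diversity (richness) correlates.
4. **Variance partitioning.** Multiple regression on distance matrices
   (MRM) with permutation inference, and the decomposition of its R²
   into per-predictor unique contributions, a joint (covariation) term
   and an unexplained remainder.

## The environmental table

Per-ecoregion climate comes from per-cell monthly series. Monthly
values are first averaged over the ecoregion's cells (unweighted —
every cell is 1 km²), then summarised into 22 variables: annual
mean/SD/range of monthly mean temperature (codes 1–3), annual
total/SD/range of monthly precipitation (4–6), mean/SD of monthly
maxima (7–8) and minima (9–10), driest- and wettest-month
precipitation (11–12), warmest-month maximum and coldest-month minimum
(13–14), mean precipitation of the driest and wettest annual quarter
(15–16), mean temperature of the coldest and warmest quarter (17–18),
and mean/max/min/SD of cell elevation (E1–E4).

Conventions fixed here, because the verbal definitions leave them
open:

* An *annual quarter* is any 3 consecutive calendar months, with
  December→January wrap-around; ties go to the earliest starting
  month. Codes 15–16 report the mean of the three monthly values
  (total/3).
* All SDs use the n−1 denominator. A single-cell ecoregion has E4 = 0
  by convention, not an error.
* Codes 13–14 take the extreme of the *ecoregion-mean* monthly series
  (mean over cells first, extreme second). Averaging per-cell extremes
  would give systematically wider values; one order had to be fixed,
  and mean-then-extreme is consistent with how all other codes are
  built from the ecoregion series.

## BIO-ENV

For candidate codes and a community `distance_matrix`, every non-empty
subset up to `max_k` is scored by the rank correlation between the
unfolded halves of the two matrices. Standardization (zero mean, unit
n−1 SD over exactly the analysed ecoregions) is per-variable, so
subsetting ecoregions re-standardizes; analyses restricted to part of
the hotspot therefore use their own scale, as they should. Spearman
with average ranks is the default nonparametric score, Kendall an
option. Tie-breaks are deterministic (smaller subsets first, then
lexicographic order), and the exhaustive search is guarded at 20
candidates. The orchestrated pipeline caps the climatic search at
subsets of 5 variables: with 12–48 ecoregions the correlation surface
is effectively flat beyond that size, and the cap keeps the end-to-end
run in seconds while `bioenv_search()` itself defaults to the full
candidate count.

## Clustering support: the multiscale bootstrap

Ordinary bootstrap proportions (BP) for dendrogram edges are biased
estimates of support. The multiscale remedy resamples the taxa at
several sampling ratios r (default 0.5–1.4 in steps of 0.1), recomputes
the Sørensen–UPGMA tree each time, and records per edge the fraction
BP_r of replicate trees containing the same leaf set. Under the
signed-distance/curvature model

```
qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)
```

the two parameters are fitted by weighted least squares on the probit
scale with binomial weights B / (BP_r (1 − BP_r)); the approximately
unbiased support is `AU = 1 - pnorm(v - c)` and the bias-corrected
`BP = 1 - pnorm(v + c)`. Numerical conventions: counts are clipped to
[0.5, B − 0.5] before the probit transform; an edge clipped at every
scale reports AU = BP (its clipped proportion at the scale nearest 1)
with a flag; a single-scale run cannot identify (v, c) and falls back
to BP with a warning. Replicates that empty an ecoregion drop it from
that replicate's tree, and reference edges containing the dropped leaf
count as unsupported there.

The resampling unit is the taxon (matrix row) — the features
describing each ecoregion — which is the standard choice when
bootstrapping community classifications. B defaults to 100 replicates
per scale in examples and tests; the classic N = 10,000 setting is one
configuration entry away and changes only Monte-Carlo precision, not
the model.

UPGMA itself is implemented in-package rather than delegated, because
the bootstrap needs per-edge leaf sets and a deterministic tie-break
(among minimal pairs, the pair whose alphabetically smallest leaves
sort first). Its cophenetic matrix is checked against base R's
average-linkage `hclust` in the tests.

## Ordination

Correspondence analysis uses the usual chi-square-standardized SVD;
site scores are standard coordinates of the ecoregions. DCA keeps CA
axis 1 and re-derives axis 2 by reciprocal averaging with
detrending-by-segments inside the loop: the axis-1 range is cut into
`segments` (default 26) equal-width bins and trial axis-2 scores are
centred to zero mean within each bin, removing the arch artefact.
Iteration stops when scores change by less than 1e-10 (cap 999
iterations). Hill's nonlinear rescaling of axis units is deliberately
omitted: the detrended configuration is used for a qualitative site
scatter, and omitting rescaling keeps the scores exactly reproducible
and testable (detrending off reduces the result to plain CA,
verified). PCA of the environmental table works on the correlation
matrix — the variables mix mm, °C and m — with the sign convention
that each axis's largest-magnitude loading is positive.

## MRM and the variance partition

The response and predictor distance matrices are unfolded to their
strictly upper triangles and fitted by OLS. The n(n−1)/2 pairwise
observations are not independent, so parametric p-values would be
anticonservative and are never reported; inference is purely
permutational. The null permutes the *response matrix's* rows and
columns by one random relabelling per permutation (predictors and
residuals stay fixed), re-unfolds and refits; p-values use the +1/+1
rule, so the smallest attainable p is 1/(nperm + 1). Coefficient tests
are two-sided on |b|, the R² test one-sided. Defaults are nperm = 999
in tests and examples, with the 1000-permutation setting available via
configuration. A condition-number guard (κ > 1e8 on the scaled design)
rejects collinear predictor sets rather than returning unstable
coefficients.

The "semi-partial" decomposition is the leave-one-out convention:
`unique_i = R²(full) − R²(without i)`, `joint = R²(full) − Σ unique_i`,
`unexplained = 1 − R²(full)`. The three parts sum to one by
construction, which every run asserts. With correlated predictors the
joint term absorbs the shared variance — exactly duplicated predictors
have zero unique contributions. Shares of the single contributions
(`unique_i / Σ unique`) are also reported, since turnover analyses
often quote "x% of the variance explained by single factors";
both scalings are returned rather than asserting which a given figure
uses.

The taxon-resampling robustness check draws k taxa with replacement
(the size of the smaller floristic element, e.g. 667 from 3384),
rebuilds the Sørensen matrix, and regresses it on the pool matrix over
the surviving ecoregions; adjusted R² uses the number of unfolded
pairs as its sample size. Ecoregions emptied by a draw are dropped for
that iteration (Sørensen is undefined for empty assemblages, and
imputation would fabricate signal); iterations with fewer than three
surviving ecoregions are discarded and counted.

## The synthetic study system

No machine-readable flora ships with the package, so a seeded
generator provides landscapes and floras with *known* drivers:

* a rectangular grid of 1-km² cells carved into contiguous rectangular
  ecoregions (jittered block boundaries, so areas differ); default
  40 × 30 km and 12 ecoregions, which keeps the full pipeline under a
  minute while leaving ≥ 66 ecoregion pairs for the matrix
  regressions;
* elevation as a smooth central ridge rising eastward plus noise;
  monthly temperature = seasonal cycle − lapse × elevation (default
  6 °C/km) plus elevation-independent structure (a northing gradient
  in both level and seasonal amplitude, cell-level noise) so climate
  is correlated with, but not a deterministic function of, elevation;
  precipitation winter-peaked and increasing westward;
* a lithology mosaic of many small nearest-seed patches with randomly
  assigned categories — patchy like a geological map and deliberately
  not a simple proxy for geographic position;
* nonendemic species (default 280): occupancy probability =
  baseline × Gaussian climate-niche match (breadth default 2 °C) ×
  exp(−decay × distance from a random origin ecoregion), decay
  default 0.03/km;
* endemic species (default 120): confined to an elevation window
  (half-width default 250 m) and, with fidelity probability (default
  0.9), to ecoregions containing a required substrate category.

Preset single-driver scenarios sharpen these for parameter-recovery
tests: `scenario_lithology_endemic()` (fidelity 1, window 200 m —
endemic turnover must load on lithology/elevation) and
`scenario_distance_decay()` (climate breadth 50 °C, decay 0.06/km —
nonendemic turnover must load on geography). Every stochastic draw
flows from the scenario seed; no global RNG state leaks.

What the generator does *not* emulate: realistic species-abundance
distributions (all occupancy is Bernoulli), irregular ecoregion
shapes, spatially autocorrelated microclimate beyond the gradients
above, or real climate fields. Passing recovery tests therefore show
that the pipeline attributes turnover to the factor that generated it
under honest spatial correlation among predictors — not that any real
flora behaves like the simulation.

## Degenerate inputs and numerical conventions, collected

* Distance matrices must be symmetric within 1e-12 with zero
  diagonals; readers re-validate files.
* Taxa with no presences are dropped with a warning outside raw input.
* The high-elevation filter quantifies "no significant fraction above
  1500 m" as < 5% of cells and "most of the surface below 500 m" as
  > 50%, both exposed as parameters; an ecoregion with no cells is an
  error.
* Merging ecoregions ORs incidence columns, sums areas, and relabels
  cells; merging a single id is a rename.
* Geographic distances offer a seeded subsample mode whose error
  shrinks with subsample size; full-size subsampling reproduces the
  exact mode bit for bit.
* `variance_partition` tolerates aliased (exactly collinear)
  predictors — the unique contributions go to zero and the shared
  variance sits in joint — while `mrm` rejects them, because
  permutation tests of unstable coefficients are meaningless.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the default 12-ecoregion,
400-species scenario; MRM tests use 199–999 permutations; the
permutation-size calibration uses 200 null datasets of 8 units at
nperm = 199; the multiscale bootstrap uses 10 scales × 100 replicates.
These sizes were chosen so that each check isolates one property with
comfortable Monte-Carlo margins.
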