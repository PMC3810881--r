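# ecoregionbeta

Environmental and geographical correlates of vascular-plant alpha and
beta diversity across ecoregions.

Floras of mountain biodiversity hotspots turn over sharply between
ecoregions, and four correlated explanations compete for that
turnover: climate, elevation, substrate (lithology), and plain
geographic distance (dispersal limitation). This package implements a
complete, tested workflow to disentangle them for a presence/absence
flora split into endemic and nonendemic elements:

* **Dissimilarity matrices** — floristic (Sørensen,
  `1 − 2a/(2a+b+c)`), lithological (Bray–Curtis on substrate surface
  fractions), climatic/altitudinal (Euclidean on standardized variable
  subsets), geographic (mean planar distance over all cross pairs of
  1-km² cells of two ecoregions).
* **BIO-ENV** — exhaustive search for the environmental-variable
  subset whose distance matrix maximizes the Spearman rank correlation
  with the community dissimilarities.
* **Clustering and ordination** — UPGMA dendrograms with
  multiscale-bootstrap approximately-unbiased (AU) edge support
  (`qnorm(1 − BP_r) = v√r + c/√r`, `AU = 1 − Φ(v − c)`); detrended
  correspondence analysis (detrending by segments); PCA of the
  22-variable environmental table; alpha-diversity (richness) linear
  models.
* **MRM and variance partitioning** — multiple regression on distance
  matrices with matrix-permutation inference (no parametric p-values),
  and the decomposition of R² into per-predictor unique contributions,
  a joint (covariation) term, and the unexplained remainder, which sum
  to 1 by construction.
* **Synthetic study systems** — a seeded landscape-and-flora generator
  with known turnover drivers (elevation windows and substrate
  fidelity for endemics, climate niches and distance decay for
  nonendemics), so every stage is testable end to end without external
  data.

## Worked example

Generate a 12-ecoregion synthetic hotspot and ask what drives endemic
beta diversity:

```r
library(ecoregionbeta)

cfg   <- scenario_config(seed = 42)
land  <- generate_landscape(cfg)
flora <- generate_flora(cfg, land)
flora$occ
#> occurrence_matrix: 400 taxa x 12 ecoregions ( 120 endemic, 280 nonendemic )

env <- build_env_table(land$cells)       # 22 variables, codes 1-18 + E1-E4
res <- run_beta_analysis(flora$occ, env, land$grid,
                         lith = build_lithology_table(land$surfaces),
                         nperm = 999, seed = 1)

res$endemic$bioenv_altitudinal
#> BIO-ENV (spearman rank correlation)
#>  size      subset correlation
#>     1          E1   0.8938175
#>     2       E1,E3   0.8774586
#>     3    E1,E2,E3   0.8605735
#>     4 E1,E2,E3,E4   0.7277727
#> best subset: {E1}  correlation = 0.8938

res$endemic$mrm
#> MRM over 12 units, 999 permutations
#>     predictor   coefficient p_value
#>   (Intercept)  0.3354206671      NA
#>      climatic  0.3028960332   0.612
#>   altitudinal -0.2209098990   0.795
#>    geographic -0.0002240365   0.960
#>  lithological  0.3713452436   0.012
#> R2 = 0.6803  (p = 0.001 )

res$endemic$partition
#> variance partition (R2 full = 0.6803 )
#>           climatic altitudinal   geographic lithological
#> unique 0.007192159 0.001927095 5.214025e-05   0.09651686
#> joint = 0.5746  unexplained = 0.3197
```

Reading the output: mean elevation (E1) alone best rank-correlates
with endemic turnover among the altitudinal variables; the
four-predictor MRM explains 68% of endemic beta diversity (permutation
p = 0.001); and the partition shows lithology holding by far the
largest *unique* share, with most of the remaining explained variance
sitting in the joint term — the predictors are spatially correlated,
and the decomposition says so instead of crediting any single one. In
this scenario endemics really were generated with substrate fidelity,
so the attribution is correct.

`run_pipeline(config)` wraps the full graph (pool summary, UPGMA + AU
clustering, DCA, PCA, alpha models, BIO-ENV, MRM + partition, optional
high-elevation subanalysis and taxon-resampling robustness check) from
a single named list or YAML file, and writes every matrix plus a
deterministic `results.json` when given an output directory.

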