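Package: ecoregionbeta
Title: Alpha- and Beta-Diversity Correlates Across Ecoregions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the environmental and geographical
    correlates of vascular-plant alpha and beta diversity across
    ecoregions. Builds floristic (Sorensen), lithological (Bray-Curtis),
    climatic/altitudinal (standardized Euclidean) and geographic
    (mean cell-pair) dissimilarity matrices from incidence tables and
    per-cell climate grids; selects environmental variable subsets by
    exhaustive BIO-ENV rank-correlation search; clusters floras by UPGMA
    with multiscale-bootstrap approximately-unbiased (AU) edge support;
    ordinates assemblages by correspondence analysis and detrending by
    segments (DCA); and partitions beta-diversity variance among
    predictor distance matrices by multiple regression on distance
    matrices (MRM) with permutation inference. A seeded synthetic
    landscape-and-flora generator with known diversity drivers makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
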