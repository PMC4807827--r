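Package: seasondiv
Title: Seasonal Change in Functional and Phylogenetic Diversity of
    Stream Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse seasonal (wet vs dry) change in species
    richness, dendrogram-based functional diversity (Gower distance +
    UPGMA, Petchey-Gaston style) and Faith-style phylogenetic diversity
    of site-by-species assemblage data.  Implements a turnover-preserving
    null-assemblage generator that conditions on observed per-season
    richness, observed species turnover and the site-level species pool;
    paired observed-versus-null tests of relative seasonal change;
    polynomial (SR + SR^2) regressions with AIC stepwise simplification
    to detect functional redundancy; Moran's I spatial autocorrelation
    checks; and a synthetic-data generator (Yule trees, traits with
    tunable phylogenetic signal, scenario-based community assembly) for
    end-to-end calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    cluster,
    picante,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
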