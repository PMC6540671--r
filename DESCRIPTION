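Package: traitshift
Title: Decomposing Interannual Functional-Diversity Change into Intraspecific
    Variation and Species Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how interannual climate variation changes the
    functional composition of grassland plant communities. Computes
    growing-period aridity indices from Holdridge potential evapotranspiration,
    two-layer (tussock and understory) relative aboveground biomass,
    community-weighted trait means (CWM), functional dispersion (FDis, per
    trait and over a multi-trait Gower/PCoA space) and Rao's quadratic entropy
    under year-specific ("specific") or across-year-average ("fixed") trait
    values, and decomposes the between-year sum of squares of each index into
    species turnover, intraspecific trait variability and their covariation.
    Includes Bray-Curtis PERMANOVA for compositional change and a
    synthetic-community generator with explicit control of intraspecific
    shift, abundance turnover and their covariation, so the full pipeline runs
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    cluster,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
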