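Package: gnotolink
Title: Linking Gut Microbiota to Host Body Weight and Gene Expression in
    Gnotobiotic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-layer linkage analysis for gnotobiotic feeding studies
    that contrast germ-free (GF) mice with fecal microbiota transplant (FMT)
    mice across diets. Provides per-diet GF-vs-FMT body-weight contrasts
    (ANCOVA line comparison, weight gain per day, absolute and slope-based
    weight differences), a differential-expression screen with cross-diet and
    cross-tissue intersections, a cross-diet Pearson correlation screen
    linking microbiota-attributable gene-expression shifts to
    microbiota-attributable weight gain, taxon-gene and taxon-weight
    correlation screens at any taxonomic rank, microbiome diversity analytics
    (observed taxa, Chao1, Shannon, Jensen-Shannon PCoA, UPGMA, unweighted
    UniFrac), and a synthetic-cohort generator with recorded ground truth so
    the whole pipeline can be validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    vegan,
    picante,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
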