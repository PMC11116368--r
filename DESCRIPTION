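Package: commgem
Title: Comparative Analysis of Microbial Community Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing genome-scale metabolic models (GEMs) of
    microbial community members reconstructed with different automated tools.
    Provides namespace harmonization to a common reference, consensus merging
    of per-genome draft models with duplicate-reaction resolution,
    abundance-ordered iterative community gap-filling with growth-medium
    augmentation, flux balance and flux variability analysis with
    blocked-reaction detection, hypergeometric enrichment of enzyme
    subclasses, exchanged-metabolite analysis, and a synthetic fixture
    generator so the whole pipeline is testable without external data.
    Models are read and written as SBML Level 3 with the fbc extension or as
    plain TSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
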