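Package: agrpipe
Title: CTCF Occupancy, Motif Orientation, and Loop Geometry in
    Antigen-Receptor Loci
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@agrpipe.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for characterizing CTCF and cohesin binding
    within antigen-receptor (Igh, Igk, Igl, TCRa/d, TCRb, TCRg) loci:
    multi-mapping-aware read placement over duplicated locus segments,
    confident peak calling against a local Poisson background,
    cross-cell-type peak merging and specificity classification,
    hypergeometric locus enrichment, position-weight-matrix scanning with
    consensus-sign orientation voting, and convergent/tandem loop-geometry
    prediction under the loop-extrusion rule. Ships a synthetic locus
    generator with planted, oriented CTCF sites, per-cell-type occupancy
    and a triplicated segment, so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    stats
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
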