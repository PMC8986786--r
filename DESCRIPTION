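Package: loopswitch
Title: Downstream 3D-Genome Analysis of Cohesin STAG-Paralog Switching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the downstream consequences of STAG2 loss
    on 3D genome organization. Classifies STAG2-to-STAG1 binding switches at
    lost cohesin sites, quantifies TAD boundary dynamics (stable/variable
    boundaries, expanded/shrinked/merged domains) and contact-probability
    decay, computes insulation-score tracks, calls differential H3K27ac
    HiChIP loops with an over-dispersed Poisson model, performs ROSE-style
    super-enhancer calling, and integrates expression, promoter binding and
    loop evidence to nominate direct target genes. Ships a synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
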