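Package: fgeskat
Title: Family-Based Gene-Environment Interaction Testing with Sequence Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Region-based association testing for quantitative traits in
    pedigree samples, jointly modelling a genetic kernel and a
    gene-by-environment interaction kernel (FGE-SKAT). Implements pedigree
    kinship and relationship matrices, REML fitting of the polygenic null
    mixed model, weighted linear kernels mixed over a rho grid, score
    statistics with chi-square-mixture p-values by saddlepoint approximation
    and characteristic-function inversion, genome-scan machinery over sliding
    variant windows with Blom-normalised traits, and a gene-drop simulation
    harness for permutation type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, IRanges, vcfR, jsonlite
Suggests: testthat (>= 3.0.0), ggplot2, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
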