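Package: msclong
Title: Modelling the Remaining Replicative Lifespan of Cultured Bone-Marrow Stromal Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for tracking the replicative ageing of cultured bone-marrow
    multipotential stromal cells (MSCs) and predicting their remaining lifespan
    in population doublings before senescence (PD-BS). Implements population
    doubling accounting from culture logs, qPCR relative expression by the
    2^(-dCt)/2^(-ddCt) method, telomere T/S ratio conversion to base pairs with
    paired differentiation-shift testing, a pluggable six-CpG methylation clock,
    rank-correlation marker screening, and a calibrated composite score
    (SPARC relative expression times reciprocal PRAMEF2 methylation) with
    confidence-band prediction of remaining PD-BS and osteogenic capacity.
    Includes a synthetic donor-cohort generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
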