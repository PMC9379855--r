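Package: andropath
Title: Linking Tissue-Culture-Induced (Epi)genetic Variation, Glutathione
    and Green Plant Regeneration Efficiency by Path Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the three analysis stages used to relate in vitro
    anther-culture conditions to green plant regeneration efficiency (GPRE)
    in cereals: quantification of methylation-sensitive AFLP (metAFLP)
    donor/regenerant band codes into sequence-variation, demethylation and
    de novo methylation events per cytosine context (CG, CHG, CHH);
    preprocessing of ATR-FTIR absorbance spectra (baseline correction,
    unit-area normalization, 10 cm-1 binning) and extraction of the
    2540-2550 cm-1 thiol (glutathione) band integral; and maximum-likelihood
    fitting of recursive path models on sample covariance matrices with
    standard errors, a standardized solution, the usual covariance-structure
    fit indices (GFI, AGFI, RMR, SRMR, NFI, RFI, IFI, CFI, PNFI, PCFI,
    RMSEA) and direct/indirect/total effect decomposition. Includes
    synthetic-data generators for all three stages and the packaged
    37-regenerant triticale anther-culture observation table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
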