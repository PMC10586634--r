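Package: zinbdap
Title: Differential Protein Abundance with Zero-Inflated Negative Binomial Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Differential-abundance analysis of label-free quantitative
    proteomics data using per-protein negative binomial and zero-inflated
    negative binomial regression with a nested likelihood-ratio-test model
    selection cascade and Storey q-value FDR control. Includes quality-control
    filtering of MaxQuant-style protein-group tables, TMM library-size
    normalization, exclusive (presence/absence) protein detection, a
    fixed-effects linear model workflow for animal performance traits with
    iterative studentized-residual outlier removal, marker-based digestibility
    and feed-chemistry arithmetic, and a synthetic-data generator that
    emulates a 24-animal two-treatment pregnant-cow feeding trial for
    end-to-end calibration of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    edgeR,
    emmeans,
    stats,
    utils
Suggests:
    glmmTMB,
    jsonlite,
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
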