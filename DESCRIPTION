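Package: aquasig
Title: Aquaporin Classification, Substrate-Specificity Signatures and
    RT-qPCR Relative Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates plant aquaporin (major intrinsic protein) amino-acid
    sequences: transmembrane topology by Kyte-Doolittle hydropathy, NPA motif
    scanning, alignment-anchored extraction of the Ar/R selectivity filter,
    Froger P1-P5 positions, substrate-specific signature sequences (SSSS) and
    specificity-determining positions (SDP), subfamily classification (PIP1,
    PIP2, TIP) by conserved residues and by neighbor-joining clade placement,
    and consensus substrate-specificity prediction. Also implements the
    companion RT-qPCR relative-expression workflow: amplification-efficiency
    estimation from raw fluorescence curves, Cq calling, no-RT contamination
    filtering, geNorm reference-gene stability, calibrated normalized relative
    quantities (CNRQ), and robust group comparison with the Brown-Forsythe
    test and Scheffe post hoc contrasts. Ships a synthetic-data generator for
    signature-bearing sequences, labelled phylogeny panels and simulated qPCR
    plates with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
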