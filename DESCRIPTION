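Package: fmcaller
Title: Probe-Based Fluorescence Melting Curve Genotyping of FUT2 and FUT3
    with Lewis Blood Group Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses probe-based fluorescence melting curve
    analysis (FMCA) assays for the secretor (FUT2) and Lewis (FUT3) blood
    group genes. A single HEX-labelled probe spanning the FUT2 c.385A>T site
    hybridises to FUT2, to its pseudogene SEC1P, and to the SEC1P-FUT2 fusion
    allele with 1, 0 and 1 mismatches respectively, so allele identity is read
    from melting temperatures and fusion zygosity from relative peak heights.
    The package encodes the assay geometry, generates synthetic three-channel
    (HEX/FAM/CY5) melting curves for arbitrary genotype configurations, detects
    -dF/dT melting peaks, calls FUT2 six-group genotypes and biallelic FUT3
    c.59T>G and c.314C>T genotypes, and maps called diplotypes to secretor
    status and Lewis red-cell phenotype, with cohort-level summaries, TSV and
    VCF output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
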