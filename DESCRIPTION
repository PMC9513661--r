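Package: heteroplasmR
Title: Mitochondrial RNA Heteroplasmy Analysis for Oocyte and Cumulus
    Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies mitochondrial RNA heteroplasmy from aligned
    RNA-seq reads on the mouse mitochondrial genome. Builds
    quality-filtered per-position base counts from SAM records, calls
    single-nucleotide variants against the consensus with depth and
    allele-frequency thresholds, annotates variants by mitochondrial
    feature and synonymy under the vertebrate mitochondrial genetic
    code, aggregates variants across a paired oocyte-cumulus study
    design (per-mouse recurrence, maternal-origin classification,
    paired heteroplasmy deltas), and provides the accompanying
    statistical layer (one-way ANOVA with Holm-Sidak correction, paired
    t-tests, linear fits, sister-sample coefficients of variation,
    D-loop cumulative-frequency curves). Includes a synthetic-study
    generator that plants known heteroplasmies and modification-induced
    artifacts so the full pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
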