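Package: csb2scan
Title: Survey of G-Tract Length Heterogeneity at Mitochondrial CSB 2
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for surveying length heterogeneity of the conserved
    sequence block 2 (CSB 2) G-tract in human mitochondrial control-region
    sequences. Provides a nomenclature model for discontinuous (GmXGn) and
    continuous (Gk) guanine tracts with a signed adenine-position index, an
    exact-match search-string library and scanner for classifying the CSB 2
    locus in multi-FASTA sequence sets, population-level frequency-matrix
    statistics (anti-diagonal totals, sample skewness, quadrant asymmetry,
    adenine-position spectrum, frequency-versus-termination cumulative
    curves), a gel-lane densitometry toolkit (ladder calibration,
    termination-product quantification, peak calling with reference
    coordinate mapping), and a fully seeded synthetic-data generator that
    emulates mixed GenBank-style sequence sets and gel lane profiles with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
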