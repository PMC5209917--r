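Package: umicall
Title: Barcode-Aware Bayesian Calling of Low-Fraction Sequence Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects somatic single-nucleotide and short indel variants at
    allele fractions down to about one percent from targeted deep sequencing
    in which every original DNA molecule carries a unique molecular barcode
    (UMI). Reads sharing a barcode are modelled jointly: a Bayesian
    per-barcode model combines Phred base-calling error probabilities with a
    heuristic PCR-error term to yield a posterior for each allele in each
    barcode family, and per-barcode posteriors are summed on a -log10 scale
    into a locus-level prediction index that is compared against a cutoff.
    Includes read-level and candidate-level artifact filters (strong-barcode,
    strand bias, homopolymer / low-complexity / tandem-repeat context),
    empirical cutoff recommendation as a function of barcode depth and
    tolerated false-positive rate, binomial locus-specific detection-limit
    estimation with bedGraph track output, and a seedable simulator of the
    barcoded PCR + sequencing error process for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    optparse,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite
Config/testthat/edition: 3
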