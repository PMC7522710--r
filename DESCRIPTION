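Package: evepirna
Title: Small RNA Signatures of Endogenous Viral Elements and piRNA
    Ping-Pong Amplification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for strand-resolved small-RNA profiling of
    endogenous viral elements (EVEs) and their cognate exogenous viruses in
    insect genomes. Detects viral-derived fragments in host contigs by
    seed-and-extend local alignment, aligns small RNAs to small references
    with an exact 0/1-mismatch stratum contract, computes size spectra,
    per-nucleotide coverage, positional nucleotide biases (1U/10A, sequence
    logo matrices) and the ping-pong 5-prime overlap spectrum with z-scores,
    disambiguates EVE-derived from virus-derived reads by zero-mismatch
    mapping to both references, and simulates ground-truthed viral small-RNA
    read populations (21-nt siRNAs, 1U-biased primary piRNAs, ping-pong
    secondary piRNAs) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
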