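Package: dipasym
Title: Dipeptide and Antidipeptide Asymmetry in Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts adjacent and gapped residue pairs (dipeptides) in sets of
    protein sequences and quantifies the asymmetry between each dipeptide AB
    and its mirror-image antidipeptide BA with the C190 statistic and
    first-order propensities. Includes a non-overlapping subsampling
    (fragmented prediction performance plot) procedure to assess sampling
    sufficiency, a random gene-mutagenesis experiment (base deletions and
    substitutions followed by frame-1 translation) to test genetic origins of
    the asymmetry, and a first-order Markov sequence generator with exact
    analytic pair statistics for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
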