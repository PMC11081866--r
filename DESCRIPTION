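Package: bequant
Title: Quantification of Adenine Base-Editing Outcomes from Amplicon Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying adenine base-editing
    outcomes at targeted loci from amplicon deep-sequencing reads. Reads are
    merged, globally aligned to a reference amplicon with affine gap scoring,
    and collapsed into an allele table from which per-adenine A-to-G editing
    rates, desired-edit-only efficiency, windowed indel rates, and
    synonymous/nonsynonymous bystander classes are computed. Includes a
    ground-truth read simulator for validation, in-silico off-target site
    enumeration by bounded-mismatch search, and downstream phenotype
    statistics (Pearson correlations with confidence intervals, Welch tests,
    delta-delta-Ct fold changes, percent changes, and a composite ataxia
    score).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
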