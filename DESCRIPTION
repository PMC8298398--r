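Package: nrykit
Title: Ancient-DNA Y-Chromosome Capture Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis toolkit for targeted capture sequencing of the
    non-recombining Y chromosome (NRY) in ancient-DNA studies. Provides
    readers for BED target regions, mpileup-style base pileups and
    haplogroup-SNP catalogues; capture-assay coverage comparison with
    per-five-million-read normalization and enrichment tests; pileup-based
    Y-haplogroup assignment from derived/ancestral SNP tallies with
    deamination-damage annotation; heterozygosity-based contamination
    screening; consensus-haplotype and segregating-site alignment
    construction; ingroup/outgroup diagnostic-SNP discovery; and calibrated
    pairwise TMRCA estimation with exact Poisson confidence intervals. A
    lineage simulator with Poisson mutation placement, post-mortem damage
    and male contamination generates data with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
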