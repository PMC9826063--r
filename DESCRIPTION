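Package: anchorphase
Title: Anchored Phasing of De Novo Mutations from Targeted Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the parent-of-origin and zygosity (prezygotic versus
    postzygotic) of Sanger-validated de novo mutations (DNMs) from deep
    amplicon long-read sequencing combined with trio short-read exome
    evidence. Reads spanning the DNM are split by the validated DNM base
    ("anchoring"), candidate informative SNPs are called from pileups,
    error-polished against exome trio genotypes and, where available,
    parental long reads, and a single informative SNP is selected to build a
    two-locus allele table from which raw and polished mutant allele
    frequencies, a possible third allelic form, background error metrics and
    the parent-of-origin are derived. A deterministic trio/amplicon read
    simulator with substitution and homopolymer-biased indel error generates
    desk-scale datasets with ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    yaml,
    optparse
Config/testthat/edition: 3
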