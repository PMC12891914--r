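Package: mhctsp
Title: Multi-Species MHC Amplicon Diversity, Codon-Usage Co-Ancestry
    Testing, and Supertyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-species major histocompatibility complex (MHC)
    amplicon studies: post-clustering allele quality control (length,
    prevalence/replication, stop-codon screening, intron and open reading
    frame trimming, nucleotide-to-protein collapse), allelic and nucleotide
    diversity summaries (Hurlbert rarefaction, Nei nucleotide diversity with
    sampling variance, per-individual allele counts and minimum gene-copy
    bounds, shared-allele Venn partitions), a Monte-Carlo codon-usage test
    that discriminates co-ancestry from convergent evolution for alleles
    shared among species (resampled codon-identity distributions, one-tailed
    Z-tests with false discovery rate correction, a co-ancestry score, and
    its correlation with phylogenetic distance), and functional supertyping
    of alleles by discriminant analysis of principal components on
    physiochemical descriptors at positively selected sites. A seeded
    synthetic-data generator emulates multi-species allele sets with known
    ground truth so the whole chain is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
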