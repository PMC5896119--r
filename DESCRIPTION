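Package: exonarch
Title: Exon-Intron Architecture Evolution of Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of exon-intron architectures across gene
    families, built around the heterotrimeric G protein alpha (GNA-) family
    as the motivating system. Derives exon-border offsets and split-codon
    phases from coding annotations, projects borders onto protein
    alignments to quantify shared architecture between paralogs, classifies
    retrotransposition-origin genes, polarizes intron gain and loss on a
    species tree (Sankoff and Dollo parsimony), detects mutually exclusive
    duplicated exons and non-canonical splice sites, enumerates and
    compares splice isoforms, classifies candidate retrogene loci from
    similarity-search hits with ORF-conservation and expression evidence,
    reconciles gene trees with species trees by LCA mapping (weak-edge
    collapse and minimum-cost polytomy resolution), and performs positional
    motif-enrichment tests (binomial and Fisher). A gene-family evolution
    simulator with a ground-truth event ledger makes every stage testable
    from synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
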