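Package: homolocus
Title: Comparative Views of Homologous Loci from CAGE Promoters and
    Chain-Alignment Anchors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing a pair of homologous genomic loci
    (orthologs, within-genome paralogs, or whole-genome-duplication
    co-orthologs) at three scales: proximal promoters, exon-intron
    structure, and genomic neighborhood. CAGE tags are clustered into
    strand-specific tag clusters with representative positions,
    tags-per-million expression and sharp/broad shape classes; UCSC chain
    alignments are decomposed into gap-free blocks used as anchors between
    loci, with 1-to-1 versus 1-to-2 multiplicity classification, top-2
    selection among many aligned loci, self-chain handling for paralogs,
    and bridged composition of two alignments through a shared outgroup
    assembly. A homology-table module derives candidate
    whole-genome-duplication paralog pairs through an ortholog bridge. A
    synthetic fixture generator produces gene models, chains, CAGE and
    homology tables with known ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xml2,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
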