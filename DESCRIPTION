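Package: InDelMarkers
Title: Agarose-Resolvable InDel Marker Development from Re-Sequenced Breeding Parents
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for developing co-dominant, agarose-resolvable
    insertion/deletion (InDel) PCR markers from whole-genome variant calls of
    two breeding parents against a shared reference genome. Provides
    left-alignment normalisation of InDel calls, derivation of cross-parent
    polymorphic InDels with size-class and density accounting, flank
    extraction and constrained primer design with a nearest-neighbor melting
    temperature model, in-silico amplicon size prediction per parent,
    hybrid-seed purity scoring from co-dominant band calls, marker panel
    statistics (allele frequencies, gene diversity, polymorphism information
    content, observed heterozygosity), Nei's minimum genetic distance and
    UPGMA dendrograms, plus a synthetic-data module that simulates reference
    genomes, parental InDel call sets, genotype panels and F1 seed lots with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, SNP, VariantDetection, Sequencing, Phylogenetics
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'InDelMarkers-package.R'
    'cli.R'
    'formats-io.R'
    'genotyping-stats.R'
    'indel-discovery.R'
    'marker-design.R'
    'purity.R'
    'simulate.R'
    'tm.R'
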