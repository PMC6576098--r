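Package: allosnp
Title: SNP Array Design, Cross-Species Genotyping QC and Subgenome
    Assignment for Allopolyploid Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing genome-wide SNP genotyping arrays from
    resequencing variant calls and for analysing the resulting genotype
    data in an allopolyploid crop and its diploid wild relatives.
    Implements subgenome-aware SNP selection filters (quality, flanking,
    dihaploid-based homeologous/allelic classification, allele recurrence,
    physical spacing), genotyping quality-control accounting (call rates,
    scorable/polymorphic/homeologous classification, replicate
    concordance), linkage-disequilibrium decay curves, neighbour-joining
    trees with block-bootstrap support, a haploid-downscaling
    identity-by-state procedure that assigns each subgenome of an
    allotetraploid to its closest present-day progenitor populations, and
    two-point linkage statistics with segregation distortion tests and
    Kosambi map distances. A seeded synthetic-data generator produces
    reference FASTA, GFF3 annotation, VCF genotypes and panel tables with
    the population structure these analyses assume, so the whole pipeline
    is testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
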