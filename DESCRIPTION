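Package: ereScout
Title: Discovery and Population Analysis of ERE1 SINE Insertion Polymorphism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for genome-wide analysis of the equine ERE1 SINE
    retrotransposon family: k-mer seeded discovery of consensus-matching loci
    with length, identity, placement and repeat-embedding filters; detection
    of empty (uninserted) alleles from unassembled trace reads by gapped
    alignment, yielding heterozygous-locus calls for the reference
    individual; classification of insertions relative to gene models;
    target-site-duplication and integration-microhomology annotation under
    the target-primed reverse transcription model; and the population and
    evolutionary statistics linking identity class, insertion polymorphism
    and insertion age, including the myostatin-promoter genotype analyses.
    A synthetic-data module generates genomes, traces and genotype panels
    with matching statistical structure and ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
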