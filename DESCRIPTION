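Package: euglintron
Title: Comparative Intron and Twintron Evolution in Euglenid Plastid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of group II/III intron evolution
    in euglenid plastid (chloroplast) genomes: parsing of annotated genome
    records (GenBank/EMBL flat files and GFF3+FASTA), genome partition
    accounting (coding/intergenic/intronic), codon-phase-resolved mapping of
    intron insertion sites onto ortholog protein alignments, clustering of
    cognate sites across species, scanning for the euglenid group III
    5'-NUNNG and 3' pseudo-domain VI stem-bulge consensuses, decomposition
    of twintrons (introns-within-introns) into external and internal
    components with detection of external-only intermediate stages, pairwise
    shared-site matrices, Dollo-parsimony gain/loss mapping on a rooted
    species tree, and a seeded simulator of intron gain/loss/nesting
    histories on a clade for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
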