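Package: contigsift
Title: Taxonomic and Compositional Profiling of Assembled Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-contig profiling of genome and metagenome assemblies:
    GC content, coding density, mean amino-acid identity to reference
    homologs, read coverage, canonical tetranucleotide frequencies and
    relative synonymous codon usage (RSCU); composition-based putative
    binning by hierarchical clustering with the cluster count estimated
    from single-copy marker-gene hit counts; threshold-based taxonomic
    partitioning of assemblies into matched/unmatched FASTA subsets; and
    screening of eukaryotic contigs for candidate horizontal gene
    transfers of prokaryotic origin. Includes a six-frame ORF finder, a
    parser for extended tabular homology-hit files carrying pre-resolved
    lineages, and a synthetic-community generator with planted ground
    truth so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
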