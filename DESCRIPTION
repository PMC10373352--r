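Package: VNTRmotifs
Title: Efficient Motif Sets for Tandem Repeat Annotation from Long-Read Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds per-locus motif catalogs for variable-number tandem
    repeats (VNTRs) from repeat-finder candidate motifs across a panel of
    haplotype-resolved assemblies, compresses each catalog to an efficient
    motif set by exact integer optimisation under a bounded total motif
    replacement cost, and annotates new assemblies or aligned long reads as
    strings of efficient motifs. Includes a locus/read simulator with known
    ground truth and population-level allelic-diversity summaries for
    evaluating annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite
biocViews: Software, GenomicVariation, Sequencing, Annotation, Alignment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
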