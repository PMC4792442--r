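Package: genomesurvey
Title: Low-Coverage Genome Survey Analyses for Diploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing low-coverage whole-genome shotgun surveys of
    diploid organisms, modelled on the bioinformatic workflow used in mussel
    (Mytilus) genome sequencing projects. Implements paired-end read quality
    filtering (ambiguous bases, poly-A structures, low-quality bases, adapter
    contamination, mate overlap), canonical k-mer spectrum construction with
    heterozygous/coverage peak classification and genome-size estimation,
    assembly contiguity statistics (N50, scaffold/contig partitions) and
    repeat-landscape summaries, a two-stage bacterial contamination screen,
    mitochondrial contig tiling with depth profiling and single-nucleotide
    variant calling on circular references, core eukaryotic gene (CEG)
    completeness reporting with gene-repertoire extrapolation, and per-term
    Fisher's exact comparison of Gene Ontology annotation counts with
    false-discovery-rate control. A synthetic-data module generates diploid
    genomes, read sets with planted quality violations, diverged
    mitochondrial genome pairs, CEG match tables and GO count tables with
    ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
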