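Package: dipeval
Title: Evaluation Toolkit for Trio-Phased Diploid Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality evaluation of diploid (haplotype-resolved) genome
    assemblies built from parent-child trios. Implements canonical k-mer
    counting with haplotype-specific marker (hapmer) extraction, k-mer based
    consensus quality (QV), completeness and false-duplication estimates,
    trio binning of long reads and linked read pairs, phase-block and
    switch-error statistics, continuity (NG50) and telomere metrics,
    conservative gap patching from donor contigs, read-depth based collapsed
    repeat detection, optical-map digestion, molecule alignment, trio
    binning and allele cross-checking, assembly-based small-variant
    benchmarking with genotype-aware recall and Phred-scaled error metrics,
    and haplotype-versus-haplotype diversity summaries. Ships a synthetic
    diploid-trio generator (haplotypes, long reads, optical molecules,
    coverage tracks) with complete ground truth so every metric can be
    validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
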