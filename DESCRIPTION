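Package: haplopop
Title: Population Genomics Toolkit for Highly Heterozygous Clonally
    Propagated Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for domestication genomics of highly
    heterozygous, clonally propagated fruit crops such as lychee.
    Implements hard filtering of variant calls, sitewise nucleotide
    diversity and Tajima's D, a called-site-normalized pi_n/pi_s
    estimator of mutational load, Weir-Cockerham F_ST, linkage
    disequilibrium decay and pruning, the f3 admixture statistic with
    block-jackknife errors, KING-robust kinship with closest-relative
    cultivation-history graphs, haplotype-of-origin classification,
    allele-specific expression (differentially expressed alleles) with
    saturation analysis, Nei-Gojobori Ka/Ks for allelic gene pairs,
    coverage-based deletion genotyping with an in-silico PCR marker, and
    inbreeding-aware rescaling of effective-population-size
    trajectories. Ships a full synthetic-data generator (Balding-Nichols
    two-population model, Mendelian pedigrees, diverged haplotype
    genomes with a planted deletion, allelic count matrices, coverage
    tracks) with ground truth so that every stage is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
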