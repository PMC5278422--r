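Package: crisprAllele
Title: Strain-Specific CRISPR/Cas9 Site Discovery and Allele-Specific
    Editing Quantification from Amplicon Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for allele-aware CRISPR/Cas9 experiments in crosses of
    deep-sequenced strains. Scans genomes for candidate N20-NGG target
    sites, flags sites whose protospacer or PAM contains a single
    nucleotide variant discriminating two strains, and annotates them
    against gene models. Quantifies editing outcomes from amplicon deep
    sequencing: quality trimming and overlap merging of read pairs, glocal
    affine-gap alignment to amplicon references, per-read allele assignment
    via a diagnostic SNP, indel classification over the target window, loxP
    knock-in detection by 10-mer containment, deletion-junction calling,
    and per-locus allele-bias statistics (chi-squared and Fisher exact
    tests). Includes a synthetic-data generator with ground-truth manifests
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer,
    GenomicRanges,
    vcfR,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
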