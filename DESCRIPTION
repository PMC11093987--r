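Package: nlrdiversity
Title: Allelic Diversity and Genomic Features of Plant NLR Immune Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links intraspecies allelic diversity of plant NLR immune receptors
    to genomic features and population-genetic signatures of selection. Computes
    per-position Shannon entropy of clade alignments in the coordinates of a
    focal accession and classifies receptors as highly variable (hvNLR) or not;
    computes nucleotide diversity, Watterson's theta, Tajima's D, Nei-Gojobori
    piN/piS, domain-restricted and sliding-window statistics, and empirical-tail
    selection flags; derives per-gene expression (TPM), gene-body CG methylation,
    transposable-element proximity and physical clustering; and compares gene
    sets with rank-based single-sample scores and plain, covariate-matched and
    tail-count permutation tests. A coalescent-based simulator generates all
    pipeline inputs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
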