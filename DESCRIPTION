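Package: ribodelim
Title: Polyphasic Delineation of Cryptic Species from Ribosomal and
    Genomic Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for delineating cryptic species in complexes of closely
    related protists, modelled on the Amoebophrya ceratii species complex
    (Syndiniales). Implements ITS2 sequence-structure analysis on a 12-letter
    alphabet (global affine-gap alignment, Jukes-Cantor corrected
    neighbor-joining trees with bootstrap, compensatory base change counting
    and the zero-CBC species partition), alignment-free genome comparison on
    canonical k-mer presence/absence (Kulczynski, Ochiai and Chord distances,
    average-linkage clustering with bootstrap Jaccard stability), rDNA operon
    copy-number estimation from coverage ratios against single-copy genes,
    flow-cytometric genome sizing, phenotype ordination (Bray-Curtis PCoA with
    descriptor fitting), Outlying Mean Index niche analysis with
    abundance-weighted kernel densities and Schoener's D overlap, and
    copy-number-normalized fitness comparisons (Kruskal-Wallis with Dunn post
    hoc). A synthetic-data generator with planted ground truth reproduces the
    full study design for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    vegan,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
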