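Package: ighclone
Title: Clone-Library Amplicon Analysis of Intraorganismal Genetic
    Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying leaf-scale intraorganismal genetic
    heterogeneity from clone-library Sanger amplicon alignments.
    Provides per-plant polymorphic-site calling with configurable
    minor-allele support, merging of consecutive deletion columns into
    single indel events, classical diversity estimators (segregating
    sites S, haplotype number h, haplotype diversity Hd, and pairwise
    nucleotide diversity pi under complete- or pairwise-deletion gap
    handling), cross-plant classification of heterogeneous sites into
    shared-by-three, shared-by-two and plant-specific categories on a
    common callable-site mask, substitution-type spectra with
    transition/transversion ratios, and nucleotide-to-protein haplotype
    collapse of coding-sequence fragments.  A seeded clone-set
    simulator with planted variant structure, indel events and
    per-base error noise supplies ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
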