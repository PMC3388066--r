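Package: prdm9znf
Title: PRDM9 Zinc-Finger Array Typing, Diversity Tests and Selection Analysis
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the hypervariable tandem zinc-finger (ZnF)
    array of the recombination-hotspot gene PRDM9 in great apes. Decomposes
    phased array sequences into 84-bp repeat units, validates the C2H2
    scaffold and extracts the DNA-contact residues (helix positions -1, 2, 3
    and 6); collapses sequences into unique nucleotide and amino-acid alleles
    with repeat-letter encodings and cross-population sharing reports; runs
    permutation tests of allelic richness between and among populations;
    draws windowed-mismatch self-similarity dot plots with a two-block
    structure score; and fits codon site models of positive selection
    (GY94-style mixture models M0/M1a/M2a/M3/M7/M8 with likelihood-ratio
    tests, empirical-Bayes site classification and a sitewise per-site omega
    test). A synthetic-data generator produces repeat libraries, diploid
    array populations, grouped allele spectra, two-block arrays and codon
    alignments with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
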