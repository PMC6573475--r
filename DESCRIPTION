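Package: msyabc
Title: Paternal Population Structure and Demographic Model Choice for
    Non-Recombining Haploid Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Within- and between-population summary statistics for a
    non-recombining haploid locus such as the male-specific region of the
    Y chromosome (haplotype and haplogroup diversity, mean pairwise
    differences, Tajima's D with a fixed-S coalescent null, Phi-st,
    corrected pairwise differences, hierarchical AMOVA with permutation
    tests, Mantel tests, nonmetric MDS, shared-haplotype matrices and
    Mann-Whitney contrasts for postmarital-residence and language-family
    comparisons), together with a structured-coalescent simulator for
    three-deme demographic scenarios (demic diffusion, cultural diffusion
    and continuous migration), unfolded site-frequency-spectrum summaries,
    and approximate Bayesian computation model choice and parameter
    estimation by random forests. Includes a synthetic-data generator that
    reproduces the statistical structure such studies assume, so the whole
    pipeline is testable without access to restricted sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    geosphere,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
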